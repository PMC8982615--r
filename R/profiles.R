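#' @title Variable genes, library clustering and co-essentiality profiles
#' @name profiles
#' @description Genes whose normalized transposon counts vary most
#'   across libraries (by standard deviation) are the informative subset
#'   for condition-specific fitness. Libraries are clustered
#'   hierarchically (Ward criterion on Euclidean distance) on the
#'   normalized counts; gene-gene Pearson correlations of insertion
#'   profiles across libraries ("co-essentiality") are clustered on the
#'   distance 1 - r to reveal modules of functionally related genes.
NULL

#' Select the most variable genes across libraries
#'
#' Per-gene sample standard deviation (n - 1 denominator) of the
#' normalized counts across libraries, ranked descending. Ties are
#' broken lexicographically by gene id so the selection is deterministic.
#'
#' @param norm a `normalized_matrix` with >= 2 libraries.
#' @param k number of genes requested (commonly 200 or 500).
#' @return list with `gene_ids` (ordered by descending StdDev),
#'   `stddevs` (aligned), and `k`.
#' @export
select_variable_genes <- function(norm, k = 500) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (k < 1) stop("k must be >= 1")
  if (ncol(norm$values) < 2L) stop("need >= 2 libraries")
  sds <- apply(norm$values, 1L, stats::sd)
  if (k > length(sds)) {
    warning(sprintf("k = %d exceeds the %d genes available; returning all",
                    k, length(sds)))
    k <- length(sds)
  }
  ord <- order(-sds, norm$genes$gene_id)
  sel <- ord[seq_len(k)]
  list(gene_ids = norm$genes$gene_id[sel],
       stddevs = unname(sds[sel]), k = k)
}

#' Hierarchically cluster libraries on normalized counts
#'
#' Agglomerative clustering of libraries (items) over genes (features)
#' with the Ward criterion (`hclust` method "ward.D") on Euclidean
#' distances, as is conventional for insertion-library similarity. An
#' optional log2(x + 1) variance-stabilizing transform is available.
#'
#' @param norm a `normalized_matrix` with >= 2 libraries.
#' @param linkage `hclust` agglomeration method; default "ward.D".
#' @param log_transform apply log2(x + 1) before clustering.
#' @return an `hclust` object; `$order` gives the display leaf order.
#' @export
cluster_libraries <- function(norm, linkage = "ward.D",
                              log_transform = FALSE) {
  stopifnot(inherits(norm, "normalized_matrix"))
  m <- t(norm$values)
  if (log_transform) m <- log2(m + 1)
  if (!all(is.finite(m))) stop("non-finite values in normalized matrix")
  if (nrow(m) < 2L) stop("need >= 2 libraries")
  stats::hclust(stats::dist(m), method = linkage)
}

#' Gene-gene Pearson correlation of insertion profiles
#'
#' Pairwise Pearson correlation of the normalized counts across
#' libraries, usually restricted to a variable-gene subset to suppress
#' noise from genes with small, biologically meaningless fluctuations.
#' Genes with zero variance get `NA` correlations (flagged with a
#' warning; they are excluded by [cluster_correlation()]).
#'
#' @param norm a `normalized_matrix` with >= 3 libraries.
#' @param gene_subset character vector of gene ids (e.g.
#'   `select_variable_genes(norm, 500)$gene_ids`); default all genes.
#' @return list of class `gene_correlation`: `gene_ids`, `r` (symmetric
#'   correlation matrix, unit diagonal), `n_libraries`.
#' @export
gene_correlation <- function(norm, gene_subset = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (ncol(norm$values) < 3L) stop("need >= 3 libraries")
  if (is.null(gene_subset)) gene_subset <- norm$genes$gene_id
  missing <- setdiff(gene_subset, norm$genes$gene_id)
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  m <- norm$values[gene_subset, , drop = FALSE]
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance gene(s) have undefined correlations: ",
            paste(gene_subset[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(m), method = "pearson"))
  diag(r) <- 1
  structure(list(gene_ids = gene_subset, r = r,
                 n_libraries = ncol(m)),
            class = "gene_correlation")
}

#' Cluster a gene correlation matrix (co-essentiality clusterogram)
#'
#' Hierarchical clustering with the Ward criterion on the distance
#' `d = 1 - r`, the standard co-fitness convention. Genes with undefined
#' correlations are dropped (with a message) before clustering. Returns
#' the dendrogram, the leaf order, and the correlation matrix reordered
#' for clusterogram display.
#'
#' @param corr a `gene_correlation` object.
#' @return list with `hclust`, `leaf_order` (gene ids in display
#'   order), and `r_ordered` (symmetric permutation of the input).
#' @export
cluster_correlation <- function(corr) {
  stopifnot(inherits(corr, "gene_correlation"))
  r <- corr$r
  bad <- apply(r, 1L, function(z) any(is.na(z)))
  if (any(bad)) {
    message("excluding ", sum(bad),
            " gene(s) with undefined correlations from clustering")
    r <- r[!bad, !bad, drop = FALSE]
  }
  if (nrow(r) < 2L) stop("fewer than 2 genes with defined correlations")
  hc <- stats::hclust(stats::as.dist(1 - r), method = "ward.D")
  ord <- rownames(r)[hc$order]
  list(hclust = hc, leaf_order = ord,
       r_ordered = r[ord, ord, drop = FALSE])
}

#' Write a dendrogram as Newick
#'
#' @param hc an `hclust` object (from [cluster_libraries()] or
#'   [cluster_correlation()]`$hclust`).
#' @param path output file.
#' @export
write_dendrogram <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
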