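#' @title Depth normalization and library-set volcano comparisons
#' @name fitness
#' @description Transposon and read counts per gene are normalized to the
#'   total number of transposons/reads mapped in each library (expressed
#'   per million mapped events). Library-set comparisons report, per
#'   gene, the fold change of the test-set mean over the reference-set
#'   mean and a two-sided Student's (pooled-variance) t-test p-value;
#'   genes are then classified as required / dispensable / neutral /
#'   untestable at caller-supplied thresholds.
NULL

#' Depth-normalize a count matrix
#'
#' `value[g, l] = (count[g, l] + pseudocount) /
#'   (total[l] + pseudocount * G) * 1e6`, where `G` is the number of
#' genes and `total[l]` counts ALL mapped events in library `l` (genic
#' and intergenic). The default pseudocount of 1 raw count per gene per
#' library keeps downstream log fold changes finite for zero-count
#' genes; pseudocount 0 gives exact depth invariance.
#'
#' @param x a `gene_count_matrix`.
#' @param source "tn" (transposon counts, default) or "reads".
#' @param pseudocount non-negative count added per gene per library.
#' @return a `normalized_matrix` (list with `genes`, `libraries`,
#'   `values`, `source`, `pseudocount`).
#' @export
normalize_counts <- function(x, source = c("tn", "reads"),
                             pseudocount = 1) {
  stopifnot(inherits(x, "gene_count_matrix"), pseudocount >= 0)
  source <- match.arg(source)
  counts <- if (source == "tn") x$tn_counts else x$read_counts
  totals <- if (source == "tn") x$totals_tn else x$totals_reads
  if (any(totals == 0))
    stop("library with zero mapped total: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  G <- nrow(counts)
  values <- sweep(counts + pseudocount, 2L,
                  totals + pseudocount * G, "/") * 1e6
  structure(list(genes = x$genes, libraries = x$libraries,
                 values = values, source = source,
                 pseudocount = pseudocount),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf(
    "normalized_matrix (%s counts per 1e6 mapped, pseudocount %g): %d genes x %d libraries\n",
    x$source, x$pseudocount, nrow(x$values), ncol(x$values)))
  invisible(x)
}

## Vectorized two-sided pooled-variance (Student) t-test on the rows of
## two matrices. Returns NA where n < 2 in either group; where both
## group variances are zero, p = 1 if the means agree (t = 0) and NA
## otherwise (the statistic is undefined).
.row_student_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L)
    return(list(t = rep(NA_real_, nrow(a)), p = rep(NA_real_, nrow(a))))
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  zerovar <- va == 0 & vb == 0
  eq <- zerovar & ma == mb
  t[eq] <- 0; p[eq] <- 1
  t[zerovar & !eq] <- NA_real_; p[zerovar & !eq] <- NA_real_
  list(t = t, p = p)
}

## Welch variant (unequal variances), available behind a flag.
.row_welch_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L)
    return(list(t = rep(NA_real_, nrow(a)), p = rep(NA_real_, nrow(a))))
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  zerovar <- va == 0 & vb == 0
  eq <- zerovar & ma == mb
  t[eq] <- 0; p[eq] <- 1
  t[zerovar & !eq] <- NA_real_; p[zerovar & !eq] <- NA_real_
  list(t = t, p = p)
}

#' Compare two library sets gene by gene (volcano computation)
#'
#' For every gene, the mean normalized count of the test set is divided
#' by that of the reference set (fold change, reported as log2), and a
#' p-value for the difference is computed with a two-sided Student's
#' t-test (pooled variance; Welch available via `welch = TRUE`). When a
#' set has fewer than two libraries the p-value is reported as `NA`
#' (untestable) and the fold change is still returned, as in
#' single-library panels. A Benjamini-Hochberg FDR column is appended as
#' supplementary output; classification (see [classify_volcano()]) uses
#' the raw p-values.
#'
#' @param norm a `normalized_matrix`.
#' @param test_ids,ref_ids disjoint, non-empty character vectors of
#'   library identifiers present in `norm`.
#' @param welch use the unequal-variance t-test instead of the pooled
#'   one (default FALSE).
#' @return data.frame of class `volcano` with one row per gene:
#'   `gene_id`, `mean_test`, `mean_ref`, `log2fc`, `p_value`, `n_test`,
#'   `n_ref`, `bh_fdr`.
#' @export
compare_sets <- function(norm, test_ids, ref_ids, welch = FALSE) {
  stopifnot(inherits(norm, "normalized_matrix"))
  libs <- colnames(norm$values)
  unknown <- setdiff(c(test_ids, ref_ids), libs)
  if (length(unknown))
    stop("unknown library id(s): ", paste(unknown, collapse = ", "))
  if (!length(test_ids) || !length(ref_ids))
    stop("test and reference sets must be non-empty")
  if (length(intersect(test_ids, ref_ids)))
    stop("test and reference sets overlap: ",
         paste(intersect(test_ids, ref_ids), collapse = ", "))
  a <- norm$values[, test_ids, drop = FALSE]
  b <- norm$values[, ref_ids, drop = FALSE]
  tt <- if (welch) .row_welch_t(a, b) else .row_student_t(a, b)
  mean_test <- rowMeans(a); mean_ref <- rowMeans(b)
  out <- data.frame(gene_id = norm$genes$gene_id,
                    mean_test = mean_test, mean_ref = mean_ref,
                    log2fc = log2(mean_test / mean_ref),
                    p_value = tt$p,
                    n_test = length(test_ids), n_ref = length(ref_ids),
                    bh_fdr = stats::p.adjust(tt$p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("volcano", "data.frame")
  out
}

#' Classify volcano records into required / dispensable / neutral
#'
#' A gene is "required" in the test condition when its insertions are
#' significantly depleted (`p < p_cut` and `log2fc < fc_cut`),
#' "dispensable" when significantly enriched (`p < p_cut` and
#' `log2fc > dispensable_cut`), "untestable" when the p-value is
#' undefined, and "neutral" otherwise. Defaults follow the conventional
#' screen thresholds p < 0.05, log2 fold change < -0.5 (required) and
#' > 2 (dispensable).
#'
#' @param records a `volcano` data.frame from [compare_sets()].
#' @param fc_cut,p_cut,dispensable_cut classification thresholds.
#' @return `records` with a `class_label` column added.
#' @export
classify_volcano <- function(records, fc_cut = -0.5, p_cut = 0.05,
                             dispensable_cut = 2) {
  lab <- rep("neutral", nrow(records))
  p <- records$p_value; fc <- records$log2fc
  lab[!is.na(p) & p < p_cut & fc < fc_cut] <- "required"
  lab[!is.na(p) & p < p_cut & fc > dispensable_cut] <- "dispensable"
  lab[is.na(p)] <- "untestable"
  records$class_label <- lab
  records
}

#' Write a volcano table as TSV
#' @param records a `volcano` data.frame; @param path output path.
#' @export
write_volcano <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-gene log2 ratio to the gene's mean across libraries
#'
#' The heatmap transform: `out[g, l] = log2(value[g, l] / mean_l
#' value[g, .])`. Requires a strictly positive gene mean, which a
#' positive pseudocount in [normalize_counts()] guarantees. In linear
#' space each row's ratios average to exactly 1.
#'
#' @param norm a `normalized_matrix`.
#' @return gene x library numeric matrix of log2 ratios.
#' @export
relative_to_gene_mean <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  m <- rowMeans(norm$values)
  if (any(m == 0))
    stop("gene(s) with zero mean normalized count; use a positive ",
         "pseudocount in normalize_counts()")
  log2(norm$values / m)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by the square
#' root of the number of observations.
#'
#' @param values numeric vector, length >= 2.
#' @export
sem <- function(values) {
  if (length(values) < 2L) stop("sem() needs at least two values")
  stats::sd(values) / sqrt(length(values))
}
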