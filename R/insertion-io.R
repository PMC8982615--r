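#' @title Insertion-site and annotation input
#' @name insertion-io
#' @description Readers for the standard SATAY interchange formats:
#'   per-library insertion sites as BED (one record per transposon, the
#'   score column carrying the read count) or WIG (per-position read
#'   counts), and gene annotation as GFF3. All coordinates are held
#'   internally as 0-based half-open intervals; GFF3 (1-based inclusive)
#'   and WIG (1-based) are converted at the boundary, BED is taken as-is.
NULL

.str_unknown <- "*"

#' Construct an insertion-site table
#'
#' @param chrom,pos,strand,reads,library vectors of equal length; `pos`
#'   is 0-based, `reads` a non-negative integer read count per site.
#' @return data.frame of class `insertion_sites` with one row per unique
#'   (chrom, pos, strand, library) site.
#' @keywords internal
insertion_sites <- function(chrom = character(), pos = integer(),
                            strand = character(), reads = integer(),
                            library = character()) {
  stopifnot(all(pos >= 0), all(reads >= 0))
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), reads = as.numeric(reads),
                   library = as.character(library),
                   stringsAsFactors = FALSE)
  class(df) <- c("insertion_sites", "data.frame")
  df
}

## Merge duplicate (chrom, pos, strand, library) records by summing reads.
merge_duplicate_sites <- function(df) {
  # numeric composite key: small factor codes scaled around the position
  ci <- match(df$chrom, unique(df$chrom))
  si <- match(df$strand, c("+", "-", "*"))
  li <- match(df$library, unique(df$library))
  key <- ((ci - 1) * 3 + (si - 1)) * length(unique(li)) + (li - 1)
  key <- key * (max(df$pos) + 1) + df$pos
  if (!anyDuplicated(key)) return(df)
  n_dup <- sum(duplicated(key))
  agg <- rowsum(df$reads, key)
  keep <- df[!duplicated(key), , drop = FALSE]
  keep$reads <- agg[match(key[!duplicated(key)],
                          as.numeric(rownames(agg))), 1L]
  message(sprintf("merged %d duplicate insertion record(s) by summing reads",
                  n_dup))
  rownames(keep) <- NULL
  keep
}

#' Read transposon insertion sites from a BED file
#'
#' One BED record per insertion; the interval start is the insertion
#' position (0-based), column 5 (score) is interpreted as the read count
#' supporting the insertion. BED files with fewer than 5 columns get
#' `reads = 1` so transposon counting still works on minimal files.
#' Records duplicated at the same (chrom, pos, strand) are merged by
#' summing their read counts.
#'
#' @param path path to a BED file (>= 3 tab-separated columns; `track`,
#'   `browser` and `#` comment lines are skipped).
#' @param library_id identifier assigned to every site read.
#' @return an `insertion_sites` data.frame.
#' @export
parse_bed <- function(path, library_id) {
  stopifnot(is.character(path), length(path) == 1L)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    warning(sprintf("BED file '%s' contains no records", path))
    return(insertion_sites())
  }
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1L]]
    stop(sprintf("malformed BED line %d in '%s': fewer than 3 columns",
                 bad, path))
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- idx[which(is.na(starts) | is.na(ends))[1L]]
    stop(sprintf("malformed BED line %d in '%s': non-integer coordinates",
                 bad, path))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  score <- rep(1, length(fields))
  has5 <- nf >= 5L
  if (any(has5)) {
    raw <- vapply(fields[has5], `[`, "", 5L)
    val <- suppressWarnings(as.numeric(raw))
    val[raw == "."] <- 1
    if (anyNA(val)) {
      bad <- idx[has5][which(is.na(val))[1L]]
      stop(sprintf("malformed BED line %d in '%s': non-numeric score",
                   bad, path))
    }
    if (any(val < 0)) {
      bad <- idx[has5][which(val < 0)[1L]]
      stop(sprintf("negative score on BED line %d in '%s'", bad, path))
    }
    score[has5] <- val
  }
  strand <- rep(.str_unknown, length(fields))
  has6 <- nf >= 6L
  if (any(has6)) {
    s <- vapply(fields[has6], `[`, "", 6L)
    s[!s %in% c("+", "-")] <- .str_unknown
    strand[has6] <- s
  }
  df <- insertion_sites(chrom = chrom, pos = starts, strand = strand,
                        reads = score, library = library_id)
  merge_duplicate_sites(df)
}

#' Read transposon insertion sites from a WIG file
#'
#' Supports `variableStep` and `fixedStep` declarations (1-based
#' positions, value = read count at that position). Positions are
#' converted to 0-based; WIG carries no strand, so strand is recorded as
#' unknown (`"*"`). Zero values are dropped (no insertion evidence);
#' duplicate declarations for the same position are an error.
#'
#' @inheritParams parse_bed
#' @return an `insertion_sites` data.frame.
#' @export
parse_wig <- function(path, library_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|#)", lines)]
  if (!length(lines)) stop(sprintf("WIG file '%s' has no step header", path))
  chrom <- NULL; mode <- NULL; fstart <- NA_integer_; fstep <- NA_integer_
  pos <- integer(); val <- numeric(); chr <- character()
  parse_attr <- function(line, key) {
    m <- regmatches(line, regexec(paste0(key, "=([^ \t]+)"), line))[[1L]]
    if (length(m) < 2L) NA_character_ else m[2L]
  }
  for (ln in lines) {
    if (grepl("^variableStep", ln) || grepl("^fixedStep", ln)) {
      mode <- if (grepl("^variableStep", ln)) "variable" else "fixed"
      chrom <- parse_attr(ln, "chrom")
      if (is.na(chrom)) stop(sprintf("step header lacks chrom= in '%s'", path))
      if (mode == "fixed") {
        fstart <- as.integer(parse_attr(ln, "start"))
        fstep <- as.integer(parse_attr(ln, "step"))
        if (is.na(fstep)) fstep <- 1L
        if (is.na(fstart))
          stop(sprintf("fixedStep header lacks start= in '%s'", path))
      }
      next
    }
    if (is.null(mode))
      stop(sprintf("WIG data before any step header in '%s'", path))
    parts <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (mode == "variable") {
      if (length(parts) != 2L)
        stop(sprintf("malformed variableStep line '%s' in '%s'", ln, path))
      p <- as.integer(parts[1L]); v <- as.numeric(parts[2L])
    } else {
      p <- fstart; v <- as.numeric(parts[1L])
      fstart <- fstart + fstep
    }
    if (is.na(p) || is.na(v))
      stop(sprintf("malformed WIG value line '%s' in '%s'", ln, path))
    pos <- c(pos, p); val <- c(val, v); chr <- c(chr, chrom)
  }
  keep <- val != 0
  pos <- pos[keep]; val <- val[keep]; chr <- chr[keep]
  if (anyDuplicated(paste(chr, pos)))
    stop(sprintf("duplicate position declaration in WIG '%s'", path))
  insertion_sites(chrom = chr, pos = pos - 1L,
                  strand = .str_unknown, reads = val, library = library_id)
}

#' Load gene models from a GFF3 annotation
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention: `start = gff_start - 1`, `end = gff_end`.
#' The gene identifier is taken from the `ID` attribute; `Name` (if
#' present) is kept as the common name.
#'
#' @param path path to a GFF3 file.
#' @param feature_type feature type to retain (column 3); default "gene".
#' @return data.frame of class `gene_models` with columns `gene_id`,
#'   `common_name`, `chrom`, `start`, `end`, `strand`.
#' @export
load_annotation <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (!length(gr))
    stop(sprintf("no '%s' features found in '%s'", feature_type, path))
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    bad <- if (is.null(ids)) 1L else which(is.na(ids))[1L]
    stop(sprintf("feature %d of type '%s' in '%s' lacks an ID attribute",
                 bad, feature_type, path))
  }
  if (anyDuplicated(ids))
    stop(sprintf("duplicate ID '%s' in '%s'", ids[duplicated(ids)][1L], path))
  common <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  gene_models(gene_id = as.character(ids), common_name = common,
              chrom = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr) - 1L,
              end = GenomicRanges::end(gr),
              strand = as.character(GenomicRanges::strand(gr)))
}

#' Construct a gene-model table (0-based half-open intervals)
#' @keywords internal
gene_models <- function(gene_id, common_name = NA_character_, chrom,
                        start, end, strand = "*") {
  if (any(end <= start))
    stop("gene interval with end <= start: ",
         gene_id[which(end <= start)[1L]])
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  df <- data.frame(gene_id = as.character(gene_id),
                   common_name = as.character(common_name),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Library metadata table
#'
#' @param library library identifiers.
#' @param psd_target,pmt_target organelle the PE- / PC-synthesizing
#'   chimeric enzyme is targeted to (e.g. ER, MIM, endo, LD, pex, MM, or
#'   "none").
#' @param kennedy "ON" (ethanolamine + choline supplemented) or "OFF".
#' @param group_tags optional free-form tags (character, ";"-separated).
#' @return data.frame of class `library_meta`.
#' @export
library_metadata <- function(library, psd_target = "none",
                             pmt_target = "none", kennedy = "ON",
                             group_tags = "") {
  kennedy <- as.character(kennedy)
  if (!all(kennedy %in% c("ON", "OFF")))
    stop("kennedy must be 'ON' or 'OFF'")
  df <- data.frame(library = as.character(library),
                   psd_target = as.character(psd_target),
                   pmt_target = as.character(pmt_target),
                   kennedy = kennedy,
                   group_tags = as.character(group_tags),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$library))
    stop("duplicate library identifier in metadata")
  class(df) <- c("library_meta", "data.frame")
  df
}

#' Count transposons and reads per gene
#'
#' A site with `start <= pos < end` of a gene increments that gene's
#' transposon count by one and its read count by the site's reads, in the
#' site's library. Strand is ignored (transposon disruption is
#' strand-agnostic). A site falling inside several overlapping genes is
#' counted for all of them. Per-library totals are computed over ALL
#' sites, genic and intergenic, as the depth-normalization denominator.
#'
#' @param sites an `insertion_sites` data.frame (one or more libraries,
#'   e.g. `rbind` of several `parse_bed()` results).
#' @param genes a `gene_models` data.frame.
#' @param libraries optional `library_meta`; defaults to a minimal table
#'   derived from the libraries present in `sites`.
#' @param truncate_frac fraction of each gene's length excluded at both
#'   termini before counting (sensitivity analysis; default 0 = full
#'   interval).
#' @return a `gene_count_matrix` (see [write_count_matrix()]).
#' @export
count_per_gene <- function(sites, genes, libraries = NULL,
                           truncate_frac = 0) {
  stopifnot(truncate_frac >= 0, truncate_frac < 0.5)
  if (is.null(libraries))
    libraries <- library_metadata(sort(unique(sites$library)))
  libs <- libraries$library
  if (!all(sites$library %in% libs))
    stop("sites reference libraries absent from metadata: ",
         paste(setdiff(unique(sites$library), libs), collapse = ", "))

  g_start <- genes$start; g_end <- genes$end
  if (truncate_frac > 0) {
    trim <- floor((g_end - g_start) * truncate_frac)
    g_start <- g_start + trim; g_end <- g_end - trim
  }
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = g_start + 1L, end = g_end))

  missing_chr <- setdiff(unique(sites$chrom), unique(genes$chrom))
  if (length(missing_chr))
    warning("sites on chromosome(s) absent from annotation (counted ",
            "toward totals only): ", paste(missing_chr, collapse = ", "))

  G <- nrow(genes); L <- length(libs)
  tn <- matrix(0, G, L, dimnames = list(genes$gene_id, libs))
  rd <- matrix(0, G, L, dimnames = list(genes$gene_id, libs))
  lib_idx <- match(sites$library, libs)
  if (nrow(sites)) {
    site_gr <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(start = sites$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(site_gr, gene_gr,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      # accumulate on the linearized gene x library index
      lin <- sh + (lib_idx[qh] - 1L) * G
      tn[] <- tabulate(lin, nbins = G * L)
      agg <- rowsum(sites$reads[qh], lin)
      rd[as.integer(rownames(agg))] <- agg[, 1L]
    }
  }
  totals_tn <- vapply(seq_len(L), function(l) sum(lib_idx == l), 0)
  totals_rd <- vapply(seq_len(L),
                      function(l) sum(sites$reads[lib_idx == l]), 0)
  names(totals_tn) <- names(totals_rd) <- libs
  gene_count_matrix(genes = genes, libraries = libraries,
                    tn_counts = tn, read_counts = rd,
                    totals_tn = totals_tn, totals_reads = totals_rd)
}

#' Gene-by-library count matrix container
#'
#' @param genes `gene_models`; @param libraries `library_meta`;
#' @param tn_counts,read_counts gene x library matrices;
#' @param totals_tn,totals_reads per-library totals over all mapped
#'   sites (genic and intergenic).
#' @keywords internal
gene_count_matrix <- function(genes, libraries, tn_counts, read_counts,
                              totals_tn, totals_reads) {
  stopifnot(nrow(tn_counts) == nrow(genes),
            ncol(tn_counts) == nrow(libraries),
            all(dim(tn_counts) == dim(read_counts)),
            all(tn_counts >= 0), all(read_counts >= 0))
  structure(list(genes = genes, libraries = libraries,
                 tn_counts = tn_counts, read_counts = read_counts,
                 totals_tn = totals_tn, totals_reads = totals_reads),
            class = "gene_count_matrix")
}

#' @export
print.gene_count_matrix <- function(x, ...) {
  cat(sprintf("gene_count_matrix: %d genes x %d libraries\n",
              nrow(x$tn_counts), ncol(x$tn_counts)))
  cat(sprintf("  total transposons/library: %s\n",
              paste(format(x$totals_tn, big.mark = ","), collapse = ", ")))
  invisible(x)
}

#' Write / read a gene count matrix
#'
#' The matrix is serialized as a TSV (genes as rows, a `<lib>.tn` and
#' `<lib>.reads` column pair per library) plus a YAML sidecar
#' (`<path>.meta.yaml`) holding the library metadata and the per-library
#' totals. `read_count_matrix(write_count_matrix(x))` is the identity.
#'
#' @param x a `gene_count_matrix`; @param path TSV path.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` returns the `gene_count_matrix`.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "gene_count_matrix"))
  libs <- x$libraries$library
  df <- data.frame(gene_id = x$genes$gene_id,
                   common_name = x$genes$common_name,
                   chrom = x$genes$chrom, start = x$genes$start,
                   end = x$genes$end, strand = x$genes$strand,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (l in libs) {
    df[[paste0(l, ".tn")]] <- x$tn_counts[, l]
    df[[paste0(l, ".reads")]] <- x$read_counts[, l]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(
    libraries = lapply(seq_along(libs), function(i)
      as.list(x$libraries[i, , drop = FALSE])),
    totals_tn = as.list(stats::setNames(unname(x$totals_tn), libs)),
    totals_reads = as.list(stats::setNames(unname(x$totals_reads), libs)))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  lib_df <- do.call(rbind, lapply(meta$libraries, function(l)
    as.data.frame(l, stringsAsFactors = FALSE)))
  class(lib_df) <- c("library_meta", "data.frame")
  libs <- lib_df$library
  tn_cols <- paste0(libs, ".tn"); rd_cols <- paste0(libs, ".reads")
  if (!all(c(tn_cols, rd_cols) %in% names(df)))
    stop("count-matrix header does not match the metadata sidecar: ",
         "missing columns for library ",
         libs[!(tn_cols %in% names(df))][1L])
  genes <- gene_models(gene_id = df$gene_id, common_name = df$common_name,
                       chrom = df$chrom, start = df$start, end = df$end,
                       strand = df$strand)
  tn <- as.matrix(df[, tn_cols, drop = FALSE])
  rd <- as.matrix(df[, rd_cols, drop = FALSE])
  dimnames(tn) <- dimnames(rd) <- list(df$gene_id, libs)
  gene_count_matrix(genes, lib_df, tn, rd,
                    totals_tn = unlist(meta$totals_tn)[libs],
                    totals_reads = unlist(meta$totals_reads)[libs])
}
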