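# Fixtures built in code: tiny BED/WIG/GFF3 files and count matrices.

write_tmp <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a 3-gene annotation on two chromosomes (GFF3, 1-based inclusive)
tiny_gff_lines <- function() c(
  "##gff-version 3",
  "chrI\ttest\tgene\t101\t200\t.\t+\t.\tID=GENE1;Name=AAA1",
  "chrI\ttest\tgene\t301\t400\t.\t-\t.\tID=GENE2",
  "chrII\ttest\tgene\t51\t150\t.\t+\t.\tID=GENE3")

# build a gene_count_matrix directly from matrices (bypassing files)
make_counts <- function(tn, reads = tn * 10, totals_tn = colSums(tn) + 5,
                        totals_reads = colSums(reads) + 50,
                        kennedy = NULL) {
  libs <- colnames(tn)
  meta <- library_metadata(
    libs, kennedy = if (is.null(kennedy)) rep("ON", length(libs)) else kennedy)
  genes <- satayfit:::gene_models(
    gene_id = rownames(tn), chrom = "chrI",
    start = seq(0, by = 1000, length.out = nrow(tn)),
    end = seq(500, by = 1000, length.out = nrow(tn)))
  satayfit:::gene_count_matrix(genes, meta, tn, reads,
                               stats::setNames(totals_tn, libs),
                               stats::setNames(totals_reads, libs))
}

# random genome + sites for counting-oracle checks
random_counting_instance <- function(n_genes, n_sites, genome_len = 20000L) {
  start <- sort(sample.int(genome_len - 200L, n_genes))
  len <- sample(50:200, n_genes, replace = TRUE)
  genes <- satayfit:::gene_models(
    gene_id = sprintf("g%03d", seq_len(n_genes)), chrom = "chrI",
    start = start, end = pmin(start + len, genome_len))
  sites <- satayfit:::insertion_sites(
    chrom = "chrI",
    pos = sample.int(genome_len, n_sites, replace = TRUE) - 1L,
    strand = "*", reads = sample(1:50, n_sites, replace = TRUE),
    library = "L1")
  sites <- suppressMessages(satayfit:::merge_duplicate_sites(sites))
  list(genes = genes, sites = sites)
}

# brute-force oracle: per-site membership scan
brute_force_counts <- function(sites, genes) {
  tn <- matrix(0, nrow(genes), 1, dimnames = list(genes$gene_id, "L1"))
  rd <- tn
  for (i in seq_len(nrow(sites))) {
    inside <- genes$start <= sites$pos[i] & sites$pos[i] < genes$end &
      genes$chrom == sites$chrom[i]
    tn[inside, 1] <- tn[inside, 1] + 1
    rd[inside, 1] <- rd[inside, 1] + sites$reads[i]
  }
  list(tn = tn, reads = rd)
}
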