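test_that("parse_bed maps fields, defaults missing scores, merges duplicates", {
  path <- write_tmp(c("chrII\t1000\t1001\t.\t17\t+",
                      "chrI\t5\t6\t.\t4\t-",
                      "chrI\t5\t6\t.\t3\t-"), ".bed")
  sites <- suppressMessages(parse_bed(path, "lib1"))
  expect_equal(nrow(sites), 2L)
  s <- sites[sites$chrom == "chrII", ]
  expect_equal(s$pos, 1000L)
  expect_equal(s$reads, 17)
  expect_equal(s$strand, "+")
  expect_equal(s$library, "lib1")
  # duplicates at chrI:5 merged by summing reads
  expect_equal(sites$reads[sites$chrom == "chrI"], 7)
  expect_message(parse_bed(path, "x"), "merged 1 duplicate")

  # minimal BED3: reads default to 1
  p3 <- write_tmp("chrI\t10\t11", ".bed")
  expect_equal(parse_bed(p3, "x")$reads, 1)
  # "." score also means 1
  pdot <- write_tmp("chrI\t10\t11\t.\t.\t+", ".bed")
  expect_equal(parse_bed(pdot, "x")$reads, 1)
})

test_that("parse_bed merging is invariant to pre-deduplication", {
  dup <- write_tmp(c("chrI\t7\t8\t.\t5\t+", "chrI\t7\t8\t.\t3\t+",
                     "chrI\t9\t10\t.\t2\t+"), ".bed")
  dedup <- write_tmp(c("chrI\t7\t8\t.\t8\t+", "chrI\t9\t10\t.\t2\t+"),
                     ".bed")
  a <- suppressMessages(parse_bed(dup, "L"))
  b <- parse_bed(dedup, "L")
  expect_equal(a, b)
})

test_that("parse_bed rejects malformed input with line numbers", {
  bad <- write_tmp(c("chrI\t1\t2\t.\t5\t+", "chrI\tbroken"), ".bed")
  expect_error(parse_bed(bad, "x"), "line 2")
  neg <- write_tmp("chrI\t1\t2\t.\t-3\t+", ".bed")
  expect_error(parse_bed(neg, "x"), "negative score.*line 1")
  empty <- write_tmp(character(), ".bed")
  expect_warning(out <- parse_bed(empty, "x"), "no records")
  expect_equal(nrow(out), 0L)
})

test_that("parse_wig converts 1-based positions, drops zeros, keeps strand unknown", {
  path <- write_tmp(c("track type=wiggle_0",
                      "variableStep chrom=chrI",
                      "501 12", "600 0", "700 3"), ".wig")
  sites <- parse_wig(path, "w1")
  expect_equal(sites$pos, c(500L, 699L))
  expect_equal(sites$reads, c(12, 3))
  expect_true(all(sites$strand == "*"))

  fx <- write_tmp(c("fixedStep chrom=chrII start=10 step=5",
                    "2", "0", "4"), ".wig")
  sf <- parse_wig(fx, "w2")
  expect_equal(sf$pos, c(9L, 19L))  # positions 10 and 20, 0-based
  expect_equal(sf$reads, c(2, 4))
})

test_that("parse_wig rejects ill-formed files", {
  nohead <- write_tmp(c("501 12"), ".wig")
  expect_error(parse_wig(nohead, "x"), "step header")
  dup <- write_tmp(c("variableStep chrom=chrI", "501 12", "501 3"),
                   ".wig")
  expect_error(parse_wig(dup, "x"), "duplicate position")
})

test_that("load_annotation converts GFF3 coordinates and filters by type", {
  path <- write_tmp(tiny_gff_lines(), ".gff3")
  genes <- load_annotation(path)
  expect_equal(nrow(genes), 3L)
  g1 <- genes[genes$gene_id == "GENE1", ]
  expect_equal(g1$start, 100L)  # 1-based 101 -> 0-based 100
  expect_equal(g1$end, 200L)    # half-open end = gff end
  expect_equal(g1$end - g1$start, 100L)
  expect_equal(g1$common_name, "AAA1")
  # type filter
  mixed <- write_tmp(c("##gff-version 3",
                       "chrI\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
                       "chrI\tt\tCDS\t10\t90\t.\t+\t.\tID=c1"), ".gff3")
  expect_equal(load_annotation(mixed, "CDS")$gene_id, "c1")
  # missing / duplicate ID
  noid <- write_tmp(c("##gff-version 3",
                      "chrI\tt\tgene\t1\t100\t.\t+\t.\tName=x"), ".gff3")
  expect_error(load_annotation(noid), "ID")
  dup <- write_tmp(c("##gff-version 3",
                     "chrI\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
                     "chrI\tt\tgene\t200\t300\t.\t+\t.\tID=g1"), ".gff3")
  expect_error(load_annotation(dup), "duplicate ID")
})

test_that("count_per_gene honors half-open boundaries, additivity and totals", {
  genes <- satayfit:::gene_models(gene_id = "G1", chrom = "chrI",
                                  start = 100L, end = 200L)
  sites <- satayfit:::insertion_sites(
    chrom = "chrI", pos = c(99L, 100L, 150L, 199L, 200L, 500L),
    strand = "*", reads = c(1, 2, 5, 1, 9, 4), library = "L1")
  m <- count_per_gene(sites, genes)
  # pos 100, 150, 199 inside [100, 200); 99 and 200 outside
  expect_equal(unname(m$tn_counts["G1", "L1"]), 3)
  expect_equal(unname(m$read_counts["G1", "L1"]), 8)
  # totals cover ALL sites including intergenic
  expect_equal(unname(m$totals_tn[["L1"]]), 6)
  expect_equal(unname(m$totals_reads[["L1"]]), 22)
})

test_that("count_per_gene counts overlapping genes multiply and warns on foreign chromosomes", {
  genes <- satayfit:::gene_models(gene_id = c("A", "B"), chrom = "chrI",
                                  start = c(0L, 50L), end = c(100L, 150L))
  sites <- satayfit:::insertion_sites(
    chrom = c("chrI", "chrMT"), pos = c(75L, 10L), strand = "*",
    reads = c(3, 2), library = "L1")
  expect_warning(m <- count_per_gene(sites, genes), "chrMT")
  expect_equal(unname(m$tn_counts[, "L1"]), c(1, 1))  # both genes hit
  expect_equal(unname(m$totals_tn[["L1"]]), 2)        # chrMT in totals
})

test_that("terminal truncation shrinks the counted interval symmetrically", {
  genes <- satayfit:::gene_models(gene_id = "G", chrom = "c",
                                  start = 0L, end = 100L)
  sites <- satayfit:::insertion_sites(
    chrom = "c", pos = c(5L, 50L, 95L), strand = "*", reads = c(1, 1, 1),
    library = "L")
  full <- count_per_gene(sites, genes)
  trimmed <- count_per_gene(sites, genes, truncate_frac = 0.1)
  expect_equal(unname(full$tn_counts[1, 1]), 3)
  expect_equal(unname(trimmed$tn_counts[1, 1]), 1)  # only pos 50 in [10,90)
})

test_that("counting agrees exactly with a brute-force membership scan", {
  set.seed(11)
  for (i in 1:10) {
    inst <- random_counting_instance(sample(5:30, 1), sample(200:800, 1))
    m <- count_per_gene(inst$sites, inst$genes)
    bf <- brute_force_counts(inst$sites, inst$genes)
    expect_identical(unname(m$tn_counts), unname(bf$tn))
    expect_identical(unname(m$read_counts), unname(bf$reads))
  }
})

test_that("count matrix round-trips through TSV + sidecar", {
  tn <- matrix(c(3, 0, 7, 2, 1, 9, 4, 5, 0, 6), 5, 2,
               dimnames = list(sprintf("zg%d", c(5, 3, 1, 4, 2)),
                               c("libA", "libB")))
  m <- make_counts(tn)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  m2 <- read_count_matrix(path)
  expect_equal(m2$tn_counts, m$tn_counts)
  expect_equal(m2$read_counts, m$read_counts)
  expect_equal(m2$totals_tn, m$totals_tn)
  expect_equal(m2$libraries$library, m$libraries$library)
  # gene order preserved (deliberately non-alphabetical)
  expect_identical(m2$genes$gene_id, m$genes$gene_id)
  # sidecar listing a library absent from the header is an error
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  meta$libraries[[3]] <- meta$libraries[[1]]
  meta$libraries[[3]]$library <- "ghost"
  meta$totals_tn$ghost <- 1; meta$totals_reads$ghost <- 1
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  expect_error(read_count_matrix(path), "ghost|match")
})
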