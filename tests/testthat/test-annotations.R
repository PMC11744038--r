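toy_out <- system.file("extdata", "toy_repeatmasker.out", package = "ervscan")
toy_gtf <- system.file("extdata", "toy_genes.gtf", package = "ervscan")

test_that("RepeatMasker records parse with coordinates, strand and divergence", {
  rm <- read_repeatmasker(toy_out)
  expect_length(rm, 6L)
  ltr7y <- rm[rm$subfamily == "LTR7Y" & GenomicRanges::seqnames(rm) == "chr1"]
  expect_equal(GenomicRanges::start(ltr7y), 10001L)
  expect_equal(GenomicRanges::end(ltr7y), 10468L)
  expect_equal(GenomicRanges::width(ltr7y), 468L)  # qend - (qbegin - 1)
  expect_equal(as.character(GenomicRanges::strand(ltr7y)), "+")
  expect_equal(ltr7y$divergence_pct, 1.3)
  expect_equal(ltr7y$class_family, "LTR/ERV1")
  # complement convention
  mlt <- rm[rm$subfamily == "MLT2A1"]
  expect_equal(as.character(GenomicRanges::strand(mlt)), "-")
  expect_false(anyDuplicated(rm$copy_id) > 0)
})

test_that("header-only and malformed RepeatMasker input are handled", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c("h1", "h2", ""), f)
  expect_length(read_repeatmasker(f), 0L)

  writeLines(c("h1", "h2", "", "100 1.0 0 0 chr1 10 20"), f)
  expect_error(read_repeatmasker(f), "line 4")
  writeLines(c("h1", "h2", "",
               "100 1.0 0 0 chr1 ten 20 (0) + R1 LTR/ERV1 1 10 (0) 1"), f)
  expect_error(read_repeatmasker(f), "line 4")
})

test_that("GTF parsing keeps genes and exons with converted widths", {
  g <- read_gene_features(toy_gtf)
  expect_setequal(unique(g$feature_type), c("gene", "exon"))
  ex <- g[g$feature_type == "exon" & g$gene_id == "GENE0001"]
  expect_length(ex, 2L)  # two exons, one gene_id
  # 1-based inclusive 30000..30500 spans 501 bases
  expect_equal(GenomicRanges::width(ex)[1], 501L)
  # no CDS or other feature types retained
  expect_false(any(g$feature_type %in% c("CDS", "transcript")))
})

test_that("ERV selection follows class/family prefixes", {
  rm <- read_repeatmasker(toy_out)
  e <- select_erv_copies(rm)
  expect_true(all(startsWith(e$class_family, "LTR/ERV")))
  expect_false("AluY" %in% e$subfamily)
  expect_true("MLT1B" %in% e$subfamily)  # LTR/ERVL-MaLR retained
  custom <- select_erv_copies(rm, classes = "SINE/Alu")
  expect_equal(custom$subfamily, "AluY")
})

test_that("intergenic filtering removes any-overlap copies, half-open safe", {
  genes <- toy_genes(1150, 1300)
  over <- toy_copies(1100, 1199)      # 50 bp overlap -> removed
  adj <- toy_copies(1000, 1149)       # abuts the gene start -> retained
  far <- toy_copies(5000, 5100, chrom = "chrZ")  # other chromosome
  expect_length(filter_intergenic(over, genes), 0L)
  expect_length(filter_intergenic(adj, genes), 1L)
  expect_length(filter_intergenic(far, genes), 1L)
  # strand-blind: opposite-strand overlap still masks
  expect_length(filter_intergenic(toy_copies(1150, 1250, strand = "-"), genes), 0L)
})

test_that("intergenic filtering is idempotent and partitions counts", {
  set.seed(11)
  fx <- random_count_fixture(0, 60, n_subs = 6)
  genes <- toy_genes(c(1000, 20000), c(5000, 30000), chrom = "chrA")
  once <- filter_intergenic(fx$features, genes)
  twice <- filter_intergenic(once, genes)
  expect_identical(once, twice)
  once$divergence_pct <- 1; once$copy_id <- as.character(seq_along(once))
  s <- suppressMessages(summarize_subfamilies(once, fx$features))
  expect_equal(sum(s$n_copies_intergenic), length(once))
  expect_true(all(s$n_copies_intergenic <= s$n_copies_total))
})

test_that("subfamily summaries merge lengths and average divergence", {
  cp <- toy_copies(c(1, 51), c(100, 150), div = c(2, 4))
  s <- summarize_subfamilies(cp)
  expect_equal(s$mean_divergence_pct, 3)
  expect_equal(s$merged_length_bp, 150)  # [1,100] u [51,150]
  # length-weighted alternative
  cp2 <- toy_copies(c(1, 201), c(100, 500), div = c(2, 4))
  sw <- summarize_subfamilies(cp2, weighted = TRUE)
  expect_equal(sw$mean_divergence_pct,
               (2 * 100 + 4 * 300) / 400)
  # zero intergenic copies -> flagged unusable
  empty <- suppressMessages(
    summarize_subfamilies(cp[0], cp))
  expect_false(empty$usable)
  expect_true(is.na(empty$mean_divergence_pct))
})

test_that("merged length equals per-base occupancy on random copies", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 30
    starts <- sample.int(9000, n, replace = TRUE)
    ends <- pmin(starts + sample(50:800, n, replace = TRUE), 10000L)
    cp <- toy_copies(starts, ends, div = runif(n, 0, 30))
    s <- summarize_subfamilies(cp)
    occupied <- logical(10000)
    for (i in seq_len(n)) occupied[starts[i]:ends[i]] <- TRUE
    expect_equal(s$merged_length_bp, sum(occupied))
    expect_equal(s$mean_divergence_pct, mean(cp$divergence_pct))
  }
})

test_that("BED round-trip preserves intervals and strand", {
  rm <- read_repeatmasker(toy_out)
  e <- select_erv_copies(rm)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(e, f)
  # BED is 0-based half-open: first record starts at qbegin - 1
  first <- strsplit(readLines(f)[1], "\t")[[1]]
  expect_equal(as.integer(first[2]),
               GenomicRanges::start(e)[1] - 1L)
  back <- read_bed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(e))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(e))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(e)))
  expect_equal(back$subfamily, e$subfamily)
})
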