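# SAM fixture writer: minimal paired-end records.
write_toy_sam <- function(path, recs,
                          sq = "@SQ\tSN:chr1\tLN:100000") {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", sq, recs), path)
}

sam_pair <- function(qname, chrom, left, right, read_len = 50,
                     strand1 = "+", mapq = 60L, dup = FALSE) {
  dupbit <- if (dup) 1024L else 0L
  if (strand1 == "+") {
    f1 <- 99L + dupbit; f2 <- 147L + dupbit; p1 <- left; p2 <- right
  } else {
    f1 <- 83L + dupbit; f2 <- 163L + dupbit; p1 <- right; p2 <- left
  }
  tlen <- right + read_len - left
  seq <- strrep("A", read_len); qual <- strrep("I", read_len)
  c(sprintf("%s\t%d\tchr1\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
            qname, f1, p1, mapq, read_len, p2,
            if (p1 <= p2) tlen else -tlen, seq, qual),
    sprintf("%s\t%d\tchr1\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
            qname, f2, p2, mapq, read_len, p1,
            if (p1 <= p2) -tlen else tlen, seq, qual))
}

test_that("fragments span the template and take read-1 strand", {
  f <- withr::local_tempfile(fileext = ".sam")
  write_toy_sam(f, c(
    sam_pair("pairA", "chr1", 101, 221, read_len = 50, strand1 = "+"),
    sam_pair("pairB", "chr1", 1001, 1101, read_len = 50, strand1 = "-")
  ))
  fr <- load_fragments(f)
  fr <- fr[order(fr$qname)]
  expect_length(fr, 2L)
  expect_equal(GenomicRanges::start(fr), c(101L, 1001L))
  expect_equal(GenomicRanges::end(fr), c(270L, 1150L))  # rightmost base
  expect_equal(as.character(GenomicRanges::strand(fr)), c("+", "-"))
})

test_that("record-level filters drop low-MAPQ and duplicate templates", {
  f <- withr::local_tempfile(fileext = ".sam")
  write_toy_sam(f, c(
    sam_pair("keep", "chr1", 101, 221),
    sam_pair("lowq", "chr1", 501, 621, mapq = 10L),
    sam_pair("dupe", "chr1", 901, 1021, dup = TRUE)
  ))
  fr <- load_fragments(f)
  expect_equal(fr$qname, "keep")
  # filters are parameters, not constants
  all3 <- load_fragments(f, counting_params(min_mapq = 0L,
                                            ignore_duplicates = FALSE))
  expect_setequal(all3$qname, c("keep", "lowq", "dupe"))
})

test_that("orphaned mates yield a single-read fragment", {
  f <- withr::local_tempfile(fileext = ".sam")
  pr <- sam_pair("orphan", "chr1", 101, 221)
  # keep only read 1; its mate never appears
  write_toy_sam(f, pr[1])
  fr <- load_fragments(f)
  expect_length(fr, 1L)
  expect_equal(GenomicRanges::width(fr), 50L)
})

test_that("strand-compatible overlap assigns; ambiguity drops", {
  copies <- c(
    toy_copies(150, 400, strand = "+", subfamily = "LTR7Y"),
    toy_copies(2000, 2400, strand = "+", subfamily = "MER48"),
    toy_copies(2300, 2800, strand = "+", subfamily = "LTR7Y")
  )
  # reverse mode: minus fragment over plus copy -> assigned
  r <- count_fragments(toy_fragments(100, 200, strand = "-"), copies)
  expect_equal(r$counts[["LTR7Y"]], 1L)
  expect_equal(r$assigned_total, 1L)
  # sense fragment -> not compatible, no_feature
  r <- count_fragments(toy_fragments(100, 200, strand = "+"), copies)
  expect_equal(r$assigned_total, 0L)
  expect_equal(r$no_feature, 1L)
  # fragment across MER48 and LTR7Y -> ambiguous, dropped
  r <- count_fragments(toy_fragments(2350, 2450, strand = "-"), copies)
  expect_equal(r$ambiguous, 1L)
  expect_equal(sum(r$counts), 0L)
  # two copies of ONE subfamily count once
  copies2 <- toy_copies(c(100, 150), c(200, 300), strand = "+",
                        subfamily = "LTR7Y")
  r <- count_fragments(toy_fragments(140, 260, strand = "-"), copies2)
  expect_equal(r$counts[["LTR7Y"]], 1L)
})

test_that("counting matches the brute-force quadratic oracle", {
  set.seed(77)
  for (rep in 1:4) {
    fx <- random_count_fixture(n_frags = 500, n_copies = 80)
    for (mode in c("reverse", "forward", "unstranded")) {
      p <- counting_params(strandedness = mode)
      fast <- count_fragments(fx$fragments, fx$features, p)
      slow <- brute_force_count(fx$fragments, fx$features, mode)
      expect_identical(fast$counts, slow$counts)
      expect_identical(fast$ambiguous, slow$ambiguous)
      expect_identical(fast$no_feature, slow$no_feature)
    }
  }
})

test_that("counting conserves fragments and ignores input order", {
  set.seed(5)
  fx <- random_count_fixture(n_frags = 300, n_copies = 50)
  r <- count_fragments(fx$fragments, fx$features)
  expect_equal(r$assigned_total + r$ambiguous + r$no_feature, r$n_fragments)
  shuffled <- fx$fragments[sample(length(fx$fragments))]
  r2 <- count_fragments(shuffled, fx$features)
  expect_identical(r$counts, r2$counts)
  expect_identical(r$ambiguous, r2$ambiguous)
})

test_that("empty feature set warns and counts nothing", {
  fr <- toy_fragments(1, 100)
  expect_warning(r <- count_fragments(fr, toy_copies(1, 100)[0]), "empty")
  expect_equal(r$no_feature, 1L)
})

test_that("FPKM follows the defining formula", {
  # count 10, length 1 kb, 1e6 assigned -> FPKM 10
  expect_equal(compute_fpkm(matrix(10), 1000, 1e6)[1, 1], 10)
  expect_equal(compute_fpkm(matrix(0), 1000, 1e6)[1, 1], 0)
  # random matrix equals the elementwise scalar loop
  set.seed(3)
  cm <- matrix(rpois(80, 40), nrow = 20,
               dimnames = list(sprintf("f%02d", 1:20), sprintf("s%d", 1:4)))
  lens <- sample(200:5000, 20)
  tot <- sample(1e5:1e6, 4)
  got <- compute_fpkm(cm, lens, tot)
  want <- cm
  for (i in 1:20) for (j in 1:4) {
    want[i, j] <- cm[i, j] * 1e9 / (as.numeric(lens[i]) * tot[j])
  }
  expect_equal(got, want)
  # scale invariance: doubling counts and totals changes nothing
  expect_equal(compute_fpkm(2 * cm, lens, 2 * tot), got)
})

test_that("FPKM rejects degenerate inputs", {
  expect_error(compute_fpkm(matrix(5), 1000, 0), "zero assigned")
  expect_error(compute_fpkm(matrix(5), 0, 1e6), "non-positive length")
  # zero-length feature with zero counts is tolerated
  cm <- matrix(c(0, 5), nrow = 2, dimnames = list(c("a", "b"), "s"))
  expect_equal(compute_fpkm(cm, c(0, 100), 1e6)["a", ], 0)
})
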