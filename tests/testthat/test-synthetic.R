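small_cfg <- function(...) {
  sim_config(seed = 11, n_subfamilies = 12, n_genes = 10, n_planted = 2,
             chromosome_length_bp = 3e5, ...)
}

test_that("annotation simulation is byte-identical under a fixed seed", {
  cfg <- small_cfg()
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(readLines(a1$rmsk_out), readLines(a2$rmsk_out))
  expect_identical(readLines(a1$gtf), readLines(a2$gtf))
  expect_identical(a1$truth, a2$truth)
  # and the RNG stream of the session is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); simulate_annotation(cfg); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("simulated files round-trip through the parsers", {
  ann <- simulate_annotation(small_cfg())
  rm <- read_repeatmasker(ann$rmsk_out)
  expect_equal(length(rm), length(ann$copies))
  expect_equal(rm$subfamily, ann$copies$subfamily)
  expect_equal(GenomicRanges::start(rm), GenomicRanges::start(ann$copies))
  expect_equal(as.character(GenomicRanges::strand(rm)),
               as.character(GenomicRanges::strand(ann$copies)))
  expect_equal(rm$divergence_pct, ann$copies$divergence_pct)
  g <- read_gene_features(ann$gtf)
  expect_equal(sum(g$feature_type == "gene"), length(ann$genes))
})

test_that("genic placement fraction drives the intergenic filter", {
  cfg <- sim_config(seed = 3, n_subfamilies = 25, copies_per_subfamily = c(4, 4),
                    n_genes = 15, genic_overlap_fraction = 0.2,
                    n_planted = 0, chromosome_length_bp = 2e6)
  ann <- simulate_annotation(cfg)
  kept <- filter_intergenic(ann$copies, ann$genes)
  removed <- length(ann$copies) - length(kept)
  # 100 copies, 20% deliberately genic; binomial 3-sigma tolerance plus
  # a little slack for by-chance overlaps of "intergenic" placements
  expect_gte(removed, 8)
  expect_lte(removed, 36)
  expect_true(all(ann$copies$copy_id[ann$copies$genic] %in%
                    setdiff(ann$copies$copy_id, kept$copy_id)))
})

test_that("divergence tiers respect their configured ranges", {
  cfg <- sim_config(seed = 5, n_subfamilies = 100, young_fraction = 0.5,
                    n_planted = 0, n_genes = 5, chromosome_length_bp = 5e6)
  ann <- simulate_annotation(cfg)
  tier <- ann$truth$age_tier[match(ann$copies$subfamily,
                                   ann$truth$subfamily)]
  young_div <- ann$copies$divergence_pct[tier == "young"]
  old_div <- ann$copies$divergence_pct[tier == "old"]
  expect_true(all(young_div >= 0.5 & young_div <= 8))
  expect_true(all(old_div >= 8 & old_div <= 30))
  expect_equal(sum(ann$truth$age_tier == "young"), 50L)
})

test_that("count simulation is deterministic and plants the fold-change", {
  cfg <- sim_config(seed = 21, n_subfamilies = 200, n_planted = 20,
                    fold_change = 8, dispersion = 0.1)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$counts >= 0))
  is_case <- s1$samples$condition == "covid"
  ratio <- rowMeans(s1$counts[, is_case]) / rowMeans(s1$counts[, !is_case])
  planted_ratio <- mean(ratio[s1$truth$planted])
  expect_gt(planted_ratio, 6)
  expect_lt(planted_ratio, 10)
})

test_that("null counts leave planted and non-planted indistinguishable", {
  cfg <- sim_config(seed = 33, n_subfamilies = 300, n_planted = 30,
                    fold_change = 1.0000001)  # planted flag set, no effect
  s <- simulate_counts(cfg)
  norm <- s$counts / s$truth$baseline_mean
  ks <- suppressWarnings(
    ks.test(as.vector(norm[s$truth$planted, ]),
            as.vector(norm[!s$truth$planted, ])))
  expect_gt(ks$p.value, 0.01)
})

test_that("read-level targets are recovered exactly by the counting pipeline", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  ig <- filter_intergenic(ann$copies, ann$genes)
  subs <- unique(ig$subfamily)[1:4]
  set.seed(2)
  target <- matrix(sample(0:9, 8, replace = TRUE), nrow = 4,
                   dimnames = list(subs, c("S1", "S2")))
  target[1, 1] <- 7L  # an isolated guaranteed case
  rd <- simulate_reads(ann, target, cfg)
  for (s in c("S1", "S2")) {
    fr <- load_fragments(rd$sam_paths[[s]])
    r <- count_fragments(fr, ig)
    expect_equal(r$counts[subs], target[, s],
                 ignore_attr = FALSE)
    expect_equal(r$ambiguous, 0L)
    expect_equal(r$no_feature, 0L)
  }
})

test_that("spiked fragments are excluded exactly as recorded in truth", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  ig <- filter_intergenic(ann$copies, ann$genes)
  subs <- unique(ig$subfamily)[1:3]
  target <- matrix(c(5L, 4L, 3L), nrow = 3, dimnames = list(subs, "S1"))
  rd <- simulate_reads(ann, target, cfg,
                       spikeins = c(low_mapq = 2, duplicate = 2,
                                    wrong_strand = 3, cross_subfamily = 1))
  tr <- rd$spikein_truth
  expect_equal(nrow(tr), 8L)
  fr <- load_fragments(rd$sam_paths[["S1"]])
  # low-MAPQ and duplicate templates never survive loading
  filtered <- tr$qname[tr$expected == "filtered"]
  expect_false(any(filtered %in% fr$qname))
  r <- count_fragments(fr, ig)
  expect_equal(r$counts[subs], target[, "S1"])
  expect_equal(r$ambiguous, sum(tr$expected == "ambiguous"))
  expect_equal(r$no_feature, sum(tr$expected == "no_feature"))
})

test_that("a too-short copy for the fragment geometry is reported by name", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  # shrink one subfamily's copies below the minimum fragment length
  short <- ann$copies[ann$copies$subfamily == ann$truth$subfamily[1]]
  GenomicRanges::end(short) <- GenomicRanges::start(short) + 50L
  ann$copies[ann$copies$subfamily == ann$truth$subfamily[1]] <- short
  target <- matrix(3L, 1, 1,
                   dimnames = list(ann$truth$subfamily[1], "S1"))
  expect_error(simulate_reads(ann, target, cfg), "shorter")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(div_young = c(0.5, 10), div_old = c(8, 30)))
  expect_error(sim_config(fold_change = 1))
  expect_error(sim_config(dispersion = 0))
  expect_error(sim_config(n_planted = 60, n_subfamilies = 50))
  expect_error(simulate_annotation(
    sim_config(n_subfamilies = 200, copies_per_subfamily = c(50, 50),
               chromosome_length_bp = 1e4, copy_length_bp = c(600, 800),
               n_genes = 30, gene_length_bp = c(2000, 3000),
               n_planted = 0)))
})
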