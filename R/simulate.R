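#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: multiple-cohort
#' bulk RNA-seq with two conditions and unequal group sizes (the default
#' 10 cases vs 5 controls mirrors a platelet-style cohort),
#' subfamily-level negative-binomial counts with log-normal library size
#' factors, an age-structured divergence distribution (young tier
#' uniform on [0.5, 8] percent, old tier on [8, 30]), and
#' condition-specific upregulation planted in a chosen age tier.
#'
#' @param seed integer seed; every stochastic output is a pure function
#'   of the configuration including this seed.
#' @param n_chromosomes,chromosome_length_bp genome geometry.
#' @param n_subfamilies number of ERV subfamilies.
#' @param copies_per_subfamily integer range (min, max).
#' @param copy_length_bp copy length range in bp.
#' @param young_fraction fraction of subfamilies in the young tier.
#' @param div_young,div_old per-copy divergence ranges (percent) of the
#'   two tiers.
#' @param n_genes,gene_length_bp gene annotation geometry.
#' @param genic_overlap_fraction fraction of copies deliberately placed
#'   overlapping a gene (exercises the intergenic filter).
#' @param n_control,n_case group sizes.
#' @param n_icu of the cases, how many are ICU (the rest are non-ICU);
#'   0 leaves severity unknown.
#' @param baseline_mean baseline mean count range per subfamily
#'   (log-uniform).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param size_factor_sdlog sdlog of the log-normal per-sample size
#'   factors (centred on 1).
#' @param n_planted number of subfamilies with planted upregulation.
#' @param fold_change planted fold-change in cases, > 1.
#' @param planted_age_tier `"young"`, `"old"` or `"mixed"` — which tier
#'   the planted subfamilies are drawn from.
#' @param feature_length_bp nominal subfamily merged-length range used
#'   by the count-level route when no annotation is simulated.
#' @param read_length_bp,insert_mean_bp,insert_sd_bp fragment geometry
#'   for read-level simulation.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L, chromosome_length_bp = 1e6,
                       n_subfamilies = 50L, copies_per_subfamily = c(3L, 8L),
                       copy_length_bp = c(600L, 3000L),
                       young_fraction = 0.3,
                       div_young = c(0.5, 8), div_old = c(8, 30),
                       n_genes = 40L, gene_length_bp = c(2000L, 10000L),
                       genic_overlap_fraction = 0.1,
                       n_control = 5L, n_case = 10L, n_icu = 0L,
                       baseline_mean = c(50, 500), dispersion = 0.1,
                       size_factor_sdlog = 0.15,
                       n_planted = 5L, fold_change = 8,
                       planted_age_tier = c("young", "old", "mixed"),
                       feature_length_bp = c(500, 5000),
                       read_length_bp = 100L, insert_mean_bp = 250L,
                       insert_sd_bp = 30L) {
  planted_age_tier <- match.arg(planted_age_tier)
  stopifnot(
    is_count(seed), is_count(n_chromosomes, 1), chromosome_length_bp >= 1e4,
    is_count(n_subfamilies, 1), length(copies_per_subfamily) == 2,
    copies_per_subfamily[1] >= 1,
    copies_per_subfamily[2] >= copies_per_subfamily[1],
    young_fraction >= 0, young_fraction <= 1,
    div_young[1] < div_young[2], div_old[1] < div_old[2],
    div_young[2] <= div_old[1],  # tiers must not overlap
    is_count(n_genes), is_count(n_control, 2), is_count(n_case, 2),
    is_count(n_icu), n_icu <= n_case,
    baseline_mean[1] > 0, baseline_mean[2] >= baseline_mean[1],
    dispersion > 0, size_factor_sdlog >= 0,
    is_count(n_planted), n_planted <= n_subfamilies, fold_change > 1,
    copy_length_bp[1] >= 2 * read_length_bp,
    insert_mean_bp >= 2 * read_length_bp
  )
  cfg <- mget(setdiff(names(formals(sim_config)), "..."))
  cfg$planted_age_tier <- planted_age_tier
  structure(cfg, class = "sim_config")
}

sim_subfamily_truth <- function(config) {
  n <- config$n_subfamilies
  n_young <- round(config$young_fraction * n)
  tier <- rep(c("young", "old"), c(n_young, n - n_young))
  pool <- switch(config$planted_age_tier,
                 young = which(tier == "young"),
                 old = which(tier == "old"),
                 mixed = seq_len(n))
  if (config$n_planted > length(pool)) {
    stopf("cannot plant %d subfamilies in tier '%s' (only %d available)",
          config$n_planted, config$planted_age_tier, length(pool))
  }
  planted <- rep(FALSE, n)
  if (config$n_planted > 0) {
    planted[resample(pool, config$n_planted)] <- TRUE
  }
  data.frame(
    subfamily = sprintf("ERVSIM%03d", seq_len(n)),
    age_tier = tier,
    planted = planted,
    true_fold_change = ifelse(planted, config$fold_change, 1),
    stringsAsFactors = FALSE
  )
}

sim_samples <- function(config) {
  n_case <- config$n_case
  severity <- rep("unknown", n_case)
  if (config$n_icu > 0) {
    severity <- rep(c("non_icu", "icu"), c(n_case - config$n_icu, config$n_icu))
  }
  data.frame(
    sample_id = c(sprintf("CTRL%02d", seq_len(config$n_control)),
                  sprintf("COVID%02d", seq_len(n_case))),
    condition = rep(c("control", "covid"), c(config$n_control, n_case)),
    severity = c(rep("none", config$n_control), severity),
    stringsAsFactors = FALSE
  )
}

#' Simulate a repeat and gene annotation with ground truth
#'
#' Places genes and ERV copies uniformly at random on a toy genome. A
#' configurable fraction of copies is deliberately placed overlapping a
#' gene so the intergenic filter has work to do; the rest are placed in
#' gene-free space by rejection sampling. Per-copy divergence is drawn
#' uniformly within the subfamily's age tier. Outputs are valid
#' RepeatMasker `.out` and GTF dialects, re-readable by
#' [read_repeatmasker()] and [read_gene_features()], and byte-identical
#' across runs with the same configuration.
#'
#' @param config a [sim_config()] object.
#' @param dir output directory (created if needed); default a fresh
#'   temporary directory.
#' @return list with paths `rmsk_out` and `gtf`, in-memory `copies` and
#'   `genes` (`GRanges`), the `truth` table (subfamily tier, planted
#'   flag, fold-change, genic flag per copy summarised) and `samples`.
#' @export
simulate_annotation <- function(config, dir = tempfile("ervsim")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, {
    truth <- sim_subfamily_truth(config)
    chroms <- sprintf("chrSIM%d", seq_len(config$n_chromosomes))
    L <- config$chromosome_length_bp

    glen <- resample(config$gene_length_bp[1]:config$gene_length_bp[2],
                     config$n_genes, replace = TRUE)
    gchrom <- resample(chroms, config$n_genes, replace = TRUE)
    gstart <- vapply(glen, function(l) sample.int(L - l, 1L), integer(1))
    genes <- GenomicRanges::GRanges(
      gchrom, IRanges::IRanges(gstart, width = glen),
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      gene_id = sprintf("GENE%04d", seq_len(config$n_genes)),
      feature_type = "gene"
    )

    ncopies <- resample(config$copies_per_subfamily[1]:config$copies_per_subfamily[2],
                        config$n_subfamilies, replace = TRUE)
    total <- sum(ncopies)
    sub_of_copy <- rep(truth$subfamily, ncopies)
    tier_of_copy <- rep(truth$age_tier, ncopies)
    clen <- resample(config$copy_length_bp[1]:config$copy_length_bp[2],
                     total, replace = TRUE)
    genic <- runif(total) < config$genic_overlap_fraction
    cchrom <- character(total)
    cstart <- integer(total)
    # intergenic placements avoid genes AND previously placed intergenic
    # copies, so that a fragment wholly inside one copy can never touch a
    # copy of another subfamily (keeps read-level truth exact)
    placed_free <- GenomicRanges::GRanges()
    for (i in seq_len(total)) {
      if (genic[i] && config$n_genes > 0) {
        g <- genes[sample.int(length(genes), 1L)]
        cchrom[i] <- as.character(GenomicRanges::seqnames(g))
        lo <- max(1L, GenomicRanges::start(g) - clen[i] + 1L)
        hi <- min(GenomicRanges::end(g), L - clen[i])
        cstart[i] <- if (hi >= lo) resample(lo:hi, 1L) else GenomicRanges::start(g)
      } else {
        placed <- FALSE
        for (try in 1:200) {
          ch <- resample(chroms, 1L)
          st <- sample.int(L - clen[i], 1L)
          cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = clen[i]))
          clash <- quiet_seqlevels(
            any(IRanges::overlapsAny(cand, genes, ignore.strand = TRUE)) ||
            any(IRanges::overlapsAny(cand, placed_free, ignore.strand = TRUE)))
          if (!clash) {
            cchrom[i] <- ch; cstart[i] <- st; placed <- TRUE
            placed_free <- quiet_seqlevels(c(placed_free, cand))
            break
          }
        }
        if (!placed) stopf("requested copies exceed placeable intergenic space")
      }
    }
    div <- vapply(seq_len(total), function(i) {
      r <- if (tier_of_copy[i] == "young") config$div_young else config$div_old
      runif(1, r[1], r[2])
    }, numeric(1))
    copies <- GenomicRanges::GRanges(
      cchrom, IRanges::IRanges(cstart, width = clen),
      strand = sample(c("+", "-"), total, replace = TRUE),
      subfamily = sub_of_copy,
      class_family = "LTR/ERV1",
      divergence_pct = round(div, 1),
      copy_id = sprintf("copy_%06d", seq_len(total)),
      genic = genic
    )
    samples <- sim_samples(config)

    rmsk_path <- file.path(dir, "annotation.out")
    write_repeatmasker(copies, rmsk_path)
    gtf_path <- file.path(dir, "genes.gtf")
    write_sim_gtf(genes, gtf_path)
    list(rmsk_out = rmsk_path, gtf = gtf_path,
         copies = copies, genes = genes,
         truth = truth, samples = samples, config = config)
  })
}

# GTF writer for simulated genes: one gene plus one identical exon per
# record (single-exon gene models are all the intergenic mask needs).
write_sim_gtf <- function(genes, path) {
  fmt <- function(type) sprintf(
    '%s\tervsim\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    as.character(GenomicRanges::seqnames(genes)), type,
    GenomicRanges::start(genes), GenomicRanges::end(genes),
    as.character(GenomicRanges::strand(genes)), genes$gene_id)
  lines <- as.vector(rbind(fmt("gene"), fmt("exon")))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a subfamily count matrix with planted upregulation
#'
#' Count-level shortcut for testing differential expression and the age
#' comparison without reads: `count[f, s] ~ NegBin(mean = baseline_f *
#' FC_f(s) * sizefactor_s, dispersion)` where `FC_f(s)` is the planted
#' fold-change for planted subfamilies in case samples and 1 otherwise.
#' Baselines are log-uniform over `baseline_mean`; size factors are
#' log-normal centred on 1. When no annotation truth is supplied, a
#' standalone truth is drawn: per-subfamily mean divergence uniform in
#' the tier range and a nominal merged length.
#'
#' @param config a [sim_config()] object.
#' @param truth optional truth table from [simulate_annotation()].
#' @param seed_offset internal stream separator so that annotation and
#'   counts drawn from one config are independent.
#' @return list with `counts` (subfamilies x samples integer matrix),
#'   `samples` sheet, `truth` (with `mean_divergence_pct`,
#'   `merged_length_bp`, `baseline_mean` columns) and `size_factors`.
#' @export
simulate_counts <- function(config, truth = NULL, seed_offset = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + seed_offset, {
    if (is.null(truth)) {
      truth <- sim_subfamily_truth(config)
      truth$mean_divergence_pct <- vapply(seq_len(nrow(truth)), function(i) {
        r <- if (truth$age_tier[i] == "young") config$div_young else config$div_old
        runif(1, r[1], r[2])
      }, numeric(1))
      truth$merged_length_bp <- round(runif(nrow(truth),
                                            config$feature_length_bp[1],
                                            config$feature_length_bp[2]))
    }
    samples <- sim_samples(config)
    nf <- nrow(truth); ns <- nrow(samples)
    baseline <- exp(runif(nf, log(config$baseline_mean[1]),
                          log(config$baseline_mean[2])))
    truth$baseline_mean <- baseline
    sf <- exp(rnorm(ns, 0, config$size_factor_sdlog))
    is_case <- samples$condition != "control"
    fc <- outer(truth$true_fold_change, is_case,
                function(f, cc) ifelse(cc, f, 1))
    mu <- baseline * fc * rep(sf, each = nf)
    counts <- matrix(
      rnbinom(nf * ns, mu = mu, size = 1 / config$dispersion),
      nrow = nf,
      dimnames = list(truth$subfamily, samples$sample_id)
    )
    list(counts = counts, samples = samples, truth = truth, size_factors = sf)
  })
}

#' Simulate per-sample SAM alignments realising a target count matrix
#'
#' For every target count, writes one properly-paired fragment wholly
#' inside a randomly chosen intergenic copy of the subfamily, antisense
#' to the copy strand so that reverse-stranded counting assigns it.
#' Optional spike-ins per sample exercise each filter: low-MAPQ pairs,
#' duplicate-flagged pairs, sense-strand (wrong-strand) pairs, and
#' fragments straddling copies of two different subfamilies (expected
#' ambiguous). Each spike-in is recorded with its expected assignment
#' outcome.
#'
#' @param ann result of [simulate_annotation()].
#' @param target_counts subfamilies x samples integer matrix; row names
#'   must be subfamily names present in the annotation.
#' @param config a [sim_config()] object (fragment geometry, seed).
#' @param dir output directory for the SAM files.
#' @param spikeins named integer vector with any of `low_mapq`,
#'   `duplicate`, `wrong_strand`, `cross_subfamily` (per sample).
#' @return list with `sam_paths` (named by sample), and `spikein_truth`
#'   (data frame of spiked fragments and expected outcomes).
#' @export
simulate_reads <- function(ann, target_counts, config,
                           dir = tempfile("ervreads"),
                           spikeins = c(low_mapq = 0L, duplicate = 0L,
                                        wrong_strand = 0L,
                                        cross_subfamily = 0L)) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spk <- c(low_mapq = 0L, duplicate = 0L, wrong_strand = 0L,
           cross_subfamily = 0L)
  spk[names(spikeins)] <- as.integer(spikeins)
  copies <- filter_intergenic(ann$copies, ann$genes)
  rl <- config$read_length_bp
  min_frag <- 2L * rl
  samples <- colnames(target_counts)
  chrom_len <- config$chromosome_length_bp

  with_seed(config$seed + 2L, {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:chrSIM%d\tLN:%d",
                        seq_len(config$n_chromosomes), as.integer(chrom_len)))
    truth_rows <- list()
    sam_paths <- character(0)
    serial <- 0L

    frag_len <- function(maxw) {
      fl <- round(rnorm(1, config$insert_mean_bp, config$insert_sd_bp))
      max(min_frag, min(fl, maxw))
    }
    pair_records <- function(qname, chrom, fstart, flen, frag_strand,
                             mapq = 60L, dup = FALSE) {
      fend <- fstart + flen - 1L
      p_left <- fstart
      p_right <- fend - rl + 1L
      dupbit <- if (dup) 1024L else 0L
      if (frag_strand == "-") {
        f1 <- 83L + dupbit; f2 <- 163L + dupbit   # read1 reverse (right)
        r1_pos <- p_right; r2_pos <- p_left
      } else {
        f1 <- 99L + dupbit; f2 <- 147L + dupbit   # read1 forward (left)
        r1_pos <- p_left; r2_pos <- p_right
      }
      seq <- strrep("A", rl); qual <- strrep("I", rl)
      tlen1 <- if (r1_pos <= r2_pos) flen else -flen
      c(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
                qname, f1, chrom, r1_pos, mapq, rl, r2_pos, tlen1, seq, qual),
        sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
                qname, f2, chrom, r2_pos, mapq, rl, r1_pos, -tlen1, seq, qual))
    }
    place_in_copy <- function(copy, antisense = TRUE) {
      w <- GenomicRanges::width(copy)
      if (w < min_frag) {
        stopf("copy %s is shorter (%d bp) than the minimum fragment (%d bp)",
              copy$copy_id, w, min_frag)
      }
      fl <- frag_len(w)
      st <- GenomicRanges::start(copy) +
        sample.int(w - fl + 1L, 1L) - 1L
      cs <- as.character(GenomicRanges::strand(copy))
      fs <- if (antisense) (if (cs == "+") "-" else "+") else cs
      list(chrom = as.character(GenomicRanges::seqnames(copy)),
           start = st, len = fl, strand = fs)
    }

    for (s in samples) {
      recs <- character(0)
      for (sub in rownames(target_counts)) {
        k <- target_counts[sub, s]
        if (k == 0) next
        cand <- copies[copies$subfamily == sub &
                         GenomicRanges::width(copies) >= min_frag]
        if (!length(cand)) {
          short <- copies[copies$subfamily == sub]
          if (length(short)) {
            stopf("copy %s is shorter (%d bp) than the minimum fragment (%d bp)",
                  short$copy_id[1], GenomicRanges::width(short)[1], min_frag)
          }
          stopf("subfamily %s has no intergenic copy to place reads in", sub)
        }
        for (j in seq_len(k)) {
          serial <- serial + 1L
          cp <- cand[sample.int(length(cand), 1L)]
          pl <- place_in_copy(cp)
          recs <- c(recs, pair_records(sprintf("frag%07d", serial),
                                       pl$chrom, pl$start, pl$len, pl$strand))
        }
      }
      # spike-ins with known expected outcomes
      big <- copies[GenomicRanges::width(copies) >= min_frag]
      spike_one <- function(kind) {
        serial <<- serial + 1L
        qn <- sprintf("spike%07d", serial)
        if (kind == "cross_subfamily") {
          pair <- find_cross_pair(big)
          if (is.null(pair)) stopf("no copy pair available for cross-subfamily spike-in")
          a <- pair$a; b <- pair$b
          fstart <- GenomicRanges::end(a) - rl + 1L
          fend <- GenomicRanges::start(b) + rl - 1L
          flen <- fend - fstart + 1L
          cs <- as.character(GenomicRanges::strand(a))
          fs <- if (cs == "+") "-" else "+"
          recs <<- c(recs, pair_records(qn, as.character(GenomicRanges::seqnames(a)),
                                        fstart, flen, fs))
          return(data.frame(sample_id = s, qname = qn, kind = kind,
                            expected = "ambiguous"))
        }
        cp <- big[sample.int(length(big), 1L)]
        pl <- place_in_copy(cp, antisense = (kind != "wrong_strand"))
        mapq <- if (kind == "low_mapq") 5L else 60L
        dup <- kind == "duplicate"
        recs <<- c(recs, pair_records(qn, pl$chrom, pl$start, pl$len,
                                      pl$strand, mapq = mapq, dup = dup))
        expected <- switch(kind, low_mapq = "filtered",
                           duplicate = "filtered",
                           wrong_strand = "no_feature")
        data.frame(sample_id = s, qname = qn, kind = kind, expected = expected)
      }
      for (kind in names(spk)) {
        for (j in seq_len(spk[[kind]])) {
          truth_rows[[length(truth_rows) + 1L]] <- spike_one(kind)
        }
      }
      path <- file.path(dir, paste0(s, ".sam"))
      writeLines(c(header, recs), path)
      sam_paths[s] <- path
    }
    list(sam_paths = sam_paths,
         spikein_truth = if (length(truth_rows)) do.call(rbind, truth_rows)
                         else NULL)
  })
}

# First pair of same-chromosome, same-strand copies from two different
# subfamilies, ordered left-to-right and non-overlapping.
find_cross_pair <- function(copies) {
  if (length(copies) < 2) return(NULL)
  ord <- order(as.character(GenomicRanges::seqnames(copies)),
               GenomicRanges::start(copies))
  cp <- copies[ord]
  for (i in seq_len(length(cp) - 1L)) {
    for (j in (i + 1L):length(cp)) {
      same_chr <- as.character(GenomicRanges::seqnames(cp[i])) ==
        as.character(GenomicRanges::seqnames(cp[j]))
      if (!same_chr) break
      ok <- cp$subfamily[i] != cp$subfamily[j] &&
        as.character(GenomicRanges::strand(cp[i])) ==
          as.character(GenomicRanges::strand(cp[j])) &&
        GenomicRanges::start(cp[j]) > GenomicRanges::end(cp[i])
      if (ok) return(list(a = cp[i], b = cp[j]))
    }
  }
  NULL
}
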