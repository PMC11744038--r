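# In-code fixture builders shared across test files.

toy_copies <- function(starts, ends, strand = "+", subfamily = "SUBF1",
                       chrom = "chr1", div = 1.0,
                       class_family = "LTR/ERV1") {
  n <- length(starts)
  GenomicRanges::GRanges(
    rep(chrom, length.out = n),
    IRanges::IRanges(starts, ends),
    strand = rep(strand, length.out = n),
    subfamily = rep(subfamily, length.out = n),
    class_family = rep(class_family, length.out = n),
    divergence_pct = rep(div, length.out = n),
    copy_id = sprintf("copy_%06d", seq_len(n))
  )
}

toy_genes <- function(starts, ends, chrom = "chr1", strand = "+") {
  n <- length(starts)
  GenomicRanges::GRanges(
    rep(chrom, length.out = n),
    IRanges::IRanges(starts, ends),
    strand = rep(strand, length.out = n),
    gene_id = sprintf("GENE%04d", seq_len(n)),
    feature_type = "gene"
  )
}

toy_fragments <- function(starts, ends, strand = "+", chrom = "chr1") {
  n <- length(starts)
  GenomicRanges::GRanges(
    rep(chrom, length.out = n),
    IRanges::IRanges(starts, ends),
    strand = rep(strand, length.out = n),
    qname = sprintf("frag%05d", seq_len(n))
  )
}

# Brute-force per-fragment x per-copy overlap scan: the independent
# counting oracle (no interval index).
brute_force_count <- function(fragments, features, strandedness = "reverse") {
  subs <- sort(unique(features$subfamily))
  counts <- stats::setNames(integer(length(subs)), subs)
  ambiguous <- 0L; no_feature <- 0L
  fc <- as.character(GenomicRanges::seqnames(fragments))
  fs <- as.character(GenomicRanges::strand(fragments))
  f1 <- GenomicRanges::start(fragments); f2 <- GenomicRanges::end(fragments)
  cc <- as.character(GenomicRanges::seqnames(features))
  cs <- as.character(GenomicRanges::strand(features))
  c1 <- GenomicRanges::start(features); c2 <- GenomicRanges::end(features)
  for (i in seq_along(fragments)) {
    hit_subs <- character(0)
    for (j in seq_along(features)) {
      if (fc[i] != cc[j]) next
      if (f1[i] > c2[j] || f2[i] < c1[j]) next
      ok <- switch(strandedness,
        reverse = (fs[i] == "+" && cs[j] == "-") ||
                  (fs[i] == "-" && cs[j] == "+"),
        forward = fs[i] == cs[j],
        unstranded = TRUE)
      if (ok) hit_subs <- union(hit_subs, features$subfamily[j])
    }
    if (length(hit_subs) == 1L) {
      counts[hit_subs] <- counts[hit_subs] + 1L
    } else if (length(hit_subs) > 1L) {
      ambiguous <- ambiguous + 1L
    } else {
      no_feature <- no_feature + 1L
    }
  }
  list(counts = counts, assigned_total = sum(counts),
       ambiguous = ambiguous, no_feature = no_feature)
}

# Random fragment/copy fixture for oracle-equivalence checks.
random_count_fixture <- function(n_frags, n_copies, n_subs = 8,
                                 chroms = c("chrA", "chrB"), len = 50000) {
  features <- GenomicRanges::GRanges(
    sample(chroms, n_copies, replace = TRUE),
    IRanges::IRanges(start = sample.int(len - 500, n_copies, replace = TRUE),
                     width = sample(100:500, n_copies, replace = TRUE)),
    strand = sample(c("+", "-"), n_copies, replace = TRUE),
    subfamily = sample(sprintf("SUBF%02d", seq_len(n_subs)), n_copies,
                       replace = TRUE)
  )
  fragments <- GenomicRanges::GRanges(
    sample(chroms, n_frags, replace = TRUE),
    IRanges::IRanges(start = sample.int(len - 400, n_frags, replace = TRUE),
                     width = sample(150:400, n_frags, replace = TRUE)),
    strand = sample(c("+", "-"), n_frags, replace = TRUE),
    qname = sprintf("f%06d", seq_len(n_frags))
  )
  list(fragments = fragments, features = features)
}
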