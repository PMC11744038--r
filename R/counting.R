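#' Count fragments over subfamily meta-features
#'
#' All copies of one subfamily form a single meta-feature. A fragment is
#' assigned to a subfamily when it overlaps at least one base of at least
#' one copy of that subfamily and is strand-compatible (reverse-stranded
#' mode: fragment strand opposite the copy strand). Strand compatibility
#' is applied before the ambiguity check, so a fragment overlapping one
#' compatible and one incompatible subfamily is assigned. A fragment
#' compatible with two or more distinct subfamilies is ambiguous and
#' dropped; overlapping several copies of a single subfamily counts once.
#'
#' @param fragments `GRanges` from [load_fragments()].
#' @param features `GRanges` of ERV copies (or exon meta-feature parts)
#'   with a `subfamily` grouping column.
#' @param params a [counting_params()] object.
#' @return list with `counts` (named integer vector over all subfamilies
#'   present in `features`), `assigned_total`, `ambiguous`, `no_feature`
#'   and `n_fragments`. The three tallies plus the assigned total always
#'   sum to `n_fragments`.
#' @export
count_fragments <- function(fragments, features, params = counting_params()) {
  stopifnot(inherits(params, "counting_params"))
  subs <- sort(unique(features$subfamily))
  n <- length(fragments)
  if (!length(features)) {
    warning("empty feature set: all counts zero")
    return(list(counts = integer(0), assigned_total = 0L,
                ambiguous = 0L, no_feature = n, n_fragments = n))
  }
  hits <- quiet_seqlevels(
    GenomicRanges::findOverlaps(fragments, features, ignore.strand = TRUE))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  fs <- as.character(GenomicRanges::strand(fragments))[q]
  cs <- as.character(GenomicRanges::strand(features))[s]
  compat <- switch(params$strandedness,
    reverse = (fs == "+" & cs == "-") | (fs == "-" & cs == "+"),
    forward = fs == cs & fs %in% c("+", "-"),
    unstranded = rep(TRUE, length(q))
  )
  q <- q[compat]
  sub_hit <- features$subfamily[s[compat]]
  pair <- !duplicated(paste(q, sub_hit, sep = "\r"))
  q <- q[pair]
  sub_hit <- sub_hit[pair]
  nsub <- tabulate(q, nbins = n)
  assigned <- which(nsub == 1L)
  ambiguous <- sum(nsub > 1L)
  keep <- q %in% assigned
  counts <- table(factor(sub_hit[keep], levels = subs))
  list(
    counts = stats::setNames(as.integer(counts), subs),
    assigned_total = length(assigned),
    ambiguous = as.integer(ambiguous),
    no_feature = as.integer(n - length(assigned) - ambiguous),
    n_fragments = n
  )
}

#' Build a count matrix over samples
#'
#' Runs [load_fragments()] and [count_fragments()] per sample and binds
#' the per-sample count vectors into a features-by-samples matrix.
#'
#' @param alignments named character vector of SAM/BAM paths; names are
#'   sample ids.
#' @param features `GRanges` with a `subfamily` column.
#' @param params a [counting_params()] object.
#' @return list with `counts` (integer matrix), `assigned_totals` (named
#'   vector) and `summary` (per-sample assignment tallies).
#' @export
count_samples <- function(alignments, features, params = counting_params()) {
  stopifnot(length(names(alignments)) == length(alignments))
  per <- lapply(alignments, function(p) {
    count_fragments(load_fragments(p, params), features, params)
  })
  counts <- vapply(per, `[[`, integer(length(per[[1]]$counts)), "counts")
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  rownames(counts) <- names(per[[1]]$counts)
  colnames(counts) <- names(alignments)
  summary <- data.frame(
    sample_id = names(alignments),
    n_fragments = vapply(per, `[[`, integer(1), "n_fragments"),
    assigned = vapply(per, `[[`, integer(1), "assigned_total"),
    ambiguous = vapply(per, `[[`, integer(1), "ambiguous"),
    no_feature = vapply(per, `[[`, integer(1), "no_feature"),
    row.names = NULL
  )
  list(counts = counts,
       assigned_totals = stats::setNames(summary$assigned, summary$sample_id),
       summary = summary)
}

#' Fragments per kilobase per million assigned fragments (FPKM)
#'
#' `fpkm[f, s] = count[f, s] * 1e9 / (length_bp[f] * total[s])`. The
#' feature length is the merged (union) intergenic copy length per
#' subfamily; the per-sample denominator is by default the total of
#' fragments assigned across the counted annotation, configurable to any
#' other total (e.g. total filtered fragments) by passing it in.
#'
#' @param counts features-by-samples count matrix (or vector).
#' @param lengths_bp per-feature length in bp, in row order.
#' @param totals per-sample assigned fragment totals, in column order.
#' @return numeric matrix of FPKM values with the same dimnames.
#' @export
compute_fpkm <- function(counts, lengths_bp, totals) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths_bp) == nrow(counts),
            length(totals) == ncol(counts))
  if (any(totals <= 0)) {
    stopf("sample(s) with zero assigned fragments: %s",
          paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  bad <- which(lengths_bp <= 0 & rowSums(counts) > 0)
  if (length(bad)) {
    stopf("feature(s) with nonzero counts but non-positive length: %s",
          paste(rownames(counts)[bad], collapse = ", "))
  }
  len <- lengths_bp
  len[len <= 0] <- NA_real_
  fpkm <- sweep(counts / len, 2L, totals, `/`) * 1e9
  fpkm[is.na(fpkm) & counts == 0] <- 0
  fpkm
}
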