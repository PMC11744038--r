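#' Counting parameter set
#'
#' Defaults mirror stranded, filtered fragment counting of bulk RNA-seq:
#' uniquely mapped is operationalized as primary alignments with
#' MAPQ >= 20, duplicates are ignored, and the library is reverse-stranded
#' (a fragment is compatible with a feature on the opposite strand).
#'
#' @param min_mapq minimum mapping quality (default 20).
#' @param primary_only drop secondary and supplementary records.
#' @param ignore_duplicates drop duplicate-flagged records.
#' @param strandedness `"reverse"` (default), `"forward"` or
#'   `"unstranded"`.
#' @param ambiguous_policy only `"drop"` is implemented: a fragment
#'   compatible with more than one subfamily is left unassigned.
#' @return a `counting_params` list.
#' @export
counting_params <- function(min_mapq = 20L, primary_only = TRUE,
                            ignore_duplicates = TRUE,
                            strandedness = c("reverse", "forward", "unstranded"),
                            ambiguous_policy = "drop") {
  strandedness <- match.arg(strandedness)
  stopifnot(is_count(min_mapq), ambiguous_policy == "drop")
  structure(list(min_mapq = as.integer(min_mapq),
                 primary_only = isTRUE(primary_only),
                 ignore_duplicates = isTRUE(ignore_duplicates),
                 strandedness = strandedness,
                 ambiguous_policy = ambiguous_policy),
            class = "counting_params")
}

#' Load aligned fragments from a SAM or BAM file
#'
#' Reads alignments, applies the record-level filters (mapped, primary
#' when `primary_only`, non-duplicate when `ignore_duplicates`,
#' `MAPQ >= min_mapq`) and collapses the surviving records of each
#' template to one fragment: for a pair on one chromosome the fragment is
#' the template span from the leftmost to the rightmost aligned base; an
#' orphaned mate yields a fragment covering just that read, counted once.
#' The fragment strand is the strand of read 1 (or of the single read).
#'
#' @param path SAM (text) or BAM file.
#' @param params a [counting_params()] object.
#' @return `GRanges` of fragments (one per template) with a `qname`
#'   metadata column; strand holds the inferred fragment strand.
#' @export
load_fragments <- function(path, params = counting_params()) {
  stopifnot(inherits(params, "counting_params"))
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    )
  )
  mc <- S4Vectors::mcols(ga)
  flag <- mc$flag
  keep <- rep(TRUE, length(ga))
  if (params$primary_only) {
    keep <- keep & bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  }
  if (params$ignore_duplicates) keep <- keep & bitwAnd(flag, 1024L) == 0L
  mapq <- mc$mapq
  mapq[is.na(mapq)] <- 0L
  keep <- keep & mapq >= params$min_mapq
  ga <- ga[keep]
  if (!length(ga)) {
    return(GenomicRanges::GRanges(qname = character()))
  }
  df <- data.frame(
    qname = S4Vectors::mcols(ga)$qname,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga),
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    first = bitwAnd(S4Vectors::mcols(ga)$flag, 64L) != 0L |
      bitwAnd(S4Vectors::mcols(ga)$flag, 1L) == 0L,
    stringsAsFactors = FALSE
  )
  # one fragment per (template, chromosome); mates split across
  # chromosomes are treated as orphans on each
  key <- paste(df$qname, df$chrom, sep = "\r")
  grp <- match(key, unique(key))
  ord <- order(grp)
  df <- df[ord, ]
  grp <- grp[ord]
  g <- factor(grp, levels = unique(grp))
  frag_start <- tapply(df$start, g, min)
  frag_end <- tapply(df$end, g, max)
  # strand of read 1 where present, else strand of the first record seen
  strand_src <- tapply(seq_len(nrow(df)), g, function(i) {
    f <- i[df$first[i]]
    if (length(f)) f[1L] else i[1L]
  })
  u <- !duplicated(grp)
  GenomicRanges::GRanges(
    seqnames = df$chrom[u],
    ranges = IRanges::IRanges(start = as.integer(frag_start),
                              end = as.integer(frag_end)),
    strand = df$strand[strand_src],
    qname = df$qname[u]
  )
}
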