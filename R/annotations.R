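#' Default ERV class/family prefixes
#'
#' ERV membership is decided by RepeatMasker class/family prefix. The
#' default keeps the LTR retroviral families (ERV1, ERVK, ERVL,
#' ERVL-MaLR) and any class/family string beginning with `LTR/ERV`. The
#' exact subfamily roster depends on the RepeatMasker release, so it is a
#' configurable pattern set rather than a hard-coded list.
#'
#' @return character vector of prefixes.
#' @export
erv_default_classes <- function() {
  c("LTR/ERV1", "LTR/ERVK", "LTR/ERVL", "LTR/ERVL-MaLR", "LTR/ERV")
}

#' Select ERV copies from a repeat annotation
#'
#' @param repeats `GRanges` from [read_repeatmasker()].
#' @param classes character vector of class/family prefixes; a record is
#'   kept when its `class_family` starts with any of them.
#' @return the matching subset, order preserved.
#' @export
select_erv_copies <- function(repeats, classes = erv_default_classes()) {
  cf <- repeats$class_family
  keep <- Reduce(`|`, lapply(classes, function(p) startsWith(cf, p)),
                 accumulate = FALSE, init = logical(length(cf)))
  repeats[keep]
}

#' Restrict ERV copies to intergenic instances
#'
#' A copy is removed when it overlaps any annotated gene body by at least
#' one base on either strand (strand-blind, any-overlap rule). Intergenic
#' restriction attributes the quantified transcription to the repeat
#' itself rather than to a host gene.
#'
#' @param copies `GRanges` of ERV copies.
#' @param genes `GRanges` from [read_gene_features()]; only
#'   `feature_type == "gene"` intervals are used as the mask.
#' @return the intergenic subset of `copies`, unmodified.
#' @export
filter_intergenic <- function(copies, genes) {
  gene_bodies <- genes[genes$feature_type == "gene"]
  if (!length(gene_bodies)) return(copies)
  hit <- quiet_seqlevels(
    IRanges::overlapsAny(copies, gene_bodies, ignore.strand = TRUE))
  copies[!hit]
}

#' Summarize ERV subfamilies over their intergenic copies
#'
#' Per subfamily: total and intergenic copy counts, the merged
#' (union) length of the intergenic copies — overlapping intervals are
#' merged before summing so shared bases are not double-counted — and the
#' mean RepeatMasker divergence over intergenic copies. Mean divergence is
#' the subfamily's evolutionary-age proxy: lower divergence means a
#' younger insertion. The default is the unweighted mean over copies;
#' `weighted = TRUE` weights each copy by its length.
#'
#' Subfamilies with zero intergenic copies are flagged `usable = FALSE`
#' (their divergence and length are `NA`) and are excluded from
#' expression quantification downstream.
#'
#' @param intergenic `GRanges` of intergenic ERV copies.
#' @param all_copies `GRanges` of all ERV copies (for total counts);
#'   defaults to `intergenic`.
#' @param weighted length-weight the divergence mean.
#' @return data frame with one row per subfamily, ordered by name.
#' @export
summarize_subfamilies <- function(intergenic, all_copies = intergenic,
                                  weighted = FALSE) {
  subs <- sort(unique(c(all_copies$subfamily, intergenic$subfamily)))
  n_total <- table(factor(all_copies$subfamily, levels = subs))
  n_inter <- table(factor(intergenic$subfamily, levels = subs))

  merged_len <- rep(NA_real_, length(subs))
  mean_div <- rep(NA_real_, length(subs))
  if (length(intergenic)) {
    by_sub <- S4Vectors::split(intergenic, intergenic$subfamily)
    ml <- vapply(by_sub, function(g)
      sum(GenomicRanges::width(GenomicRanges::reduce(g, ignore.strand = TRUE))),
      numeric(1))
    md <- vapply(by_sub, function(g) {
      if (weighted) {
        stats::weighted.mean(g$divergence_pct, GenomicRanges::width(g))
      } else {
        mean(g$divergence_pct)
      }
    }, numeric(1))
    idx <- match(names(by_sub), subs)
    merged_len[idx] <- ml
    mean_div[idx] <- md
  }
  out <- data.frame(
    subfamily = subs,
    n_copies_total = as.integer(n_total),
    n_copies_intergenic = as.integer(n_inter),
    merged_length_bp = merged_len,
    mean_divergence_pct = mean_div,
    usable = as.integer(n_inter) > 0L,
    stringsAsFactors = FALSE
  )
  if (any(!out$usable)) {
    message(sum(!out$usable),
            " subfamily(ies) with no intergenic copy flagged unusable")
  }
  out
}
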