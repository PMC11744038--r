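#' Compare divergence of upregulated subfamilies against the remainder
#'
#' Tests whether the subfamilies called upregulated are evolutionarily
#' younger (lower mean RepeatMasker divergence) than the remaining
#' tested subfamilies, with a two-tailed Mann-Whitney U test on the two
#' divergence-value groups. The remainder is by default the tested
#' (expression-eligible) subfamilies not called up, not the full genomic
#' roster; pass `roster` to compare against a wider set.
#'
#' @param de an `erv_de` result from [call_differential()].
#' @param summaries subfamily summary data frame from
#'   [summarize_subfamilies()] (needs `subfamily` and
#'   `mean_divergence_pct`).
#' @param alpha significance level for the direction call (default 0.05).
#' @param roster optional character vector of subfamily names to use as
#'   the comparison universe instead of the tested set.
#' @return an `erv_age_test` list: group sizes, medians, `u_statistic`,
#'   `p_two_sided`, `direction` (`"younger"`, `"older"` or `"none"`) and
#'   the per-group divergence values. With zero upregulated subfamilies
#'   the result is flagged degenerate (`p_two_sided = NA`,
#'   `direction = "none"`), not an error.
#' @export
compare_divergence <- function(de, summaries, alpha = 0.05, roster = NULL) {
  stopifnot(inherits(de, "data.frame"), "status" %in% names(de))
  up <- de$feature_id[de$status == "up"]
  universe <- if (is.null(roster)) de$feature_id else unique(roster)
  rest <- setdiff(universe, up)
  div <- summaries$mean_divergence_pct[match(c(up, rest), summaries$subfamily)]
  if (anyNA(div)) {
    missing <- c(up, rest)[is.na(div)]
    stopf("no divergence summary for subfamily(ies): %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  div_up <- div[seq_along(up)]
  div_rest <- div[seq_along(rest) + length(up)]
  if (!length(up)) {
    res <- list(n_upregulated = 0L, n_remainder = length(rest),
                median_div_upregulated = NA_real_,
                median_div_remainder = median(div_rest),
                u_statistic = NA_real_, p_two_sided = NA_real_,
                direction = "none", degenerate = TRUE,
                divergence_up = numeric(0), divergence_remainder = div_rest)
    return(structure(res, class = "erv_age_test"))
  }
  mw <- mann_whitney_u(div_up, div_rest)
  med_up <- median(div_up)
  med_rest <- median(div_rest)
  direction <- "none"
  if (!is.na(mw$p_value) && mw$p_value < alpha) {
    if (med_up < med_rest) direction <- "younger"
    if (med_up > med_rest) direction <- "older"
  }
  structure(list(
    n_upregulated = length(up), n_remainder = length(rest),
    median_div_upregulated = med_up, median_div_remainder = med_rest,
    u_statistic = mw$u_statistic, p_two_sided = mw$p_value,
    mw_method = mw$method, direction = direction, degenerate = FALSE,
    divergence_up = div_up, divergence_remainder = div_rest
  ), class = "erv_age_test")
}

#' @export
print.erv_age_test <- function(x, ...) {
  cat("Divergence comparison: upregulated vs remainder\n")
  if (isTRUE(x$degenerate)) {
    cat(sprintf("  no upregulated subfamilies (remainder n = %d); test not run\n",
                x$n_remainder))
    return(invisible(x))
  }
  cat(sprintf("  upregulated: n = %d, median div = %.2f%%\n",
              x$n_upregulated, x$median_div_upregulated))
  cat(sprintf("  remainder:   n = %d, median div = %.2f%%\n",
              x$n_remainder, x$median_div_remainder))
  cat(sprintf("  Mann-Whitney U = %g, two-sided p = %.3g (%s) -> %s\n",
              x$u_statistic, x$p_two_sided, x$mw_method, x$direction))
  invisible(x)
}

#' Long-format divergence table for box plots
#'
#' @param x an `erv_age_test` object.
#' @return data frame with columns `group` and `divergence_pct`.
#' @export
age_test_long <- function(x) {
  stopifnot(inherits(x, "erv_age_test"))
  data.frame(
    group = rep(c("upregulated", "remainder"),
                c(length(x$divergence_up), length(x$divergence_remainder))),
    divergence_pct = c(x$divergence_up, x$divergence_remainder)
  )
}

#' Intersect upregulated subfamily sets across tissues
#'
#' Exact set algebra over named per-tissue sets of upregulated
#' subfamilies: a per-subfamily membership table (rows in lexicographic
#' order) plus intersection counts for every combination of two or more
#' tissues.
#'
#' @param sets named list (length >= 2) of character vectors; names are
#'   tissue labels and must be unique.
#' @return list with `membership` (data frame: subfamily, one logical
#'   column per tissue, `n_tissues`) and `intersections` (data frame:
#'   `tissues` label, `n`, comma-separated `subfamilies`).
#' @export
intersect_upregulated <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  labs <- names(sets)
  if (is.null(labs) || any(!nzchar(labs))) stopf("all sets must be named")
  if (anyDuplicated(labs)) stopf("duplicate tissue names")
  sets <- lapply(sets, unique)
  all_sub <- sort(unique(unlist(sets)))
  memb <- data.frame(subfamily = all_sub, stringsAsFactors = FALSE)
  for (l in labs) memb[[l]] <- all_sub %in% sets[[l]]
  memb$n_tissues <- rowSums(as.matrix(memb[labs]))
  combos <- list()
  for (k in 2:length(labs)) {
    cmb <- utils::combn(labs, k, simplify = FALSE)
    for (cc in cmb) {
      inter <- Reduce(intersect, sets[cc])
      inter <- sort(inter)
      combos[[length(combos) + 1L]] <- data.frame(
        tissues = paste(cc, collapse = "&"),
        n = length(inter),
        subfamilies = paste(inter, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  list(membership = memb, intersections = do.call(rbind, combos))
}
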