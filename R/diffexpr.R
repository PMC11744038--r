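#' Differential-expression thresholds
#'
#' Calling a subfamily up (or down) requires BOTH a Holm-adjusted
#' p-value below `alpha` and a fold-change beyond `min_fold_change`: the
#' two volcano-plot threshold lines are intersected, matching standard
#' volcano semantics. The pseudocount keeps the log2 fold-change finite
#' when one group mean is zero; it enters fold-changes only, never the
#' t-test.
#'
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param min_fold_change fold-change threshold, > 1 (default 2).
#' @param pseudocount_fpkm pseudocount added to both group means for the
#'   fold-change ratio (default 0.01 FPKM).
#' @param adjust `"holm"` (default) or `"none"`.
#' @param log_transform test `log2(FPKM + pseudocount)` instead of raw
#'   FPKM (default `FALSE`; fold-changes are always computed from the
#'   raw FPKM group means).
#' @return a `de_thresholds` list.
#' @export
de_thresholds <- function(alpha = 0.05, min_fold_change = 2,
                          pseudocount_fpkm = 0.01,
                          adjust = c("holm", "none"),
                          log_transform = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1, min_fold_change > 1, pseudocount_fpkm > 0)
  structure(list(alpha = alpha, min_fold_change = min_fold_change,
                 pseudocount_fpkm = pseudocount_fpkm, adjust = adjust,
                 log_transform = isTRUE(log_transform)),
            class = "de_thresholds")
}

de_table <- function(fpkm, idx_case, idx_control, thresholds) {
  eps <- thresholds$pseudocount_fpkm
  test_mat <- if (thresholds$log_transform) log2(fpkm + eps) else fpkm
  w <- welch_t_rows(test_mat, idx_case, idx_control)
  mean_case <- rowMeans(fpkm[, idx_case, drop = FALSE])
  mean_control <- rowMeans(fpkm[, idx_control, drop = FALSE])
  ratio <- (mean_case + eps) / (mean_control + eps)
  p_adj <- switch(thresholds$adjust,
                  holm = holm_adjust(w$p_value),
                  none = w$p_value)
  status <- rep("ns", nrow(fpkm))
  sig <- p_adj < thresholds$alpha
  status[sig & ratio > thresholds$min_fold_change] <- "up"
  status[sig & ratio < 1 / thresholds$min_fold_change] <- "down"
  data.frame(
    feature_id = rownames(fpkm),
    mean_fpkm_control = mean_control,
    mean_fpkm_case = mean_case,
    log2fc = log2(ratio),
    t_stat = w$t_stat,
    df_welch = w$df_welch,
    p_value = w$p_value,
    p_adjusted = p_adj,
    status = status,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Call differentially expressed features between two conditions
#'
#' Per feature: Welch t-test of the case samples against the control
#' samples on FPKM values, Holm step-down adjustment over all tested
#' features of the run, and a fold-change on the pseudocounted group
#' means. A feature is `up` when the adjusted p-value is below `alpha`
#' and the fold-change exceeds `min_fold_change`; `down` symmetrically;
#' otherwise `ns`. Features that are all-zero in both groups carry no
#' signal and are excluded before testing (so they do not enter the Holm
#' family).
#'
#' @param fpkm features-by-samples FPKM matrix with rownames and
#'   colnames.
#' @param condition vector over samples with values `"control"` and
#'   `"covid"` (any single non-control label is accepted as the case
#'   group).
#' @param thresholds a [de_thresholds()] object.
#' @return an `erv_de` data frame (one row per tested feature) with
#'   attributes recording the thresholds and group sizes.
#' @export
call_differential <- function(fpkm, condition, thresholds = de_thresholds()) {
  fpkm <- as.matrix(fpkm)
  stopifnot(length(condition) == ncol(fpkm))
  condition <- as.character(condition)
  if (!"control" %in% condition) stopf("no control samples in condition")
  case_lab <- setdiff(unique(condition), "control")
  if (length(case_lab) != 1L) {
    stopf("expected exactly one non-control condition, found: %s",
          paste(case_lab, collapse = ", "))
  }
  idx_control <- which(condition == "control")
  idx_case <- which(condition == case_lab)
  if (length(idx_control) < 2L || length(idx_case) < 2L) {
    stopf("each condition needs at least 2 samples")
  }
  allzero <- rowSums(fpkm[, c(idx_case, idx_control), drop = FALSE]) == 0
  if (any(allzero)) {
    message(sum(allzero), " all-zero feature(s) excluded before testing")
  }
  tested <- fpkm[!allzero, , drop = FALSE]
  out <- de_table(tested, idx_case, idx_control, thresholds)
  structure(out,
            class = c("erv_de", "data.frame"),
            thresholds = thresholds,
            contrast = c(case = case_lab, control = "control"),
            n_case = length(idx_case), n_control = length(idx_control),
            n_excluded = sum(allzero))
}

#' Compare ICU against non-ICU cases
#'
#' Severity contrast within the case samples: Welch t-test of ICU
#' against non-ICU, unadjusted by default (set `adjust = "holm"` in the
#' thresholds to change this). Healthy controls, when present in
#' `condition`, are reported alongside as a descriptive
#' `mean_fpkm_healthy` column and take no part in the test.
#'
#' @param fpkm features-by-samples FPKM matrix.
#' @param severity vector over samples with values `"icu"`, `"non_icu"`
#'   for cases and `"none"`/`NA` otherwise.
#' @param thresholds a [de_thresholds()] object; default unadjusted.
#' @param condition optional condition vector used only to locate
#'   healthy controls for the descriptive column.
#' @return an `erv_de` data frame; `case` is the ICU group.
#' @export
severity_comparison <- function(fpkm, severity,
                                thresholds = de_thresholds(adjust = "none"),
                                condition = NULL) {
  fpkm <- as.matrix(fpkm)
  stopifnot(length(severity) == ncol(fpkm))
  severity <- as.character(severity)
  idx_icu <- which(severity == "icu")
  idx_non <- which(severity == "non_icu")
  if (length(idx_icu) < 2L || length(idx_non) < 2L) {
    stopf("both severity groups need at least 2 samples (icu: %d, non_icu: %d)",
          length(idx_icu), length(idx_non))
  }
  allzero <- rowSums(fpkm[, c(idx_icu, idx_non), drop = FALSE]) == 0
  tested <- fpkm[!allzero, , drop = FALSE]
  out <- de_table(tested, idx_icu, idx_non, thresholds)
  names(out)[names(out) == "mean_fpkm_control"] <- "mean_fpkm_non_icu"
  names(out)[names(out) == "mean_fpkm_case"] <- "mean_fpkm_icu"
  if (!is.null(condition)) {
    idx_healthy <- which(as.character(condition) == "control")
    if (length(idx_healthy)) {
      out$mean_fpkm_healthy <-
        rowMeans(tested[, idx_healthy, drop = FALSE])
    }
  }
  structure(out,
            class = c("erv_de", "data.frame"),
            thresholds = thresholds,
            contrast = c(case = "icu", control = "non_icu"),
            n_case = length(idx_icu), n_control = length(idx_non),
            n_excluded = sum(allzero))
}

#' @export
print.erv_de <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("Differential expression: %s (n = %d) vs %s (n = %d)\n",
              ct[["case"]], attr(x, "n_case"),
              ct[["control"]], attr(x, "n_control")))
  th <- attr(x, "thresholds")
  cat(sprintf("  %d features tested; adjust = %s, alpha = %g, min FC = %g\n",
              nrow(x), th$adjust, th$alpha, th$min_fold_change))
  tab <- table(factor(x$status, levels = c("up", "down", "ns")))
  cat(sprintf("  up: %d  down: %d  ns: %d\n", tab["up"], tab["down"], tab["ns"]))
  invisible(x)
}

#' @method summary erv_de
#' @export
summary.erv_de <- function(object, n = 10L, ...) {
  print(object)
  o <- order(object$p_adjusted, object$p_value)
  top <- utils::head(as.data.frame(object)[o, ], n)
  cat("Top features by adjusted p-value:\n")
  print(top, digits = 4, row.names = FALSE)
  invisible(top)
}

#' Volcano plot of a differential-expression result
#'
#' @param x an `erv_de` object.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @method plot erv_de
#' @export
plot.erv_de <- function(x, ...) {
  th <- attr(x, "thresholds")
  col <- ifelse(x$status == "up", "red3",
                ifelse(x$status == "down", "blue3", "grey50"))
  lp <- -log10(pmax(x$p_adjusted, 1e-300))
  graphics::plot(x$log2fc, lp, col = col, pch = 16, cex = 0.6,
                 xlab = "log2 fold-change", ylab = "-log10 adjusted p", ...)
  graphics::abline(h = -log10(th$alpha), lty = 2)
  graphics::abline(v = c(-1, 1) * log2(th$min_fold_change), lty = 2)
  invisible(x)
}
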