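#' Study cohort sample sizes
#'
#' The eight public RNA-seq cohorts the analysis design targets, with
#' their COVID-19 and control sample counts: platelets, PBMCs, lung,
#' frontal cortex, ventral midbrain, pooled HUVECs, placenta and cardiac
#' microvascular endothelial cells. The totals (124 COVID-19, 53
#' control) are the bookkeeping anchor for cohort-structured
#' simulations.
#'
#' @return data frame with columns `cohort`, `n_covid`, `n_control`.
#' @examples
#' colSums(covid_cohort_sizes()[, -1])
#' @export
covid_cohort_sizes <- function() {
  data.frame(
    cohort = c("platelet", "pbmc", "lung", "frontal_cortex",
               "ventral_midbrain", "phuvec", "placenta", "hcmec"),
    n_covid = c(10L, 31L, 11L, 22L, 11L, 15L, 17L, 7L),
    n_control = c(5L, 16L, 3L, 10L, 3L, 5L, 4L, 7L),
    stringsAsFactors = FALSE
  )
}
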