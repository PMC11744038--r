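#' Pipeline configuration
#'
#' Collects the inputs and parameter blocks for one cohort run. Either
#' `alignments` (full SAM/BAM route) or `counts` (a count-matrix TSV or
#' matrix, the short route) must be supplied alongside the annotation
#' inputs.
#'
#' @param rmsk RepeatMasker `.out` path.
#' @param gtf gene annotation GTF path.
#' @param sample_sheet TSV path or data frame with columns `sample_id`,
#'   `condition` (`control`/`covid`), optional `cohort`, `severity`.
#' @param alignments named character vector of SAM/BAM paths (names =
#'   sample ids), or `NULL` for the count route.
#' @param counts count-matrix TSV path (first column feature id) or a
#'   features-by-samples matrix, or `NULL` for the alignment route.
#' @param gene_list optional path to a plain-text gene-id list (one per
#'   line) defining the innate-immune panel counted alongside the ERVs.
#' @param counting a [counting_params()] block.
#' @param thresholds a [de_thresholds()] block.
#' @param erv_classes ERV class/family prefixes.
#' @param weighted_divergence length-weight the subfamily divergence
#'   mean.
#' @param alpha_age significance level of the divergence comparison.
#' @param seed seed echoed into outputs (the analysis itself is
#'   deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(rmsk, gtf, sample_sheet,
                            alignments = NULL, counts = NULL,
                            gene_list = NULL,
                            counting = counting_params(),
                            thresholds = de_thresholds(),
                            erv_classes = erv_default_classes(),
                            weighted_divergence = FALSE,
                            alpha_age = 0.05, seed = 1L) {
  if (is.null(alignments) && is.null(counts)) {
    stopf("either alignments or a count matrix must be supplied")
  }
  structure(list(rmsk = rmsk, gtf = gtf, sample_sheet = sample_sheet,
                 alignments = alignments, counts = counts,
                 gene_list = gene_list, counting = counting,
                 thresholds = thresholds, erv_classes = erv_classes,
                 weighted_divergence = weighted_divergence,
                 alpha_age = alpha_age, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments;
#' `counting` and `thresholds` sub-blocks onto [counting_params()] and
#' [de_thresholds()].
#'
#' @param path YAML file.
#' @return a `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cnt <- do.call(counting_params, as.list(y$counting %||% list()))
  thr <- do.call(de_thresholds, as.list(y$thresholds %||% list()))
  al <- y$alignments
  if (!is.null(al)) al <- unlist(al)
  pipeline_config(
    rmsk = y$rmsk, gtf = y$gtf, sample_sheet = y$sample_sheet,
    alignments = al, counts = y$counts, gene_list = y$gene_list,
    counting = cnt, thresholds = thr,
    erv_classes = y$erv_classes %||% erv_default_classes(),
    weighted_divergence = isTRUE(y$weighted_divergence),
    alpha_age = y$alpha_age %||% 0.05, seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_sample_sheet <- function(x) {
  sheet <- if (is.data.frame(x)) x else read_tsv_table(x)
  need <- c("sample_id", "condition")
  if (!nrow(sheet) || !all(need %in% names(sheet))) {
    stopf("sample sheet must be non-empty with columns %s",
          paste(need, collapse = ", "))
  }
  if (!"severity" %in% names(sheet)) sheet$severity <- "none"
  bad <- sheet$condition == "control" &
    !sheet$severity %in% c("none", NA, "")
  if (any(bad)) stopf("control samples cannot carry a severity label")
  sheet
}

#' Run the full analysis pipeline for one cohort
#'
#' Executes annotate (parse, ERV selection, intergenic filter, subfamily
#' summary) -> count (or load a count matrix) -> FPKM -> differential
#' expression -> severity contrast (when both severity groups have at
#' least 2 samples) -> divergence age comparison, writing every stage
#' table under `out_dir` with a parameter-echo header plus a manifest
#' (`manifest.yaml`) of outputs, parameters and input checksums. The
#' analysis is deterministic: rerunning with identical inputs and
#' configuration reproduces identical stage outputs (timestamps live
#' only in the manifest).
#'
#' @param config a [pipeline_config()] object or YAML path.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the in-memory stage results
#'   (`summaries`, `counts`, `fpkm`, `de`, `severity`, `age`,
#'   `genes_de`) and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- read_sample_sheet(config$sample_sheet)
  if (!all(c("control") %in% sheet$condition)) {
    stopf("sample sheet has no control samples")
  }
  param_echo <- c(
    sprintf("ervscan %s", as.character(packageVersion("ervscan"))),
    sprintf("strandedness=%s min_mapq=%d", config$counting$strandedness,
            config$counting$min_mapq),
    sprintf("alpha=%g min_fold_change=%g pseudocount=%g adjust=%s",
            config$thresholds$alpha, config$thresholds$min_fold_change,
            config$thresholds$pseudocount_fpkm, config$thresholds$adjust)
  )
  outputs <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_table(df, path, comments = param_echo)
    outputs[[name]] <<- path
    path
  }

  # --- annotate ---
  repeats <- read_repeatmasker(config$rmsk)
  genes <- read_gene_features(config$gtf)
  ervs <- select_erv_copies(repeats, config$erv_classes)
  intergenic <- filter_intergenic(ervs, genes)
  summaries <- summarize_subfamilies(intergenic, ervs,
                                     weighted = config$weighted_divergence)
  write_bed(intergenic, file.path(out_dir, "intergenic_ervs.bed"))
  outputs[["intergenic_ervs.bed"]] <- file.path(out_dir, "intergenic_ervs.bed")
  emit(summaries, "subfamily_summary.tsv")
  usable <- summaries$subfamily[summaries$usable]
  features <- intergenic[intergenic$subfamily %in% usable]

  # --- count ---
  if (!is.null(config$alignments)) {
    al <- config$alignments
    if (is.null(names(al))) names(al) <- sub("\\.(sam|bam)$", "", basename(al))
    missing <- setdiff(sheet$sample_id, names(al))
    if (length(missing)) {
      stopf("no alignment for sample(s): %s", paste(missing, collapse = ", "))
    }
    cs <- count_samples(al[sheet$sample_id], features, config$counting)
    counts <- cs$counts
    totals <- cs$assigned_totals
    emit(cs$summary, "assignment_summary.tsv")
  } else {
    counts <- config$counts
    if (is.character(counts)) {
      df <- read_tsv_table(counts)
      counts <- as.matrix(df[, -1, drop = FALSE])
      rownames(counts) <- df[[1]]
    }
    counts <- as.matrix(counts[, sheet$sample_id, drop = FALSE])
    totals <- colSums(counts)
  }
  emit(data.frame(feature_id = rownames(counts), counts,
                  check.names = FALSE), "erv_counts.tsv")

  # --- fpkm ---
  lens <- summaries$merged_length_bp[match(rownames(counts),
                                           summaries$subfamily)]
  if (anyNA(lens)) {
    # count route may carry features absent from the annotation summary;
    # that is a configuration error
    stopf("no merged length for feature(s): %s",
          paste(utils::head(rownames(counts)[is.na(lens)], 5), collapse = ", "))
  }
  fpkm <- compute_fpkm(counts, lens, totals)
  emit(data.frame(feature_id = rownames(fpkm), fpkm,
                  check.names = FALSE), "erv_fpkm.tsv")

  # --- differential expression ---
  de <- call_differential(fpkm, sheet$condition, config$thresholds)
  emit(as.data.frame(de), "erv_de.tsv")

  # --- severity contrast (platelet-style cohorts) ---
  severity <- NULL
  if (sum(sheet$severity == "icu") >= 2 &&
      sum(sheet$severity == "non_icu") >= 2) {
    severity <- severity_comparison(
      fpkm, sheet$severity,
      de_thresholds(alpha = config$thresholds$alpha,
                    min_fold_change = config$thresholds$min_fold_change,
                    pseudocount_fpkm = config$thresholds$pseudocount_fpkm,
                    adjust = "none"),
      condition = sheet$condition)
    emit(as.data.frame(severity), "severity_de.tsv")
  }

  # --- age comparison ---
  age <- compare_divergence(de, summaries, alpha = config$alpha_age)
  age_df <- data.frame(
    n_upregulated = age$n_upregulated, n_remainder = age$n_remainder,
    median_div_upregulated = age$median_div_upregulated,
    median_div_remainder = age$median_div_remainder,
    u_statistic = age$u_statistic, p_two_sided = age$p_two_sided,
    direction = age$direction)
  emit(age_df, "age_comparison.tsv")
  emit(age_test_long(age), "age_divergence_long.tsv")

  # --- optional immune gene panel ---
  genes_de <- NULL
  if (!is.null(config$gene_list) && !is.null(config$alignments)) {
    panel <- readLines(config$gene_list)
    panel <- panel[nzchar(trimws(panel))]
    meta <- exon_meta_features(genes, panel)
    gs <- count_samples(config$alignments[sheet$sample_id], meta,
                        config$counting)
    glens <- vapply(split(GenomicRanges::width(meta), meta$subfamily),
                    sum, numeric(1))
    glens <- glens[rownames(gs$counts)]
    gf <- compute_fpkm(gs$counts, glens, pmax(gs$assigned_totals, 1L))
    genes_de <- call_differential(gf, sheet$condition, config$thresholds)
    emit(as.data.frame(genes_de), "immune_genes_de.tsv")
  }

  manifest <- list(
    package = "ervscan",
    version = as.character(packageVersion("ervscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = list(
      counting = unclass(config$counting),
      thresholds = unclass(config$thresholds),
      erv_classes = config$erv_classes,
      weighted_divergence = config$weighted_divergence,
      alpha_age = config$alpha_age
    ),
    inputs = manifest_checksums(c(
      rmsk = config$rmsk, gtf = config$gtf,
      if (is.character(config$sample_sheet)) c(sample_sheet = config$sample_sheet),
      if (!is.null(config$alignments)) config$alignments,
      if (is.character(config$counts)) c(counts = config$counts)
    )),
    outputs = manifest_checksums(unlist(outputs))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(summaries = summaries, counts = counts, fpkm = fpkm,
                 de = de, severity = severity, age = age,
                 genes_de = genes_de, manifest = manifest,
                 out_dir = out_dir))
}

manifest_checksums <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  lapply(as.list(paths), function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
}
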