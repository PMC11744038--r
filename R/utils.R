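#' @importFrom methods is
#' @importFrom stats median pnorm pt rnbinom rnorm runif var
#' @importFrom utils packageVersion read.delim write.table
NULL

# Evaluate expr with a temporary RNG state so simulations are pure
# functions of their seed and never disturb the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

#' Write a TSV table with a parameter-echo comment header
#'
#' All pipeline outputs use this writer so that every table records the
#' parameters that produced it. Comment lines start with `#` and are
#' skipped by [read_tsv_table()].
#'
#' @param x data frame to write.
#' @param path output file path.
#' @param comments character vector written as `# `-prefixed lines.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv_table()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, comment.char = "#", sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

# sample() without the scalar-x surprise: always draws from the elements
# of x, even when length(x) == 1.
resample <- function(x, ...) x[sample.int(length(x), ...)]

# Muffle only the GenomeInfoDb notice about disjoint seqlevel sets:
# features on chromosomes absent from the other annotation are a
# documented, legitimate case (they simply cannot overlap).
quiet_seqlevels <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("sequence levels in common", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
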