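#' Read a RepeatMasker annotation (.out format)
#'
#' Parses the standard RepeatMasker `.out` dialect: three header lines
#' followed by whitespace-delimited records with columns score, div., del.,
#' ins., query, begin, end, (left), strand, repeat, class/family, repeat
#' begin/end/(left) and ID. Coordinates in the file are 1-based inclusive
#' and are stored directly in the returned `GRanges`. The complement
#' strand code `C` is mapped to `-`. The per-copy percent divergence from
#' the subfamily consensus (`div.`) is kept as metadata column
#' `divergence_pct`; it is the evolutionary-age proxy used downstream.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return A `GRanges` with metadata columns `subfamily`, `class_family`,
#'   `divergence_pct` and a unique `copy_id`.
#' @examples
#' out <- system.file("extdata", "toy_repeatmasker.out", package = "ervscan")
#' read_repeatmasker(out)
#' @export
read_repeatmasker <- function(path) {
  lines <- readLines(path)
  if (length(lines) <= 3L) return(empty_erv_granges())
  body <- lines[-(1:3)]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  lineno <- (4:length(lines))[keep]
  if (!length(body)) return(empty_erv_granges())

  fields <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 15L | nf > 16L)
  if (length(bad)) {
    stopf("malformed RepeatMasker line %d: expected 15 columns, found %d",
          lineno[bad[1L]], nf[bad[1L]])
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:15))
  div <- suppressWarnings(as.numeric(m[, 2L]))
  qbeg <- suppressWarnings(as.integer(m[, 6L]))
  qend <- suppressWarnings(as.integer(m[, 7L]))
  bad <- which(is.na(div) | is.na(qbeg) | is.na(qend))
  if (length(bad)) {
    stopf("malformed RepeatMasker line %d: non-numeric coordinate or divergence",
          lineno[bad[1L]])
  }
  bad <- which(qend < qbeg)
  if (length(bad)) {
    stopf("malformed RepeatMasker line %d: end precedes begin", lineno[bad[1L]])
  }
  strand_raw <- m[, 9L]
  bad <- which(!strand_raw %in% c("+", "C"))
  if (length(bad)) {
    stopf("malformed RepeatMasker line %d: strand must be '+' or 'C'",
          lineno[bad[1L]])
  }
  if (any(div < 0 | div > 100)) {
    stopf("divergence out of [0, 100] at line %d",
          lineno[which(div < 0 | div > 100)[1L]])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 5L],
    ranges = IRanges::IRanges(start = qbeg, end = qend),
    strand = ifelse(strand_raw == "C", "-", "+"),
    subfamily = m[, 10L],
    class_family = m[, 11L],
    divergence_pct = div,
    copy_id = sprintf("copy_%06d", seq_along(div))
  )
  gr
}

empty_erv_granges <- function() {
  GenomicRanges::GRanges(
    subfamily = character(), class_family = character(),
    divergence_pct = numeric(), copy_id = character()
  )
}

#' Write ERV copies as a RepeatMasker-style .out file
#'
#' Emits the three-line header plus one record per copy, re-readable by
#' [read_repeatmasker()]. Used by the simulator.
#'
#' @param copies `GRanges` with `subfamily`, `class_family`,
#'   `divergence_pct` metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker <- function(copies, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query              matching  repeat           position in repeat",
    "score   div. del. ins.  sequence  begin  end          (left)     repeat    class/family   begin  end    (left)  ID",
    ""
  )
  w <- GenomicRanges::width(copies)
  recs <- sprintf(
    "%5d %6.1f %4.1f %4.1f  %s %9d %9d (%d) %s %s %s %6d %6d (%d) %6d",
    1000L + seq_along(copies), copies$divergence_pct, 0, 0,
    as.character(GenomicRanges::seqnames(copies)),
    GenomicRanges::start(copies), GenomicRanges::end(copies), 0L,
    ifelse(as.character(GenomicRanges::strand(copies)) == "-", "C", "+"),
    copies$subfamily, copies$class_family, 1L, w, 0L, seq_along(copies)
  )
  writeLines(c(hdr, recs), path)
  invisible(path)
}
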