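#' Read gene and exon features from a GTF file
#'
#' Imports a standard GTF (1-based inclusive coordinates) via
#' `rtracklayer` and keeps only `gene` and `exon` records; all other
#' feature types (CDS, transcript, UTRs, ...) are dropped. Every retained
#' record must carry a `gene_id` attribute.
#'
#' @param path path to a GTF file.
#' @return A `GRanges` with metadata columns `gene_id` and `feature_type`
#'   (one of `"gene"`, `"exon"`).
#' @export
read_gene_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("gene", "exon")]
  if (length(gr) && (is.null(gr$gene_id) || anyNA(gr$gene_id))) {
    stopf("GTF record without a gene_id attribute in %s", path)
  }
  out <- GenomicRanges::granges(gr)
  out$gene_id <- if (length(gr)) gr$gene_id else character()
  out$feature_type <- if (length(gr)) as.character(gr$type) else character()
  out
}

#' Collapse exon annotations to one union meta-feature per gene
#'
#' Gene expression is quantified exactly like ERV subfamilies: all exons
#' of one gene form one meta-feature, with overlapping exons merged so
#' the feature length is the exon-union length.
#'
#' @param features `GRanges` from [read_gene_features()].
#' @param gene_ids optional character vector restricting the panel (e.g.
#'   an innate-immune gene list read from a file).
#' @return `GRanges` of merged exon intervals with a `subfamily` column
#'   holding the gene id, directly usable by [count_fragments()].
#' @export
exon_meta_features <- function(features, gene_ids = NULL) {
  ex <- features[features$feature_type == "exon"]
  if (!length(ex)) ex <- features[features$feature_type == "gene"]
  if (!is.null(gene_ids)) ex <- ex[ex$gene_id %in% gene_ids]
  parts <- GenomicRanges::reduce(
    S4Vectors::split(ex, ex$gene_id), ignore.strand = FALSE)
  flat <- unlist(parts, use.names = TRUE)
  out <- GenomicRanges::granges(flat)
  out$subfamily <- names(flat)
  names(out) <- NULL
  out
}

#' Write genomic intervals as BED6
#'
#' BED uses 0-based half-open coordinates; the conversion from the
#' 1-based `GRanges` representation happens here and only here.
#'
#' @param gr `GRanges`; a `subfamily` or `copy_id` column supplies names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  nm <- if (!is.null(gr$subfamily)) gr$subfamily else
    if (!is.null(gr$copy_id)) gr$copy_id else rep(".", length(gr))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm,
    score = 0L,
    strand = as.character(GenomicRanges::strand(gr))
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file back into a GRanges
#'
#' @param path BED file path.
#' @return `GRanges` with a `subfamily` metadata column from the name field.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- GenomicRanges::granges(gr)
  out$subfamily <- gr$name
  out
}
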