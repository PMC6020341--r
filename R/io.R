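#' Read and write count matrices as TSV
#'
#' Counts are stored as a plain TSV with a `gene_id` column followed by one
#' column per cell. The in-memory representation is an integer matrix with
#' gene rownames and cell colnames.
#'
#' @param path file path.
#' @return `read_counts_tsv()` returns a genes x cells integer matrix.
#' @export
read_counts_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tb[[1]]
  assert_counts(m)
  m
}

#' @param counts genes x cells matrix with dimnames.
#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  assert_counts(counts)
  tb <- tibble::as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Read and write gene models (GTF)
#'
#' Gene models are a tibble of `gene` and `exon` records with columns
#' `type`, `gene_id`, `transcript_id`, `chrom`, `start`, `end`, `strand`.
#' Coordinates are 0-based half-open in memory; GTF's 1-based closed records
#' are converted on read and write (via rtracklayer).
#'
#' @param path GTF file path.
#' @return a tibble of gene/exon records.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  tibble(
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = if ("transcript_id" %in% names(md)) {
      as.character(md$transcript_id)
    } else {
      NA_character_
    },
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' @param gene_models tibble of gene/exon records (see `read_gtf()`).
#' @rdname read_gtf
#' @export
write_gtf <- function(gene_models, path) {
  gr <- granges0(gene_models$chrom, gene_models$start, gene_models$end,
    strand = gene_models$strand
  )
  S4Vectors::mcols(gr)$type <- gene_models$type
  S4Vectors::mcols(gr)$source <- "cginoise"
  S4Vectors::mcols(gr)$gene_id <- gene_models$gene_id
  S4Vectors::mcols(gr)$transcript_id <- gene_models$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read and write CpG islands (BED4)
#'
#' Islands are a tibble with `chrom`, `start`, `end` (0-based half-open),
#' `name` and derived `length_bp = end - start`, sorted per chromosome.
#'
#' @param path BED file path.
#' @return a tibble of islands.
#' @export
read_cgi_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tbl_from_granges(gr)
  nm <- S4Vectors::mcols(gr)$name
  out$name <- if (is.null(nm)) paste0("cgi_", seq_len(nrow(out))) else as.character(nm)
  out$length_bp <- out$end - out$start
  if (any(out$length_bp <= 0)) abort("CpG island with non-positive length.")
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' @param islands tibble with `chrom`, `start`, `end`, `name`.
#' @rdname read_cgi_bed
#' @export
write_cgi_bed <- function(islands, path) {
  gr <- granges0(islands$chrom, islands$start, islands$end)
  S4Vectors::mcols(gr)$name <- islands$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read and write windowed coverage tracks (bedGraph)
#'
#' A track is a tibble with `chrom`, `start`, `end` (0-based half-open) and
#' `value` (a count or a log2 enrichment, depending on the stage).
#'
#' @param path bedGraph file path.
#' @return a tibble track.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- tbl_from_granges(gr)
  out$value <- as.numeric(S4Vectors::mcols(gr)$score)
  out
}

#' @param track tibble with `chrom`, `start`, `end`, `value`.
#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  gr <- granges0(track$chrom, track$start, track$end, score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read and write time-series fold-change tables
#'
#' Plain TSV with a `gene_id` column, one `fc_*` column per consecutive
#' time-point comparison, and optionally further columns.
#'
#' @param path TSV file path.
#' @return a tibble.
#' @export
read_timeseries_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @param ts time-series tibble.
#' @rdname read_timeseries_tsv
#' @export
write_timeseries_tsv <- function(ts, path) {
  readr::write_tsv(ts, path, progress = FALSE)
  invisible(path)
}
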