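# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||% .data :=
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom utils head
NULL

# Coordinates are 0-based half-open everywhere in this package (BED-native).
# GRanges is 1-based closed, so shift on the way in and out.
granges0 <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    ...
  )
}

# Inverse of granges0: a tibble with 0-based half-open start/end.
tbl_from_granges <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# z-score with a zero-variance guard; constant columns are returned unchanged
# with attribute "constant" set so callers can flag them.
zscore_guard <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    attr(x, "constant") <- TRUE
    return(x)
  }
  (x - mean(x, na.rm = TRUE)) / s
}

# Fast per-row mean and sample variance (denominator n - 1) for a matrix.
row_moments <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  v <- (rowSums(x^2) - n * mu^2) / (n - 1)
  # guard tiny negative values from floating-point cancellation
  v[v < 0 & v > -1e-12] <- 0
  list(mean = mu, var = v)
}

# geometric-mean-1 rescaling for positive factors
rescale_geomean <- function(s) {
  s / exp(mean(log(s)))
}

assert_counts <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x cells).", arg))
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort(sprintf("`%s` must have gene rownames and cell colnames.", arg))
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort(sprintf("`%s` has duplicated gene or cell identifiers.", arg))
  }
  if (any(counts < 0)) abort(sprintf("`%s` contains negative values.", arg))
  invisible(counts)
}

# stable hash of an R object (used for config fingerprints)
config_hash <- function(x) rlang::hash(x)
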