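#' Windowed log2 fold enrichment (ChIP vs input)
#'
#' Both libraries are depth-normalized to counts-per-million over the same
#' non-overlapping 200-bp window grid, then
#' `value = log2((chip + pc) / (input + pc))` per window.
#'
#' @param chip,input Window-count tibbles (`chrom`, `start`, `end`,
#'   `value`) on an identical grid.
#' @param pseudocount Added to both normalized counts. Default 1.
#' @return A track tibble with `value` = log2 fold enrichment.
#' @export
fold_enrichment <- function(chip, input, pseudocount = 1) {
  chip <- dplyr::arrange(chip, .data$chrom, .data$start)
  input <- dplyr::arrange(input, .data$chrom, .data$start)
  if (nrow(chip) != nrow(input) ||
    !all(chip$chrom == input$chrom) ||
    !all(chip$start == input$start) || !all(chip$end == input$end)) {
    abort("chip and input are not on the same window grid")
  }
  cpm <- function(v) v / sum(v) * 1e6
  dplyr::mutate(chip,
    value = log2((cpm(chip$value) + pseudocount) /
      (cpm(input$value) + pseudocount))
  )
}

#' Average promoter signal from windowed tracks
#'
#' For each promoter and replicate, the unweighted mean of the track value
#' over all windows overlapping the promoter interval by at least 1 bp;
#' replicate means are then averaged. Promoters overlapping no window get a
#' missing value.
#'
#' @param track A track tibble (`chrom`, `start`, `end`, `value`) with an
#'   optional `replicate` column; or a list of such tibbles (one per
#'   replicate).
#' @param promoters Promoter tibble from [define_promoters()].
#' @return A tibble: `gene_id`, `signal`.
#' @export
promoter_signal <- function(track, promoters) {
  if (is.list(track) && !is.data.frame(track)) {
    track <- dplyr::bind_rows(track, .id = "replicate")
  }
  if (!"replicate" %in% names(track)) track$replicate <- 1L
  pr <- granges0(promoters$chrom, promoters$start, promoters$end)
  per_rep <- track |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_map(function(g, key) {
      wins <- granges0(g$chrom, g$start, g$end)
      hits <- suppressWarnings(
        GenomicRanges::findOverlaps(pr, wins, minoverlap = 1L)
      )
      means <- rep(NA_real_, nrow(promoters))
      if (length(hits) > 0) {
        agg <- tapply(
          g$value[S4Vectors::subjectHits(hits)],
          S4Vectors::queryHits(hits), mean
        )
        means[as.integer(names(agg))] <- as.numeric(agg)
      }
      means
    })
  signal <- rowMeans(do.call(cbind, per_rep))
  if (anyNA(signal)) {
    inform(sprintf(
      "promoter_signal: %d promoter(s) overlap no window", sum(is.na(signal))
    ))
  }
  tibble(gene_id = promoters$gene_id, signal = signal)
}

# lowest interior local minimum of a KDE, between the two largest modes
kde_valley <- function(x) {
  d <- tryCatch(stats::density(x, bw = "nrd0", n = 512),
    error = function(e) abort(paste("density estimation failed:", conditionMessage(e)))
  )
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  is_min <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n], FALSE)
  maxima <- which(is_max)
  if (length(maxima) < 2) {
    abort(paste(
      "H3K4me3 density looks unimodal (no interior local minimum);",
      "inspect the signal distribution and pass `k4_threshold` manually"
    ))
  }
  top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)][1:2])
  valley <- which(is_min & seq_len(n) > top2[1] & seq_len(n) < top2[2])
  if (length(valley) == 0) {
    abort(paste(
      "no local minimum between the two largest H3K4me3 modes;",
      "pass `k4_threshold` manually"
    ))
  }
  d$x[valley[which.min(y[valley])]]
}

#' Classify promoters as active, repressed, bivalent or low
#'
#' The H3K4me3 signal distribution over promoters is bimodal, so its
#' threshold is the local minimum of a Gaussian kernel density estimate
#' (Silverman bandwidth, 512-point grid) between the two largest modes.
#' The H3K27me3 distribution is long-tailed without a clear minimum, so its
#' threshold is the mean signal over all promoters. A promoter is called
#' for a mark when its signal strictly exceeds `multiplier` (1.5) times the
#' mark's threshold: both marks = bivalent, only H3K4me3 = active, only
#' H3K27me3 = repressed, neither = low.
#'
#' Signals are log2 enrichments, so a threshold can be negative; the
#' multiplier is applied to the threshold as printed, with a warning that
#' multiplying a non-positive threshold lowers the bar.
#'
#' @param k4,k27 Per-gene signal tibbles (`gene_id`, `signal`) from
#'   [promoter_signal()].
#' @param multiplier Threshold multiplier. Default 1.5.
#' @param k4_threshold,k27_threshold Manual threshold overrides (before the
#'   multiplier); by default estimated from the data, which needs at least
#'   `min_genes` promoters with both signals defined.
#' @param min_genes Minimum promoters for density estimation. Default 200.
#' @return A `promoter_chromatin` tibble: `gene_id`, `k4_signal`,
#'   `k27_signal`, `class`; thresholds and multiplier are attached as
#'   attributes and via [generics::glance()].
#' @export
classify_bivalency <- function(k4, k27, multiplier = 1.5,
                               k4_threshold = NULL, k27_threshold = NULL,
                               min_genes = 200) {
  d <- dplyr::inner_join(
    dplyr::rename(k4, k4_signal = "signal"),
    dplyr::rename(k27, k27_signal = "signal"),
    by = "gene_id"
  ) |>
    dplyr::filter(is.finite(.data$k4_signal), is.finite(.data$k27_signal))
  if (is.null(k4_threshold) || is.null(k27_threshold)) {
    if (nrow(d) < min_genes) {
      abort(sprintf(
        "only %d promoters with both signals; need >= %d for threshold estimation",
        nrow(d), min_genes
      ))
    }
  }
  k4_threshold <- k4_threshold %||% kde_valley(d$k4_signal)
  k27_threshold <- k27_threshold %||% mean(d$k27_signal)
  if (k4_threshold <= 0 || k27_threshold <= 0) {
    warn("non-positive threshold: the multiplier lowers the bar for that mark")
  }
  a <- d$k4_signal > multiplier * k4_threshold
  r <- d$k27_signal > multiplier * k27_threshold
  d$class <- dplyr::case_when(
    a & r ~ "bivalent",
    a ~ "active",
    r ~ "repressed",
    .default = "low"
  )
  structure(d,
    class = c("promoter_chromatin", class(d)),
    k4_threshold = k4_threshold, k27_threshold = k27_threshold,
    multiplier = multiplier
  )
}

#' Chromatin thresholds of a classification
#'
#' @param x A `promoter_chromatin` tibble from [classify_bivalency()].
#' @return A named list with `k4_threshold`, `k27_threshold`, `multiplier`.
#' @export
chromatin_thresholds <- function(x) {
  list(
    k4_threshold = attr(x, "k4_threshold"),
    k27_threshold = attr(x, "k27_threshold"),
    multiplier = attr(x, "multiplier")
  )
}

#' Noise on promoter class and CpG island size jointly
#'
#' Robust fit of the mean-adjusted noise on indicator columns for the
#' active, bivalent and low classes (repressed promoters are the
#' reference) plus the z-scored CpG island size, separating the chromatin
#' effect from the island-size effect.
#'
#' @param noise Noise tibble with `rcv2`.
#' @param classes `promoter_chromatin` tibble from [classify_bivalency()].
#' @param cgi Tibble with `gene_id` and a CpG island size column.
#' @param cgi_col Name of the island-size column. Default `"cgi_size_bp"`.
#' @param response Response column. Default `"rcv2"`.
#' @return A `robust_fit` object (see [robust_fit()]).
#' @export
category_regression <- function(noise, classes, cgi, cgi_col = "cgi_size_bp",
                                response = "rcv2") {
  d <- noise[, c("gene_id", response)] |>
    dplyr::inner_join(classes[, c("gene_id", "class")], by = "gene_id") |>
    dplyr::inner_join(cgi[, c("gene_id", cgi_col)], by = "gene_id")
  present <- unique(d$class)
  if (length(present) < 2) {
    abort("need at least 2 promoter classes for contrasts")
  }
  if (!"repressed" %in% present) {
    abort("reference class `repressed` is empty")
  }
  feats <- character()
  for (cl in intersect(c("active", "bivalent", "low"), present)) {
    col <- paste0("class_", cl)
    d[[col]] <- as.numeric(d$class == cl)
    feats <- c(feats, col)
  }
  d$cgi_size_z <- as.numeric(zscore_guard(d[[cgi_col]]))
  robust_fit(d, response = response, features = c(feats, "cgi_size_z"))
}
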