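#' Filter time-series features before enrichment testing
#'
#' CAGE peaks must be detected (count > 0) in more than 75% of samples;
#' RNA-seq genes must average more than 5 counts across samples. Both
#' boundaries are exclusive: a peak detected in exactly 75% of samples, or
#' a gene averaging exactly 5 counts, is removed.
#'
#' @param ts Time-series tibble carrying the measurement columns.
#' @param kind `"cage"` or `"rnaseq"`.
#' @param sample_cols Names of the per-sample count columns used for the
#'   filter.
#' @param detect_fraction CAGE detection threshold. Default 0.75.
#' @param min_mean_count RNA-seq mean-count threshold. Default 5.
#' @return The filtered tibble.
#' @export
filter_timeseries <- function(ts, kind = c("cage", "rnaseq"), sample_cols,
                              detect_fraction = 0.75, min_mean_count = 5) {
  kind <- rlang::arg_match(kind)
  m <- as.matrix(ts[, sample_cols, drop = FALSE])
  if (any(m < 0)) abort("negative counts in sample columns")
  keep <- if (kind == "cage") {
    rowMeans(m > 0) > detect_fraction
  } else {
    rowMeans(m) > min_mean_count
  }
  if (!any(keep)) abort("all features removed by the time-series filter")
  inform(sprintf(
    "filter_timeseries (%s): kept %d / %d features", kind, sum(keep), nrow(ts)
  ))
  ts[keep, , drop = FALSE]
}

#' Assign CpG islands to CAGE peaks
#'
#' An island is assigned when it overlaps a 500-bp window centred on the
#' peak position, `[pos - flank/2, pos + flank/2)`; among several
#' candidates the maximal-overlap island wins, ties going to the longer
#' island (the same rule as [assign_cgi()]).
#'
#' @param peaks Tibble with `peak_id`, `chrom`, `pos` (0-based).
#' @param islands Island tibble (`chrom`, `start`, `end`).
#' @param flank Total window width centred on the peak. Default 500.
#' @return A tibble: `peak_id`, `cgi_overlap`, `cgi_size_bp` (0 if none).
#' @export
assign_cgi_to_peaks <- function(peaks, islands, flank = 500) {
  query <- tibble(
    peak_id = peaks$peak_id, chrom = peaks$chrom,
    start = as.integer(peaks$pos - flank %/% 2),
    end = as.integer(peaks$pos + flank %/% 2)
  )
  overlap_max_island(query, islands, id_col = "peak_id")
}

#' Naive shrunken log2 fold changes between consecutive time points
#'
#' Replicate columns of each time point are averaged and
#' `fc = log2((mean_t2 + pc) / (mean_t1 + pc))` is computed for each
#' consecutive pair of time points. This is a plain pseudocount-shrunken
#' estimate; externally computed moderated fold-change tables can be used
#' interchangeably downstream.
#'
#' @param counts Tibble with `gene_id` and one column per sample.
#' @param timepoints Vector (length = number of sample columns) giving each
#'   sample's time point; comparisons follow the sorted unique values.
#' @param pseudocount Shrinkage pseudocount. Default 1.
#' @return A tibble: `gene_id` plus one `fc_<t1>v<t2>` column per
#'   consecutive comparison.
#' @export
naive_log2fc <- function(counts, timepoints, pseudocount = 1) {
  sample_cols <- setdiff(names(counts), "gene_id")
  if (length(timepoints) != length(sample_cols)) {
    abort("`timepoints` must match the sample columns")
  }
  m <- as.matrix(counts[, sample_cols, drop = FALSE])
  if (any(m < 0)) abort("negative counts")
  tps <- sort(unique(timepoints))
  if (length(tps) < 2) abort("need at least 2 time points")
  means <- vapply(
    tps, function(tp) rowMeans(m[, timepoints == tp, drop = FALSE]),
    numeric(nrow(m))
  )
  out <- tibble(gene_id = counts$gene_id)
  for (k in seq_len(length(tps) - 1)) {
    out[[sprintf("fc_%sv%s", tps[k], tps[k + 1])]] <-
      log2((means[, k + 1] + pseudocount) / (means[, k] + pseudocount))
  }
  out
}

#' CpG-island size enrichment among top up-regulated genes
#'
#' Tests whether the genes most strongly up-regulated in the earliest
#' time-point comparison carry smaller CpG islands than those most
#' up-regulated later. Island-bearing genes are ranked by descending log2
#' fold change separately within the early and the late comparison; the
#' r-th early gene is paired with the r-th late gene for r = 1..`top_n`,
#' a success being an early island strictly smaller than its late partner
#' (exact-size ties excluded, the sign-test convention). The one-tailed
#' p-value is the exact binomial tail
#' `P(Binomial(n_pairs, 1/2) >= n_early_smaller)` against a 50:50 null --
#' a paired-sample sign test on the rank-matched pairs.
#'
#' @param ts Time-series tibble with `gene_id`, fold-change columns and a
#'   `cgi_size_bp` column (or join one via `cgi`).
#' @param early,late Names of the early and late fold-change columns.
#' @param top_n Number of top-ranked genes per comparison. Default 250
#'   (truncated with a warning when fewer ranked genes exist).
#' @param cgi Optional tibble (`gene_id`, `cgi_size_bp`) if `ts` lacks
#'   island sizes.
#' @return A `cgi_enrichment` object: `n_pairs`, `n_early_smaller`,
#'   `ties_excluded`, `p_one_tailed`, `direction` (`"short_early"` when
#'   successes exceed half, else `"long_early"`). Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
cgi_size_enrichment <- function(ts, early, late, top_n = 250, cgi = NULL) {
  if (!is.null(cgi)) {
    ts <- dplyr::inner_join(ts, cgi[, c("gene_id", "cgi_size_bp")],
      by = "gene_id"
    )
  }
  for (col in c(early, late, "cgi_size_bp")) {
    if (!col %in% names(ts)) abort(paste("column not found:", col))
  }
  d <- dplyr::filter(ts, .data$cgi_size_bp > 0, is.finite(.data[[early]]),
    is.finite(.data[[late]])
  )
  n_avail <- nrow(d)
  if (top_n > n_avail) {
    warn(sprintf(
      "top_n = %d exceeds the %d ranked genes; using all", top_n, n_avail
    ))
    top_n <- n_avail
  }
  early_sizes <- d$cgi_size_bp[order(d[[early]], decreasing = TRUE)][seq_len(top_n)]
  late_sizes <- d$cgi_size_bp[order(d[[late]], decreasing = TRUE)][seq_len(top_n)]
  keep <- !is.na(early_sizes) & !is.na(late_sizes) & early_sizes != late_sizes
  ties <- sum(early_sizes == late_sizes, na.rm = TRUE)
  n_pairs <- sum(keep)
  if (n_pairs == 0) abort("no informative pairs (all ties or missing)")
  k <- sum(early_sizes[keep] < late_sizes[keep])
  p <- stats::pbinom(k - 1, n_pairs, 0.5, lower.tail = FALSE)
  structure(
    list(
      n_pairs = n_pairs, n_early_smaller = k, ties_excluded = ties,
      p_one_tailed = p,
      direction = if (k / n_pairs > 0.5) "short_early" else "long_early",
      top_n = top_n, early = early, late = late
    ),
    class = "cgi_enrichment"
  )
}

#' @export
print.cgi_enrichment <- function(x, ...) {
  cat(sprintf(
    paste0(
      "CpG-island size enrichment (%s vs %s, top %d):\n",
      "  %d / %d pairs with the smaller island early (%d ties excluded)\n",
      "  one-tailed binomial p = %.3g, direction = %s\n"
    ),
    x$early, x$late, x$top_n, x$n_early_smaller, x$n_pairs,
    x$ties_excluded, x$p_one_tailed, x$direction
  ))
  invisible(x)
}

#' Label genes by stimulation response
#'
#' Differential expression between unstimulated and stimulated cells by a
#' per-gene Wilcoxon rank-sum test on library-size-normalized expression,
#' Benjamini-Hochberg corrected; significant genes are split into `up` and
#' `down` by the sign of the shrunken log2 fold change, the rest are
#' `nochange`.
#'
#' @param unstim,stim Count matrices (genes x cells) over a shared gene
#'   universe; each group needs at least 20 cells.
#' @param fdr BH false-discovery-rate cutoff. Default 0.05.
#' @return A tibble: `gene_id`, `log2fc`, `p_value`, `p_adj`, `label`.
#' @export
label_response <- function(unstim, stim, fdr = 0.05) {
  assert_counts(unstim, "unstim")
  assert_counts(stim, "stim")
  genes <- intersect(rownames(unstim), rownames(stim))
  if (length(genes) == 0) abort("no shared genes")
  if (ncol(unstim) < 20 || ncol(stim) < 20) {
    abort("each group needs at least 20 cells")
  }
  norm_mat <- function(m) {
    s <- rescale_geomean(colSums(m) / mean(colSums(m)))
    sweep(m[genes, , drop = FALSE], 2, s, "/")
  }
  a <- norm_mat(unstim)
  b <- norm_mat(stim)
  p <- vapply(seq_along(genes), function(i) {
    x <- b[i, ]
    y <- a[i, ]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
      return(1)
    }
    suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    )
  }, numeric(1))
  p[is.na(p)] <- 1
  p_adj <- stats::p.adjust(p, method = "BH")
  log2fc <- log2((rowMeans(b) + 1) / (rowMeans(a) + 1))
  tibble(
    gene_id = genes, log2fc = log2fc, p_value = p, p_adj = p_adj,
    label = dplyr::case_when(
      p_adj < fdr & log2fc > 0 ~ "up",
      p_adj < fdr & log2fc < 0 ~ "down",
      .default = "nochange"
    )
  )
}

#' Pre-stimulation noise versus response direction
#'
#' Summarizes pre-stimulation expression noise (CV2, or rCV2 with
#' `use_rcv2`) of island-bearing genes per 0.5-kb island-size bin and
#' response label, and tests with one-tailed two-sample Kolmogorov-Smirnov
#' tests whether up-regulated genes are stochastically noisier than
#' down-regulated and unchanged genes. The same tests are run on the
#' non-island stratum as a contrast.
#'
#' @param noise Noise tibble computed on the unstimulated cells.
#' @param labels Label tibble from [label_response()].
#' @param cgi Tibble with `gene_id`, `cgi_size_bp`.
#' @param bin_width Island-size bin width in bp. Default 500.
#' @param use_rcv2 Summarize rCV2 instead of CV2? Default FALSE.
#' @param min_bin Minimum genes per bin-label cell; smaller cells are
#'   reported as missing. Default 3.
#' @return A list with `bins` (stratum, bin, bin_start, label, n,
#'   mean_noise) and `ks` (stratum, comparison, statistic, p_value).
#' @export
noise_vs_response <- function(noise, labels, cgi, bin_width = 500,
                              use_rcv2 = FALSE, min_bin = 3) {
  noise_col <- if (use_rcv2) "rcv2" else "cv2"
  d <- noise[, c("gene_id", noise_col)] |>
    dplyr::inner_join(labels[, c("gene_id", "label")], by = "gene_id") |>
    dplyr::inner_join(cgi[, c("gene_id", "cgi_size_bp")], by = "gene_id") |>
    dplyr::filter(is.finite(.data[[noise_col]])) |>
    dplyr::mutate(
      stratum = ifelse(.data$cgi_size_bp > 0, "cgi", "non_cgi"),
      bin = .data$cgi_size_bp %/% bin_width
    )
  bins <- d |>
    dplyr::filter(.data$stratum == "cgi") |>
    dplyr::group_by(.data$bin, .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_noise = mean(.data[[noise_col]]), .groups = "drop"
    ) |>
    dplyr::mutate(
      stratum = "cgi",
      bin_start = .data$bin * bin_width,
      mean_noise = ifelse(.data$n < min_bin, NA_real_, .data$mean_noise)
    ) |>
    dplyr::select("stratum", "bin", "bin_start", "label", "n", "mean_noise")
  ks_one <- function(up, other, name, stratum) {
    if (length(up) < 3 || length(other) < 3) {
      return(tibble(
        stratum = stratum, comparison = name,
        statistic = NA_real_, p_value = NA_real_
      ))
    }
    # H1: up-labelled genes stochastically noisier, i.e. their CDF below
    kt <- suppressWarnings(
      stats::ks.test(up, other, alternative = "less")
    )
    tibble(
      stratum = stratum, comparison = name,
      statistic = unname(kt$statistic), p_value = kt$p.value
    )
  }
  ks <- purrr::map_dfr(c("cgi", "non_cgi"), function(st) {
    g <- dplyr::filter(d, .data$stratum == st)
    up <- g[[noise_col]][g$label == "up"]
    dplyr::bind_rows(
      ks_one(up, g[[noise_col]][g$label == "down"], "up_vs_down", st),
      ks_one(up, g[[noise_col]][g$label == "nochange"], "up_vs_nochange", st)
    )
  })
  list(bins = bins, ks = ks)
}
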