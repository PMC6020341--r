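#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mean-CV2 fit
#'
#' @param x A `mean_cv2_fit` from [fit_mean_cv2()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient.
#' @export
tidy.mean_cv2_fit <- function(x, ...) {
  tibble(
    term = c("a0", "a1"),
    estimate = c(x$a0, x$a1),
    std.error = x$se
  )
}

#' @rdname tidy.mean_cv2_fit
#' @export
glance.mean_cv2_fit <- function(x, ...) {
  tibble(
    a0 = x$a0, a1 = x$a1, deviance = x$deviance, iter = x$iter,
    converged = x$converged, n_genes = x$n_genes,
    negative_fitted = x$negative_fitted
  )
}

#' Tidy a robust fit
#'
#' @param x A `robust_fit` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.robust_fit <- function(x, ...) {
  dplyr::rename(x$coefficients,
    estimate = "beta", std.error = "se",
    statistic = "t_stat", p.value = "p_value"
  )
}

#' @rdname tidy.robust_fit
#' @export
glance.robust_fit <- function(x, ...) {
  tibble(
    n = x$n, df.residual = x$df_residual, sigma = x$sigma,
    converged = x$converged, psi = x$psi
  )
}

#' Tidy an island-size enrichment result
#'
#' @param x A `cgi_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.cgi_enrichment <- function(x, ...) {
  tibble(
    n_pairs = x$n_pairs, n_early_smaller = x$n_early_smaller,
    ties_excluded = x$ties_excluded, p_one_tailed = x$p_one_tailed,
    direction = x$direction, top_n = x$top_n,
    early = x$early, late = x$late
  )
}

#' @rdname tidy.cgi_enrichment
#' @export
glance.cgi_enrichment <- tidy.cgi_enrichment

#' Summary of a promoter chromatin classification
#'
#' @param x A `promoter_chromatin` tibble from [classify_bivalency()].
#' @param ... Unused.
#' @return A one-row tibble with thresholds and per-class counts.
#' @export
glance.promoter_chromatin <- function(x, ...) {
  counts <- table(factor(x$class,
    levels = c("active", "repressed", "bivalent", "low")
  ))
  dplyr::bind_cols(
    tibble(
      k4_threshold = attr(x, "k4_threshold"),
      k27_threshold = attr(x, "k27_threshold"),
      multiplier = attr(x, "multiplier"),
      n = nrow(x)
    ),
    tibble::as_tibble_row(as.list(counts))
  )
}
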