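#' Filter low-count cells
#'
#' Removes cells whose total count falls below `min_total` (strictly) and
#' any cells explicitly flagged as bad.
#'
#' @param counts genes x cells count matrix.
#' @param min_total Minimum total count per cell; cells with totals strictly
#'   below are removed. Default 100000.
#' @param bad_cells Character vector of cell ids to drop regardless.
#' @return The filtered count matrix.
#' @export
filter_cells <- function(counts, min_total = 100000, bad_cells = NULL) {
  assert_counts(counts)
  totals <- colSums(counts)
  keep <- totals >= min_total & !colnames(counts) %in% bad_cells
  if (!any(keep)) abort("all cells removed by the cell filter")
  inform(sprintf(
    "filter_cells: kept %d / %d cells (min_total = %s)",
    sum(keep), ncol(counts), format(min_total, scientific = FALSE)
  ))
  counts[, keep, drop = FALSE]
}

#' Filter rarely detected genes
#'
#' Keeps a gene iff it is detected (count > 0) in at least
#' `min_cell_fraction` of cells; a gene detected in exactly 1% of cells is
#' kept at the default threshold.
#'
#' @inheritParams filter_cells
#' @param min_cell_fraction Minimum fraction of cells with a non-zero
#'   count. Default 0.01.
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, min_cell_fraction = 0.01) {
  assert_counts(counts)
  stopifnot(min_cell_fraction >= 0, min_cell_fraction <= 1)
  frac <- rowMeans(counts > 0)
  keep <- frac >= min_cell_fraction
  if (!any(keep)) abort("all genes removed by the gene filter")
  inform(sprintf(
    "filter_genes: kept %d / %d genes (min fraction = %g)",
    sum(keep), nrow(counts), min_cell_fraction
  ))
  counts[keep, , drop = FALSE]
}

#' Per-cell size factors
#'
#' Deconvolution size factors (pooled normalization, via scran) rescaled to
#' geometric mean 1, or simple library-size factors. Deconvolution needs at
#' least 20 cells; below that the library-size method is used with a
#' warning.
#'
#' @inheritParams filter_cells
#' @param method `"deconvolution"` (default) or `"library"`.
#' @param pool_sizes Pool sizes for deconvolution, capped at the number of
#'   cells.
#' @return A tibble: `cell_id`, `size_factor` (all positive, geometric mean
#'   1).
#' @export
size_factors <- function(counts, method = c("deconvolution", "library"),
                         pool_sizes = c(20, 40, 60, 80, 100)) {
  assert_counts(counts)
  method <- rlang::arg_match(method)
  totals <- colSums(counts)
  if (any(totals == 0)) abort("zero-count cell; run filter_cells() first")
  if (method == "deconvolution" && ncol(counts) < 20) {
    warn("fewer than 20 cells; falling back to library-size factors")
    method <- "library"
  }
  s <- if (method == "library") {
    totals
  } else {
    sizes <- unique(pmin(pool_sizes, ncol(counts)))
    scran::calculateSumFactors(counts, sizes = sizes, positive = TRUE)
  }
  if (any(!is.finite(s) | s <= 0)) {
    warn("non-positive size factor estimate(s); replacing by library size")
    s[!is.finite(s) | s <= 0] <- totals[!is.finite(s) | s <= 0] /
      mean(totals)
  }
  tibble(cell_id = colnames(counts), size_factor = rescale_geomean(s))
}

#' Per-gene expression moments and CV-squared
#'
#' Normalizes counts by the size factors and computes, per gene: `mu`, the
#' log2 of the mean normalized count; `var_hat`, the sample variance
#' (denominator m - 1); and the squared coefficient of variation `cv2`,
#' the variance over the squared mean on a common scale. With the default
#' `cv2_on = "normalized"` the variance and squared mean are those of the
#' normalized counts themselves (the parametrisation of Brennecke-style
#' technical-noise fits); with `cv2_on = "log2"` both are computed on
#' `log2(c/s + pseudocount)` values, so `cv2 = var_hat / mu^2`. Genes with
#' `mu <= mu_floor` are flagged as excluded from the mean-CV2 fit so that
#' `1/mu` stays bounded.
#'
#' @inheritParams filter_cells
#' @param sf Size-factor tibble from [size_factors()].
#' @param pseudocount Added inside the log2 for the log2-scale variance.
#'   Default 1.
#' @param mu_floor Minimum `mu` (log2 scale) for fit inclusion. Default 0.1.
#' @param cv2_on Scale on which the coefficient of variation is computed:
#'   `"normalized"` counts (default) or `"log2"`-transformed counts.
#' @return A noise tibble: `gene_id`, `mu`, `var_hat`, `cv2`, `fit_include`.
#' @export
gene_moments <- function(counts, sf, pseudocount = 1, mu_floor = 0.1,
                         cv2_on = c("normalized", "log2")) {
  assert_counts(counts)
  cv2_on <- rlang::arg_match(cv2_on)
  if (ncol(counts) < 3) abort("need at least 3 cells for a sample variance")
  s <- sf$size_factor[match(colnames(counts), sf$cell_id)]
  if (anyNA(s)) abort("size factors missing for some cells")
  norm <- sweep(counts, 2, s, "/")
  mean_norm <- rowMeans(norm)
  mu <- log2(mean_norm)
  if (cv2_on == "log2") {
    var_hat <- row_moments(log2(norm + pseudocount))$var
    cv2 <- var_hat / mu^2
  } else {
    var_hat <- row_moments(norm)$var
    cv2 <- var_hat / mean_norm^2
  }
  tibble(
    gene_id = rownames(counts),
    mu = unname(mu), var_hat = unname(var_hat), cv2 = unname(cv2),
    fit_include = unname(
      is.finite(mu) & mu > mu_floor & is.finite(cv2) & cv2 > 0
    )
  )
}

#' Fit the mean-CV2 curve
#'
#' Fits `E[CV2_i] = a0 + a1 / mu_i` over fit-eligible genes with a
#' gamma-family generalized linear model with identity link (iteratively
#' reweighted least squares), the parametrisation of Brennecke-style
#' technical-noise fits. With clean reciprocal data the coefficients are
#' recovered exactly.
#'
#' @param noise Noise tibble from [gene_moments()].
#' @param min_genes Minimum number of fit-eligible genes. Default 50.
#' @param epsilon,maxit IRLS convergence tolerance and iteration cap.
#' @return An object of class `mean_cv2_fit` with elements `a0`, `a1`,
#'   `deviance`, `iter`, `converged`, `n_genes` and
#'   `negative_fitted` (flag: some included gene got a negative fitted
#'   E\[CV2\]). Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_mean_cv2 <- function(noise, min_genes = 50, epsilon = 1e-8, maxit = 100) {
  d <- dplyr::filter(noise, .data$fit_include)
  if (nrow(d) < min_genes) {
    abort(sprintf("only %d fit-eligible genes (< %d)", nrow(d), min_genes))
  }
  x <- 1 / d$mu
  start <- stats::coef(stats::lm(d$cv2 ~ x))
  if (start[1] + start[2] * min(x) <= 0 || start[1] + start[2] * max(x) <= 0) {
    start <- c(max(mean(d$cv2), 1e-3), 0)
  }
  # identity-link gamma IRLS can emit transient step-halving/NaN warnings
  # on its way to the optimum; convergence is reported via the fit object
  fit <- suppressWarnings(tryCatch(
    stats::glm(cv2 ~ I(1 / mu),
      family = stats::Gamma(link = "identity"), data = d,
      start = start, control = list(epsilon = epsilon, maxit = maxit)
    ),
    error = function(e) {
      stats::glm(cv2 ~ I(1 / mu),
        family = stats::Gamma(link = "identity"), data = d,
        start = c(mean(d$cv2), 0),
        control = list(epsilon = epsilon, maxit = maxit)
      )
    }
  ))
  if (!fit$converged) {
    warn("mean-CV2 gamma GLM did not converge; reporting the last iterate")
  }
  cf <- unname(stats::coef(fit))
  structure(
    list(
      a0 = cf[1], a1 = cf[2],
      deviance = stats::deviance(fit),
      iter = fit$iter, converged = fit$converged,
      n_genes = nrow(d),
      negative_fitted = any(stats::fitted(fit) <= 0),
      se = unname(sqrt(diag(stats::vcov(fit))))
    ),
    class = "mean_cv2_fit"
  )
}

#' @export
print.mean_cv2_fit <- function(x, ...) {
  cat(sprintf(
    "mean-CV2 gamma GLM fit: E[CV2] = %.4g + %.4g / mu  (n = %d, %s)\n",
    x$a0, x$a1, x$n_genes,
    if (x$converged) sprintf("converged in %d iter", x$iter) else "NOT converged"
  ))
  invisible(x)
}

#' Residual CV-squared
#'
#' Adds the fitted expectation `expected_cv2 = a0 + a1 / mu` and the
#' mean-adjusted noise `rcv2 = |cv2 - expected_cv2|` to the noise table.
#' Genes below the fit floor keep their `cv2` but get missing `rcv2`.
#'
#' @param noise Noise tibble from [gene_moments()].
#' @param fit A `mean_cv2_fit`, or a numeric vector `c(a0, a1)`.
#' @return The noise tibble with `expected_cv2` and `rcv2` columns; the
#'   coefficients are attached as attribute `"mean_cv2_fit"`.
#' @export
residual_cv2 <- function(noise, fit) {
  ab <- if (inherits(fit, "mean_cv2_fit")) c(fit$a0, fit$a1) else fit
  stopifnot(length(ab) == 2)
  out <- dplyr::mutate(
    noise,
    expected_cv2 = ifelse(.data$fit_include, ab[1] + ab[2] / .data$mu, NA_real_),
    rcv2 = abs(.data$cv2 - .data$expected_cv2)
  )
  attr(out, "mean_cv2_fit") <- ab
  out
}

#' Counts to noise table in one call
#'
#' Convenience wrapper chaining [filter_cells()], [filter_genes()],
#' [size_factors()], [gene_moments()], [fit_mean_cv2()] and
#' [residual_cv2()].
#'
#' @inheritParams filter_cells
#' @inheritParams gene_moments
#' @inheritParams size_factors
#' @param min_cell_fraction Gene detection threshold, see [filter_genes()].
#' @return A list with `noise` (the completed noise tibble), `fit` (the
#'   `mean_cv2_fit`) and `size_factors`.
#' @export
compute_noise <- function(counts, min_total = 100000, bad_cells = NULL,
                          min_cell_fraction = 0.01,
                          method = c("deconvolution", "library"),
                          pseudocount = 1, mu_floor = 0.1,
                          cv2_on = c("normalized", "log2")) {
  counts <- filter_cells(counts, min_total = min_total, bad_cells = bad_cells)
  counts <- filter_genes(counts, min_cell_fraction = min_cell_fraction)
  sf <- size_factors(counts, method = method)
  noise <- gene_moments(counts, sf,
    pseudocount = pseudocount, mu_floor = mu_floor, cv2_on = cv2_on
  )
  fit <- fit_mean_cv2(noise)
  list(noise = residual_cv2(noise, fit), fit = fit, size_factors = sf)
}
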