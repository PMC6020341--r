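#' Robust linear fit of noise on features
#'
#' M-estimation with Huber loss (tuning constant 1.345; Tukey bisquare
#' available) by iteratively reweighted least squares, scale estimated by
#' the rescaled median absolute deviation. rCV2 has a long right tail, so a
#' median-based robust fit is used instead of ordinary least squares, whose
#' zero-breakdown mean a single extreme gene can drag. Each coefficient
#' gets a two-sided t-test on n - p degrees of freedom.
#'
#' @param data A tibble holding the response and feature columns; rows with
#'   any missing value among them are dropped (listwise) with a note.
#' @param response Name of the response column (usually `"rcv2"`).
#' @param features Character vector of feature column names.
#' @param psi `"huber"` (default) or `"bisquare"`.
#' @param k Huber tuning constant (1.345 gives 95% Gaussian efficiency);
#'   for `"bisquare"` the conventional c = 4.685 is used.
#' @param maxit,acc IRLS iteration cap and convergence tolerance.
#' @return An object of class `robust_fit` with a coefficient table
#'   (`term`, `beta`, `se`, `t_stat`, `p_value`), `n`, `converged` and a
#'   robustness-weight summary. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
robust_fit <- function(data, response = "rcv2", features,
                       psi = c("huber", "bisquare"), k = 1.345,
                       maxit = 200, acc = 1e-8) {
  psi <- rlang::arg_match(psi)
  cols <- c(response, features)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste("columns not found:", paste(missing_cols, collapse = ", ")))
  }
  d <- data[, cols, drop = FALSE]
  keep <- rowSums(!is.finite(as.matrix(d))) == 0
  if (sum(!keep) > 0) {
    inform(sprintf("robust_fit: dropped %d row(s) with missing values", sum(!keep)))
  }
  d <- d[keep, , drop = FALSE]
  n <- nrow(d)
  p <- length(features) + 1L
  if (n <= p + 2) abort("too few complete rows for the requested model")

  X <- cbind(`(Intercept)` = 1, as.matrix(d[, features, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste(
      "design matrix is rank deficient; collinear column(s):",
      paste(dropped, collapse = ", ")
    ))
  }
  y <- d[[response]]

  # convergence is re-derived and reported below, so rlm's own warning is
  # muffled (it mis-fires on interpolating fits with zero residual scale)
  fit <- withCallingHandlers(
    if (psi == "huber") {
      MASS::rlm(X, y,
        psi = MASS::psi.huber, k = k, scale.est = "MAD",
        maxit = maxit, acc = acc
      )
    } else {
      MASS::rlm(X, y,
        psi = MASS::psi.bisquare, c = 4.685, scale.est = "MAD",
        maxit = maxit, acc = acc, method = "M"
      )
    },
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  converged <- fit$converged
  # an interpolating fit has zero residual scale; rlm flags it as
  # non-convergence even though the solution is exact
  if (!converged &&
    sqrt(mean(stats::residuals(fit)^2)) <= 1e-10 * (stats::sd(y) + 1e-300)) {
    converged <- TRUE
  }
  if (!converged) warn("robust_fit: IRLS did not converge; returning last iterate")

  sm <- summary(fit, method = "XtWX")$coefficients
  beta <- sm[, "Value"]
  se <- sm[, "Std. Error"]
  t_stat <- beta / se
  p_value <- 2 * stats::pt(-abs(t_stat), df = n - p)
  structure(
    list(
      coefficients = tibble(
        term = rownames(sm), beta = unname(beta), se = unname(se),
        t_stat = unname(t_stat), p_value = unname(p_value)
      ),
      n = n, df_residual = n - p, converged = converged,
      sigma = fit$s, psi = psi,
      weights = summary(fit$w)
    ),
    class = "robust_fit"
  )
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf(
    "robust linear fit (%s psi), n = %d%s\n", x$psi, x$n,
    if (x$converged) "" else ", NOT converged"
  ))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

# pull one coefficient row (no intercept) into the long screen format
screen_row <- function(fit, term, model_kind, alpha) {
  fit$coefficients |>
    dplyr::filter(.data$term %in% .env$term) |>
    dplyr::mutate(
      feature = .data$term, model_kind = model_kind, n = fit$n,
      significant = .data$p_value < alpha
    ) |>
    dplyr::select(
      "feature", "model_kind", "beta", "se", "t_stat", "p_value",
      "n", "significant"
    )
}

#' Univariate feature screen
#'
#' Regresses the mean-adjusted noise on each feature individually with a
#' robust linear model and flags coefficients significant at `alpha`
#' (0.05, uncorrected; the optional `bh` column adds
#' Benjamini-Hochberg-adjusted p-values across the screened features).
#'
#' @param noise Noise tibble carrying `gene_id` and the response column.
#' @param features Feature tibble keyed by `gene_id` (standardized columns
#'   recommended, see [build_feature_table()]).
#' @param columns Feature columns to screen; default: all numeric columns
#'   of `features` except `gene_id`.
#' @param response Response column name. Default `"rcv2"`.
#' @param alpha Per-feature significance level. Default 0.05.
#' @param bh Also report BH-adjusted p-values? Default FALSE.
#' @inheritParams robust_fit
#' @return A long tibble: `feature`, `model_kind`, `beta`, `se`, `t_stat`,
#'   `p_value`, `n`, `significant` (one row per feature).
#' @export
univariate_screen <- function(noise, features, columns = NULL,
                              response = "rcv2", alpha = 0.05, bh = FALSE,
                              psi = c("huber", "bisquare"), k = 1.345) {
  psi <- rlang::arg_match(psi)
  columns <- columns %||% setdiff(
    names(features)[vapply(features, is.numeric, logical(1))], "gene_id"
  )
  d <- dplyr::inner_join(
    noise[, c("gene_id", response)], features,
    by = "gene_id"
  )
  out <- purrr::map_dfr(columns, function(cc) {
    fit <- robust_fit(d, response = response, features = cc, psi = psi, k = k)
    screen_row(fit, cc, "univariate", alpha)
  })
  if (bh) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Multivariate feature screen
#'
#' Joint robust fit of the mean-adjusted noise on all requested features,
#' testing each coefficient for linear independence from the rest.
#'
#' @inheritParams univariate_screen
#' @param columns Feature columns entering the joint model (must be jointly
#'   full rank).
#' @return A long tibble as in [univariate_screen()] with
#'   `model_kind = "multivariate"`.
#' @export
multivariate_screen <- function(noise, features, columns,
                                response = "rcv2", alpha = 0.05, bh = FALSE,
                                psi = c("huber", "bisquare"), k = 1.345) {
  psi <- rlang::arg_match(psi)
  d <- dplyr::inner_join(
    noise[, c("gene_id", response)], features,
    by = "gene_id"
  )
  fit <- robust_fit(d, response = response, features = columns, psi = psi, k = k)
  out <- screen_row(fit, columns, "multivariate", alpha)
  if (bh) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Re-run the screens after excluding a gene set
#'
#' Repeats the univariate (and optionally multivariate) screens on the
#' complement of an exclusion list -- e.g. dropping developmentally
#' associated genes to check that a CpG-island association is not carried
#' by one co-regulated programme -- and tabulates before/after
#' coefficients. Feature columns that become constant on the complement are
#' dropped with a note.
#'
#' @inheritParams univariate_screen
#' @param exclude_genes Character vector of gene ids to drop.
#' @param multivariate Also refit the joint model? Default FALSE.
#' @return A list with `before`, `after` (screen tibbles) and `comparison`
#'   (features joined with `beta_before`, `beta_after`, `delta_beta`).
#' @export
subset_refit <- function(noise, features, exclude_genes, columns = NULL,
                         response = "rcv2", alpha = 0.05,
                         multivariate = FALSE) {
  columns <- columns %||% setdiff(
    names(features)[vapply(features, is.numeric, logical(1))], "gene_id"
  )
  keep <- !noise$gene_id %in% exclude_genes
  if (mean(keep) < 0.1) {
    abort("exclusion list removes more than 90% of genes")
  }
  sub_noise <- noise[keep, , drop = FALSE]
  sub_features <- features[!features$gene_id %in% exclude_genes, , drop = FALSE]
  const <- columns[vapply(
    columns,
    function(cc) {
      v <- sub_features[[cc]]
      stats::sd(v, na.rm = TRUE) %in% c(0, NA) || all(is.na(v))
    },
    logical(1)
  )]
  if (length(const) > 0) {
    inform(paste(
      "subset_refit: dropping constant column(s) on the complement:",
      paste(const, collapse = ", ")
    ))
    columns <- setdiff(columns, const)
  }
  run <- function(nz, ft) {
    out <- univariate_screen(nz, ft,
      columns = columns, response = response, alpha = alpha
    )
    if (multivariate) {
      out <- dplyr::bind_rows(out, multivariate_screen(
        nz, ft,
        columns = columns, response = response, alpha = alpha
      ))
    }
    out
  }
  before <- run(noise, features)
  after <- run(sub_noise, sub_features)
  comparison <- dplyr::inner_join(
    dplyr::select(before, "feature", "model_kind", beta_before = "beta"),
    dplyr::select(after, "feature", "model_kind", beta_after = "beta"),
    by = c("feature", "model_kind")
  ) |>
    dplyr::mutate(delta_beta = .data$beta_after - .data$beta_before)
  list(before = before, after = after, comparison = comparison)
}
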