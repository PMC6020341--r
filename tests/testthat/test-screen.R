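make_xy <- function(n = 300, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    gene_id = sprintf("g%04d", 1:n),
    x = rnorm(n), w = rnorm(n)
  )
}

test_that("robust fit reproduces exact linear data to machine precision", {
  d <- make_xy()
  d$rcv2 <- 2 + 0.5 * d$x
  fit <- robust_fit(d, features = "x")
  expect_equal(fit$coefficients$beta, c(2, 0.5), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("the Huber fit resists gross outliers where least squares fails", {
  set.seed(21)
  n <- 400
  d <- tibble::tibble(x = rnorm(n))
  d$rcv2 <- 1 - 0.5 * d$x + rnorm(n, 0, 0.1)
  bad <- sample(n, 20) # 5% contamination
  d$rcv2[bad] <- 50
  fit <- robust_fit(d, features = "x")
  slope <- fit$coefficients$beta[2]
  expect_lt(abs(slope - (-0.5)), 0.05)
  ols <- coef(lm(rcv2 ~ x, data = d))[2]
  expect_gt(abs(ols - (-0.5)), 0.2)
})

test_that("rank-deficient designs are rejected naming the columns", {
  d <- make_xy()
  d$rcv2 <- rnorm(nrow(d))
  d$x_copy <- d$x
  expect_error(
    robust_fit(d, features = c("x", "x_copy")),
    "x_copy"
  )
  # constant column duplicates the intercept
  d$konst <- 1
  expect_error(robust_fit(d, features = "konst"), "konst")
})

test_that("a huge Huber constant converges to ordinary least squares", {
  set.seed(3)
  d <- make_xy(150)
  d$rcv2 <- 0.3 + 1.2 * d$x + rnorm(150, 0, 0.5)
  fit <- robust_fit(d, features = "x", k = 1e6)
  ols <- unname(coef(lm(rcv2 ~ x, data = d)))
  expect_equal(fit$coefficients$beta, ols, tolerance = 1e-6)
})

test_that("coefficients are equivariant under feature rescaling", {
  set.seed(5)
  d <- make_xy(200)
  d$rcv2 <- 1 + 0.4 * d$x + rnorm(200, 0, 0.3)
  b1 <- robust_fit(d, features = "x")$coefficients$beta[2]
  d$x <- 2 * d$x
  b2 <- robust_fit(d, features = "x")$coefficients$beta[2]
  expect_equal(b2, b1 / 2, tolerance = 1e-6)
})

test_that("single-column multivariate fit matches the univariate screen", {
  set.seed(6)
  d <- make_xy(250)
  noise <- tibble::tibble(
    gene_id = d$gene_id, rcv2 = 1 + 0.2 * d$x + rnorm(250, 0, 0.2)
  )
  uni <- quietly(univariate_screen(noise, d, columns = "x"))
  multi <- quietly(multivariate_screen(noise, d, columns = "x"))
  expect_equal(nrow(uni), 1)
  expect_equal(uni$beta, multi$beta, tolerance = 1e-10)
  expect_equal(uni$p_value, multi$p_value, tolerance = 1e-10)
})

test_that("two independent planted effects are jointly recovered", {
  set.seed(7)
  d <- make_xy(500)
  noise <- tibble::tibble(
    gene_id = d$gene_id,
    rcv2 = 1 + 0.3 * d$x - 0.4 * d$w + rnorm(500, 0, 0.2)
  )
  multi <- quietly(multivariate_screen(noise, d, columns = c("x", "w")))
  expect_gt(multi$beta[multi$feature == "x"], 0)
  expect_lt(multi$beta[multi$feature == "w"], 0)
  expect_true(all(multi$significant))
})

test_that("a noisy proxy is attenuated once the causal feature is modelled", {
  set.seed(8)
  d <- make_xy(800)
  d$proxy <- d$x + rnorm(800, 0, 0.6)
  noise <- tibble::tibble(
    gene_id = d$gene_id, rcv2 = 1 + 0.5 * d$x + rnorm(800, 0, 0.3)
  )
  uni <- quietly(univariate_screen(noise, d, columns = c("x", "proxy")))
  multi <- quietly(multivariate_screen(noise, d, columns = c("x", "proxy")))
  b_uni <- uni$beta[uni$feature == "proxy"]
  b_multi <- multi$beta[multi$feature == "proxy"]
  expect_lt(abs(b_multi), abs(b_uni))
  expect_true(multi$significant[multi$feature == "x"])
})

test_that("rows with missing feature values are dropped listwise", {
  set.seed(9)
  d <- make_xy(100)
  noise <- tibble::tibble(
    gene_id = d$gene_id, rcv2 = 1 + 0.3 * d$x + rnorm(100, 0, 0.2)
  )
  d$x[1:10] <- NA
  sc <- quietly(univariate_screen(noise, d, columns = c("x", "w")))
  expect_equal(sc$n[sc$feature == "x"], 90)
  expect_equal(sc$n[sc$feature == "w"], 100)
})

test_that("subset refits reproduce the full screen on empty exclusions", {
  set.seed(10)
  d <- make_xy(300)
  noise <- tibble::tibble(
    gene_id = d$gene_id, rcv2 = 1 - 0.3 * d$x + rnorm(300, 0, 0.2)
  )
  res <- quietly(subset_refit(noise, d, exclude_genes = character(0)))
  expect_equal(res$before$beta, res$after$beta, tolerance = 1e-12)
  expect_true(all(res$comparison$delta_beta == 0))

  # constant columns on the complement are dropped with a note
  d$flag <- as.numeric(seq_len(300) <= 150)
  excl <- d$gene_id[d$flag == 1]
  expect_message(
    res2 <- quietly2 <- suppressWarnings(
      subset_refit(noise, d, exclude_genes = excl, columns = c("x", "flag"))
    ),
    "constant"
  )
  expect_false("flag" %in% res2$after$feature)

  expect_error(
    quietly(subset_refit(noise, d, exclude_genes = d$gene_id[1:280])),
    "90%"
  )

  # a planted effect independent of the excluded set keeps its sign
  res3 <- quietly(subset_refit(noise, d,
    exclude_genes = sample(d$gene_id, 100), columns = "x"
  ))
  expect_lt(res3$after$beta[res3$after$feature == "x"], 0)
})

test_that("tidy and glance expose robust fits in broom vocabulary", {
  d <- make_xy(120)
  d$rcv2 <- 2 + 0.5 * d$x
  fit <- robust_fit(d, features = "x")
  td <- tidy(fit)
  expect_named(
    td, c("term", "estimate", "std.error", "statistic", "p.value")
  )
  gl <- glance(fit)
  expect_equal(gl$n, 120)
  expect_equal(gl$psi, "huber")
})
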