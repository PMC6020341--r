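grid2 <- function(v) {
  tibble::tibble(
    chrom = "chr1", start = c(0L, 200L), end = c(200L, 400L), value = v
  )
}

test_that("fold enrichment is zero for identical libraries and ~2 at 4x", {
  eq <- fold_enrichment(grid2(c(500, 500)), grid2(c(500, 500)))
  expect_equal(eq$value, c(0, 0))
  # one window at 4x the input, equal depths, large counts
  fe <- fold_enrichment(grid2(c(80000, 20000)), grid2(c(20000, 80000)))
  expect_equal(fe$value[1], 2, tolerance = 1e-3)
  # pseudocount guard: 0/0 windows sit at 0
  z <- fold_enrichment(grid2(c(0, 1000)), grid2(c(0, 1000)))
  expect_equal(z$value[1], 0)
  # mismatched grids are rejected
  other <- grid2(c(1, 1))
  other$start <- other$start + 50L
  other$end <- other$end + 50L
  expect_error(fold_enrichment(grid2(c(1, 1)), other), "grid")
})

test_that("promoter signal averages overlapping windows, then replicates", {
  pr <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+", tss = 500,
    start = 100, end = 700, clipped = FALSE
  )
  tr <- tibble::tibble(
    chrom = "chr1", start = c(0, 200, 400, 600, 800),
    end = c(200, 400, 600, 800, 1000), value = c(1, 2, 3, 10, 99)
  )
  # promoter [100,700) overlaps windows [0,200),[200,400),[400,600),[600,800)
  got <- quietly(promoter_signal(tr, pr))
  expect_equal(got$signal, mean(c(1, 2, 3, 10)))

  # replicate averaging: replicate means 2 and 4 -> 3
  tr2 <- dplyr::bind_rows(
    dplyr::mutate(tr, value = 2, replicate = 1L),
    dplyr::mutate(tr, value = 4, replicate = 2L)
  )
  got2 <- quietly(promoter_signal(tr2, pr))
  expect_equal(got2$signal, 3)

  # a 1500-bp promoter starting at 0 touches exactly 8 windows
  pr8 <- dplyr::mutate(pr, start = 0, end = 1500)
  tr8 <- tibble::tibble(
    chrom = "chr1", start = seq(0, 1400, 200), end = seq(200, 1600, 200),
    value = 1:8
  )
  got8 <- quietly(promoter_signal(tr8, pr8))
  expect_equal(got8$signal, mean(1:8))

  # promoters with no windows give missing values, with a note
  pr_off <- dplyr::mutate(pr, chrom = "chrM")
  expect_message(off <- promoter_signal(tr, pr_off), "no window")
  expect_true(is.na(off$signal))
})

test_that("the KDE valley threshold lands between two well-separated modes", {
  set.seed(12)
  n <- 600
  k4 <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    signal = c(rnorm(n / 2, 0, 0.5), rnorm(n / 2, 4, 0.5))
  )
  k27 <- tibble::tibble(gene_id = k4$gene_id, signal = rexp(n, 5))
  cl <- quietly(classify_bivalency(k4, k27))
  thr <- chromatin_thresholds(cl)
  expect_gt(thr$k4_threshold, 1.5)
  expect_lt(thr$k4_threshold, 2.5)
  expect_equal(thr$k27_threshold, mean(k27$signal))
})

test_that("strong double-positive signals are called bivalent", {
  k4 <- tibble::tibble(gene_id = c("a", "b"), signal = c(20, 0.1))
  k27 <- tibble::tibble(gene_id = c("a", "b"), signal = c(15, 0.1))
  cl <- quietly(classify_bivalency(k4, k27,
    k4_threshold = 2, k27_threshold = 1.5
  ))
  expect_equal(cl$class[cl$gene_id == "a"], "bivalent")
  expect_equal(cl$class[cl$gene_id == "b"], "low")
})

test_that("degenerate unimodal signals hit the guided error path", {
  k4 <- tibble::tibble(gene_id = sprintf("g%03d", 1:300), signal = 0)
  k27 <- tibble::tibble(gene_id = k4$gene_id, signal = 0)
  expect_error(quietly(classify_bivalency(k4, k27)), "k4_threshold")
  expect_error(
    classify_bivalency(k4[1:50, ], k27[1:50, ]),
    "threshold estimation"
  )
})

test_that("every gene with both signals gets exactly one class", {
  set.seed(13)
  cfg <- sim_config()
  ann <- simulate_annotations(300, cfg, seed = 13)
  chip <- quietly(simulate_chip(ann$promoters, ann$truth, cfg, seed = 14))
  k4 <- quietly(promoter_signal(chip$k4, ann$promoters))
  k27 <- quietly(promoter_signal(chip$k27, ann$promoters))
  cl <- quietly(classify_bivalency(k4, k27))
  expect_equal(nrow(cl), 300)
  expect_true(all(cl$class %in% c("active", "repressed", "bivalent", "low")))
})

test_that("a common K27 shift moves only the mean threshold (multiplier 1)", {
  set.seed(14)
  n <- 400
  k4 <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    signal = c(rnorm(n / 2, 0, 0.4), rnorm(n / 2, 4, 0.4))
  )
  k27 <- tibble::tibble(gene_id = k4$gene_id, signal = rnorm(n, 2, 1))
  cl1 <- quietly(classify_bivalency(k4, k27, multiplier = 1))
  k27b <- dplyr::mutate(k27, signal = signal + 5)
  cl2 <- quietly(classify_bivalency(k4, k27b, multiplier = 1))
  expect_equal(
    chromatin_thresholds(cl2)$k27_threshold,
    chromatin_thresholds(cl1)$k27_threshold + 5
  )
  expect_identical(cl1$class, cl2$class)
})

test_that("category regression needs contrasts and a repressed reference", {
  noise <- tibble::tibble(gene_id = c("a", "b", "c"), rcv2 = c(1, 2, 3))
  cgi <- tibble::tibble(gene_id = noise$gene_id, cgi_size_bp = c(0, 500, 800))
  all_one <- tibble::tibble(gene_id = noise$gene_id, class = "active")
  expect_error(category_regression(noise, all_one, cgi), "2 promoter classes")
  no_ref <- tibble::tibble(
    gene_id = noise$gene_id, class = c("active", "low", "active")
  )
  expect_error(category_regression(noise, no_ref, cgi), "repressed")
})
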