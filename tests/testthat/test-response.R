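test_that("time-series filters apply exclusive boundaries", {
  ts <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    s1 = c(1, 1, 0), s2 = c(1, 1, 0), s3 = c(1, 1, 0), s4 = c(0, 1, 0)
  )
  # feature a detected in exactly 75% of samples -> removed
  cage <- quietly(filter_timeseries(ts, "cage", sample_cols = paste0("s", 1:4)))
  expect_equal(cage$gene_id, "b")
  rs <- tibble::tibble(
    gene_id = c("a", "b"),
    s1 = c(5, 6), s2 = c(5, 6), s3 = c(5, 5)
  )
  # mean exactly 5 -> removed (strict >)
  rna <- quietly(filter_timeseries(rs, "rnaseq", sample_cols = paste0("s", 1:3)))
  expect_equal(rna$gene_id, "b")
  expect_error(
    filter_timeseries(ts, "caeg", sample_cols = paste0("s", 1:4))
  )
})

test_that("islands are assigned to peaks within a 500-bp centred window", {
  peaks <- tibble::tibble(peak_id = "p1", chrom = "chr1", pos = 1000)
  isl <- function(s, e) {
    tibble::tibble(
      chrom = "chr1", start = s, end = e,
      name = "i", length_bp = e - s
    )
  }
  # window [750, 1250): island [1200,1500) overlaps 50 bp -> assigned, 300 bp
  hit <- quietly(assign_cgi_to_peaks(peaks, isl(1200, 1500)))
  expect_true(hit$cgi_overlap)
  expect_equal(hit$cgi_size_bp, 300)
  miss <- quietly(assign_cgi_to_peaks(peaks, isl(1300, 1500)))
  expect_false(miss$cgi_overlap)
  # two candidates with equal overlap: longer island wins
  two <- rbind(isl(700, 800), isl(1200, 1600))
  tie <- quietly(assign_cgi_to_peaks(peaks, two))
  expect_equal(tie$cgi_size_bp, 400)
})

test_that("naive log2 fold changes follow the pseudocount formula", {
  counts <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    t0_r1 = c(10, 7, 0), t0_r2 = c(10, 7, 0),
    t1_r1 = c(40, 7, 0), t1_r2 = c(40, 7, 0)
  )
  tp <- c(0, 0, 1, 1)
  fc0 <- naive_log2fc(counts, tp, pseudocount = 0)
  expect_equal(fc0$fc_0v1[1], 2) # 10 -> 40
  fc1 <- naive_log2fc(counts, tp, pseudocount = 1)
  expect_equal(fc1$fc_0v1[2], 0) # equal means
  expect_equal(fc1$fc_0v1[3], 0) # 0/0 with pseudocount
  bad <- counts
  bad$t0_r1[1] <- -2
  expect_error(naive_log2fc(bad, tp), "negative")
})

test_that("enrichment matches the exact binomial tail in closed form", {
  # construct 8 island genes where every early island is the smaller one
  ts <- tibble::tibble(
    gene_id = sprintf("g%d", 1:16),
    cgi_size_bp = c(seq(200, 900, 100), seq(2000, 2700, 100)),
    fc_0v1 = c(rep(2, 8), rep(-2, 8)), # small islands top the early list
    fc_1v2 = c(rep(-2, 8), rep(2, 8)) # large islands top the late list
  )
  enr <- quietly(cgi_size_enrichment(ts, "fc_0v1", "fc_1v2", top_n = 8))
  expect_equal(enr$n_pairs, 8)
  expect_equal(enr$n_early_smaller, 8)
  expect_equal(enr$p_one_tailed, 0.5^8)
  expect_equal(enr$direction, "short_early")
  expect_equal(enr$p_one_tailed, oracle_binom_tail(8, 8))
})

test_that("ties are excluded and identical rankings are rejected", {
  ts <- tibble::tibble(
    gene_id = sprintf("g%d", 1:10),
    cgi_size_bp = rep(500, 10),
    fc_0v1 = 10:1, fc_1v2 = 10:1
  )
  expect_error(
    quietly(cgi_size_enrichment(ts, "fc_0v1", "fc_1v2", top_n = 10)),
    "ties"
  )
})

test_that("swapping early and late flips direction and maps k to n - k", {
  set.seed(31)
  n <- 80
  ts <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    cgi_size_bp = sample(200:3000, n),
    fc_0v1 = rnorm(n), fc_1v2 = rnorm(n)
  )
  fwd <- quietly(cgi_size_enrichment(ts, "fc_0v1", "fc_1v2", top_n = 50))
  rev <- quietly(cgi_size_enrichment(ts, "fc_1v2", "fc_0v1", top_n = 50))
  expect_equal(rev$n_pairs, fwd$n_pairs)
  expect_equal(rev$n_early_smaller, fwd$n_pairs - fwd$n_early_smaller)
  if (fwd$n_early_smaller / fwd$n_pairs != 0.5) {
    expect_false(rev$direction == fwd$direction)
  }
})

test_that("top_n beyond the ranked list truncates with a warning", {
  ts <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6),
    cgi_size_bp = c(300, 400, 500, 0, 0, 600),
    fc_0v1 = c(3, 2, 1, 5, 5, -1), fc_1v2 = c(-1, 1, 3, 5, 5, 2)
  )
  expect_warning(
    enr <- suppressMessages(
      cgi_size_enrichment(ts, "fc_0v1", "fc_1v2", top_n = 250)
    ),
    "exceeds"
  )
  expect_equal(enr$top_n, 4) # only island-bearing genes are ranked
})

test_that("identical populations give no-change labels that partition", {
  set.seed(32)
  m <- toy_counts(matrix(rpois(200 * 50, 20), nrow = 200))
  m2 <- m
  colnames(m2) <- paste0("s_", colnames(m2))
  lab <- label_response(m, m2)
  expect_equal(nrow(lab), 200)
  expect_true(all(lab$label == "nochange"))
  expect_true(all(table(lab$label) == c(nochange = 200)))
})

test_that("a planted mean shift is labelled up in most shifted genes", {
  set.seed(33)
  n <- 600
  base <- rlnorm(n, log(20), 1)
  unstim <- toy_counts(
    matrix(rnbinom(n * 200, mu = base, size = 5), nrow = n)
  )
  shifted <- base
  shifted[1:100] <- shifted[1:100] * 2
  stim <- toy_counts(
    matrix(rnbinom(n * 200, mu = shifted, size = 5), nrow = n),
    cells = sprintf("s%03d", 1:200)
  )
  lab <- label_response(unstim, stim)
  expect_gte(sum(lab$label[1:100] == "up"), 80)
  # labels partition the shared gene universe
  expect_equal(sum(table(lab$label)), n)
})

test_that("island-size binning uses floor(size / width)", {
  noise <- tibble::tibble(
    gene_id = c("a", "b", "c"), cv2 = c(1, 1, 1), rcv2 = c(1, 1, 1)
  )
  labs <- tibble::tibble(gene_id = noise$gene_id, label = "up")
  cgi <- tibble::tibble(
    gene_id = noise$gene_id, cgi_size_bp = c(100, 600, 1100)
  )
  nvr <- noise_vs_response(noise, labs, cgi, min_bin = 1)
  expect_equal(sort(nvr$bins$bin), c(0, 1, 2))
  expect_equal(sort(nvr$bins$bin_start), c(0, 500, 1000))
})

test_that("an upward noise shift in up-labelled genes is detected by KS", {
  set.seed(34)
  n <- 400
  noise <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    cv2 = c(rexp(n / 2, 1) + 1, rexp(n / 2, 1)), # up genes shifted by +1
    rcv2 = NA_real_
  )
  labs <- tibble::tibble(
    gene_id = noise$gene_id,
    label = rep(c("up", "nochange"), each = n / 2)
  )
  cgi <- tibble::tibble(
    gene_id = noise$gene_id, cgi_size_bp = rep(c(300, 800, 1300, 0), n / 4)
  )
  nvr <- noise_vs_response(noise, labs, cgi)
  p <- nvr$ks$p_value[nvr$ks$stratum == "cgi" &
    nvr$ks$comparison == "up_vs_nochange"]
  expect_lt(p, 0.01)
})

test_that("enrichment results tidy into a one-row table", {
  set.seed(35)
  ts <- simulate_timeseries(
    sprintf("g%03d", 1:300),
    ifelse(runif(300) < 0.6, sample(200:3000, 300, TRUE), 0),
    effect = 2, seed = 36
  )
  enr <- quietly(cgi_size_enrichment(ts, "fc_0v1", "fc_1v2", top_n = 100))
  td <- tidy(enr)
  expect_equal(nrow(td), 1)
  expect_equal(td$n_pairs, enr$n_pairs)
  expect_identical(tidy(enr), glance(enr))
})
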