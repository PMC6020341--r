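# shared fixtures and independent oracles, all built in code

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

# a small labelled count matrix
toy_counts <- function(x, genes = NULL, cells = NULL) {
  m <- as.matrix(x)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- cells %||% sprintf("c%02d", seq_len(ncol(m)))
  storage.mode(m) <- "double"
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# gene-model tibble builder (0-based half-open)
gm_row <- function(type, gene, chrom, start, end, strand, tx = NA) {
  tibble::tibble(
    type = type, gene_id = gene, transcript_id = tx,
    chrom = chrom, start = start, end = end, strand = strand
  )
}

# brute-force per-gene moments, written as explicit loops so they stay
# independent of the vectorised implementation
oracle_moments <- function(counts, s, pseudocount = 1,
                           cv2_on = c("normalized", "log2")) {
  cv2_on <- match.arg(cv2_on)
  n_genes <- nrow(counts)
  m <- ncol(counts)
  out <- data.frame(
    mu = numeric(n_genes), var_hat = numeric(n_genes),
    cv2 = numeric(n_genes)
  )
  for (i in seq_len(n_genes)) {
    norm <- numeric(m)
    for (j in seq_len(m)) norm[j] <- counts[i, j] / s[j]
    mean_norm <- sum(norm) / m
    out$mu[i] <- log2(mean_norm)
    x <- if (cv2_on == "log2") log2(norm + pseudocount) else norm
    xbar <- sum(x) / m
    v <- 0
    for (j in seq_len(m)) v <- v + (x[j] - xbar)^2
    v <- v / (m - 1)
    out$var_hat[i] <- v
    out$cv2[i] <- if (cv2_on == "log2") v / out$mu[i]^2 else v / mean_norm^2
  }
  out
}

# exact upper binomial tail P(X >= k | n, 1/2) by explicit summation
oracle_binom_tail <- function(k, n) {
  if (k <= 0) {
    return(1)
  }
  total <- 0
  for (j in k:n) total <- total + choose(n, j) * 0.5^n
  total
}

# independently coded paired-sample sign test on rank-matched top lists
oracle_sign_test <- function(fc_early, fc_late, sizes, top_n) {
  keep <- sizes > 0 & is.finite(fc_early) & is.finite(fc_late)
  fe <- fc_early[keep]
  fl <- fc_late[keep]
  sz <- sizes[keep]
  top_n <- min(top_n, sum(keep))
  e <- sz[order(fe, decreasing = TRUE)][seq_len(top_n)]
  l <- sz[order(fl, decreasing = TRUE)][seq_len(top_n)]
  diff <- e - l
  diff <- diff[diff != 0]
  k <- sum(diff < 0)
  list(n_pairs = length(diff), k = k, p = oracle_binom_tail(k, length(diff)))
}
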