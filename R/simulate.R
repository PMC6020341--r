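#' Simulation parameters
#'
#' Collects the parameters of the synthetic-data generators in one list.
#' Counts are negative binomial with a mean drawn per gene from a
#' log-normal. The dispersion emulates the structure of real single-cell
#' data: every gene carries a baseline (technical-plus-housekeeping)
#' dispersion with its own feature-independent log-normal spread, and a
#' minority of genes carry a right-skewed biological excess on top,
#' `phi_i = phi_floor * exp(eta_i) + B_i * exp(phi0 + e_i + eps_i)`,
#' where `eta_i ~ N(0, floor_sd)`, `B_i ~ Bernoulli(p_i)` marks the
#' biologically noisy genes, `eps_i ~ N(0, bio_sd)`, and the planted
#' feature effect
#' `e_i = beta_cgi * cgi_size_kb + beta_bivalent * I(bivalent) +
#' beta_early * I(early responder)` acts on both channels of the excess:
#' its log magnitude and the log odds of being noisy,
#' `logit(p_i) = logit(noisy_fraction) + e_i`. A damping feature thus
#' makes fewer genes noisy and makes the noisy ones quieter, while the
#' baseline bulk stays feature-independent -- the geometry that lets a
#' residual-noise screen see planted effects. Planting effects on the
#' dispersion rather than the variance decouples mean and noise. With
#' `noisy_fraction = 0` and `floor_sd = 0` every dispersion is exactly
#' `phi_floor`; with `noisy_fraction = 1`, `floor_sd = 0` and `bio_sd = 0`
#' the excess collapses to the exact `phi_floor + exp(phi0 + e_i)` form.
#'
#' Defaults describe the demo scenario: roughly 60% of promoters carry a CpG
#' island (log-normal sizes, 200 bp to 10 kb), larger islands damp
#' dispersion, bivalent promoters carry a four-fold dispersion excess, and
#' early-responder genes are noisier before stimulation.
#'
#' @param mean_log Mean of log true expression (natural log scale).
#' @param mean_sdlog SD of log true expression.
#' @param phi0 Median log biological excess dispersion of a noisy,
#'   feature-free gene; `exp(phi0)` is its excess at `eps = 0`.
#' @param phi_floor Median baseline dispersion shared by all genes.
#' @param floor_sd SD of the per-gene log baseline dispersion
#'   (feature-independent).
#' @param bio_sd SD of the per-gene log biological excess (right-skewed
#'   gene-to-gene noise heterogeneity among noisy genes).
#' @param noisy_fraction Baseline probability that a feature-free gene
#'   carries biological excess at all.
#' @param effect_cgi_size Additive effect on log-dispersion per kb of CpG
#'   island; negative means larger islands are less noisy.
#' @param effect_bivalent Additive effect on log-dispersion for bivalent
#'   promoters (`log(4)` plants a four-fold excess).
#' @param effect_early Additive effect on log-dispersion for early-responder
#'   genes.
#' @param sf_sdlog SD of log cell scaling factors (log-normal, geometric
#'   mean 1).
#' @param cgi_fraction Fraction of genes whose promoter overlaps an island.
#' @param cgi_meanlog,cgi_sdlog Log-normal parameters of island size (bp).
#' @param cgi_min_bp,cgi_max_bp Truncation bounds on island size.
#' @param class_weights Named mixture weights over promoter classes
#'   `active`, `repressed`, `bivalent`, `low`.
#' @param early_fraction Fraction of genes that are early responders.
#' @param gene_spacing Distance between consecutive TSSs on a synthetic
#'   chromosome (bp).
#' @param n_chroms Number of synthetic chromosomes.
#' @param chrom_length Optional fixed chromosome length (bp); by default
#'   chromosomes are sized to fit the genes. If given and too short to place
#'   all promoters, generation fails.
#' @param k4_high,k4_low,k4_mode_sd H3K4me3 promoter-level modes (log2
#'   enrichment) for {active, bivalent} vs {repressed, low} and their SD.
#' @param k27_high,k27_mode_sd,k27_bg_mean H3K27me3 elevated mode and SD
#'   for {repressed, bivalent}; background is exponential with the given
#'   mean.
#' @param window_sd SD of per-window noise around the promoter-level signal.
#' @param n_replicates ChIP replicates per mark.
#' @param fc_sd SD of per-comparison log2 fold changes in the time-series
#'   generator.
#' @return a named list of parameters.
#' @export
sim_config <- function(mean_log = log(50), mean_sdlog = 1,
                       phi0 = log(0.4),
                       phi_floor = 0.15, floor_sd = 0.6, bio_sd = 0.8,
                       noisy_fraction = 0.3,
                       effect_cgi_size = -1,
                       effect_bivalent = log(4),
                       effect_early = 1,
                       sf_sdlog = 0.2,
                       cgi_fraction = 0.6,
                       cgi_meanlog = log(700), cgi_sdlog = 0.7,
                       cgi_min_bp = 200, cgi_max_bp = 10000,
                       class_weights = c(
                         active = 0.4, repressed = 0.2,
                         bivalent = 0.2, low = 0.2
                       ),
                       early_fraction = 0.1,
                       gene_spacing = 12000,
                       n_chroms = 4,
                       chrom_length = NULL,
                       k4_high = 4, k4_low = 0, k4_mode_sd = 0.4,
                       k27_high = 3, k27_mode_sd = 0.3, k27_bg_mean = 0.2,
                       window_sd = 0.3,
                       n_replicates = 2,
                       fc_sd = 1) {
  cfg <- as.list(environment())
  if (!is.finite(cfg$phi0) || cfg$phi_floor < 0 || cfg$bio_sd < 0 ||
    cfg$floor_sd < 0) {
    abort("dispersion parameters must be finite and non-negative")
  }
  if (cfg$phi_floor + exp(cfg$phi0) <= 0) {
    abort("baseline dispersion must be positive")
  }
  if (cfg$noisy_fraction < 0 || cfg$noisy_fraction > 1) {
    abort("`noisy_fraction` must lie in [0, 1]")
  }
  if (cfg$cgi_fraction < 0 || cfg$cgi_fraction > 1) {
    abort("`cgi_fraction` must lie in [0, 1]")
  }
  stopifnot(abs(sum(cfg$class_weights) - 1) < 1e-8)
  cfg
}

# draw the per-gene ground truth shared by the generators
draw_truth <- function(n_genes, cfg) {
  gene_id <- sprintf("gene_%05d", seq_len(n_genes))
  true_mean <- stats::rlnorm(n_genes, cfg$mean_log, cfg$mean_sdlog)
  has_cgi <- stats::runif(n_genes) < cfg$cgi_fraction
  size <- round(stats::rlnorm(n_genes, cfg$cgi_meanlog, cfg$cgi_sdlog))
  size <- pmin(pmax(size, cfg$cgi_min_bp), cfg$cgi_max_bp)
  cgi_size_bp <- ifelse(has_cgi, size, 0L)
  promoter_class <- sample(names(cfg$class_weights),
    size = n_genes, replace = TRUE, prob = cfg$class_weights
  )
  early_responder <- stats::runif(n_genes) < cfg$early_fraction
  planted <- cfg$effect_cgi_size * cgi_size_bp / 1000 +
    cfg$effect_bivalent * (promoter_class == "bivalent") +
    cfg$effect_early * early_responder
  p_noisy <- stats::plogis(stats::qlogis(cfg$noisy_fraction) + planted)
  p_noisy[cfg$noisy_fraction %in% c(0, 1)] <- cfg$noisy_fraction
  noisy <- stats::runif(n_genes) < p_noisy
  baseline <- cfg$phi_floor * exp(stats::rnorm(n_genes, 0, cfg$floor_sd))
  log_excess <- cfg$phi0 + planted + stats::rnorm(n_genes, 0, cfg$bio_sd)
  tibble(
    gene_id = gene_id,
    true_mean = true_mean,
    true_dispersion = baseline + noisy * exp(log_excess),
    cgi_size_bp = as.integer(cgi_size_bp),
    noise_effect = planted,
    promoter_class = promoter_class,
    early_responder = early_responder
  )
}

#' Simulate a single-cell count matrix with known ground truth
#'
#' Counts are `c_ij ~ NB(mean = s_j * m_i, dispersion = phi_i)` with the
#' gene dispersion `phi_i` carrying the planted feature effects
#' (see [sim_config()]) and cell scaling factors `s_j` log-normal with
#' geometric mean 1.
#'
#' @param n_genes,n_cells Matrix dimensions (`n_genes >= 2`,
#'   `n_cells >= 10`).
#' @param cfg Parameters from [sim_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param truth Optional truth tibble from an earlier call; when given, the
#'   same genes (means, dispersions, features) generate a fresh matrix --
#'   e.g. a second cell population, possibly after editing `true_mean`.
#' @return A list with `counts` (genes x cells integer matrix), `truth`
#'   (per-gene ground-truth tibble) and `size_factors_true` (the planted
#'   `s_j`).
#' @export
simulate_counts <- function(n_genes, n_cells, cfg = sim_config(), seed = 1L,
                            truth = NULL) {
  if (n_genes < 2 || n_cells < 10) {
    abort("need n_genes >= 2 and n_cells >= 10")
  }
  set.seed(seed)
  if (is.null(truth)) {
    truth <- draw_truth(n_genes, cfg)
  } else if (nrow(truth) != n_genes) {
    abort("`truth` and `n_genes` disagree")
  }
  s <- rescale_geomean(stats::rlnorm(n_cells, 0, cfg$sf_sdlog))
  mu <- outer(truth$true_mean, s)
  size <- 1 / truth$true_dispersion
  counts <- matrix(
    if (any(is.infinite(size))) {
      # zero dispersion: NB degenerates to Poisson
      ifelse(is.infinite(rep(size, n_cells)),
        stats::rpois(n_genes * n_cells, mu),
        stats::rnbinom(n_genes * n_cells, mu = mu, size = rep(size, n_cells))
      )
    } else {
      stats::rnbinom(n_genes * n_cells, mu = mu, size = rep(size, n_cells))
    },
    nrow = n_genes,
    dimnames = list(truth$gene_id, sprintf("cell_%05d", seq_len(n_cells)))
  )
  list(counts = counts, truth = truth, size_factors_true = s)
}

#' Simulate gene models, promoters and CpG islands
#'
#' Places one gene per TSS slot on synthetic chromosomes, non-overlapping,
#' and gives every CGI-positive gene one island centred on its TSS so the
#' island always overlaps the promoter. Gene-structure features (exon count,
#' exon lengths) are drawn and written as exon records so annotation readers
#' round-trip them.
#'
#' @inheritParams simulate_counts
#' @param truth Optional truth tibble from [simulate_counts()]; when given,
#'   its planted `cgi_size_bp` values are reused so that counts and
#'   annotations describe the same genes.
#' @return A list with `gene_models` (GTF-style tibble), `promoters`,
#'   `islands`, `features` (planted per-gene features) and `truth`.
#' @export
simulate_annotations <- function(n_genes, cfg = sim_config(), seed = 1L,
                                 truth = NULL) {
  set.seed(seed)
  if (is.null(truth)) truth <- draw_truth(n_genes, cfg)
  if (nrow(truth) != n_genes) abort("`truth` and `n_genes` disagree")

  per_chrom <- ceiling(n_genes / cfg$n_chroms)
  margin <- max(cfg$cgi_max_bp, 2000)
  needed <- per_chrom * cfg$gene_spacing + 2 * margin
  chrom_length <- cfg$chrom_length %||% needed
  if (chrom_length < needed) {
    abort(sprintf(
      "chromosome length %d too short to place %d promoters (need %d)",
      chrom_length, per_chrom, needed
    ))
  }

  idx <- seq_len(n_genes) - 1L
  chrom <- sprintf("chrS%d", idx %/% per_chrom + 1L)
  slot <- idx %% per_chrom
  tss <- margin + slot * cfg$gene_spacing
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)

  # gene structure: exon lengths sum to the transcript length
  transcript_length <- pmin(
    pmax(200L, round(stats::rlnorm(n_genes, log(2000), 0.8))), 8000L
  )
  n_exons <- 1L + stats::rpois(n_genes, 6)
  exon_tbl <- purrr::map_dfr(seq_len(n_genes), function(i) {
    k <- n_exons[i]
    w <- as.vector(stats::rmultinom(1, transcript_length[i] - k, rep(1, k))) + 1L
    intron <- 200L
    if (strand[i] == "+") {
      st <- tss[i] + cumsum(c(0L, head(w, -1) + intron))
      en <- st + w
    } else {
      en <- tss[i] - cumsum(c(0L, head(w, -1) + intron))
      st <- en - w
    }
    tibble(
      type = "exon", gene_id = truth$gene_id[i],
      transcript_id = paste0("t_", truth$gene_id[i]),
      chrom = chrom[i], start = pmin(st, en), end = pmax(st, en),
      strand = strand[i]
    )
  })
  gene_tbl <- exon_tbl |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      type = "gene", transcript_id = NA_character_,
      chrom = .data$chrom[1], start = min(.data$start),
      end = max(.data$end), strand = .data$strand[1],
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(names(exon_tbl)))
  gene_models <- dplyr::bind_rows(gene_tbl, exon_tbl) |>
    dplyr::arrange(.data$chrom, .data$start)

  promoters <- define_promoters(gene_models)

  with_cgi <- truth$cgi_size_bp > 0
  islands <- tibble(
    chrom = chrom[with_cgi],
    start = as.integer(tss[with_cgi] - truth$cgi_size_bp[with_cgi] %/% 2),
    end = NA_integer_,
    name = paste0("cgi_", truth$gene_id[with_cgi])
  )
  islands$start <- pmax(islands$start, 0L)
  islands$end <- islands$start + truth$cgi_size_bp[with_cgi]
  islands$length_bp <- islands$end - islands$start
  islands <- dplyr::arrange(islands, .data$chrom, .data$start)

  features <- tibble(
    gene_id = truth$gene_id,
    cgi_overlap = with_cgi,
    cgi_size_bp = truth$cgi_size_bp,
    transcript_length_bp = as.numeric(transcript_length),
    n_exons = as.numeric(n_exons),
    mean_exon_length_bp = transcript_length / n_exons
  )

  list(
    gene_models = gene_models, promoters = promoters,
    islands = islands, features = features, truth = truth
  )
}

#' Simulate chromosome sequences with GC-enriched islands
#'
#' Background base composition is 40% GC; within CpG islands it is raised to
#' 65%, so promoter GC content correlates with island presence as in real
#' genomes.
#'
#' @param annotations Output of [simulate_annotations()].
#' @param seed Integer seed.
#' @param gc_background,gc_island GC fractions outside/inside islands.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_genome_fasta <- function(annotations, seed = 1L,
                                  gc_background = 0.4, gc_island = 0.65) {
  set.seed(seed)
  chroms <- unique(annotations$gene_models$chrom)
  lens <- vapply(chroms, function(ch) {
    max(
      annotations$gene_models$end[annotations$gene_models$chrom == ch],
      annotations$promoters$end[annotations$promoters$chrom == ch]
    ) + 1000L
  }, integer(1))
  p_bg <- c(
    A = (1 - gc_background) / 2, C = gc_background / 2,
    G = gc_background / 2, T = (1 - gc_background) / 2
  )
  p_cgi <- c(
    A = (1 - gc_island) / 2, C = gc_island / 2,
    G = gc_island / 2, T = (1 - gc_island) / 2
  )
  seqs <- lapply(seq_along(chroms), function(k) {
    x <- sample(names(p_bg), lens[k], replace = TRUE, prob = p_bg)
    isl <- annotations$islands[annotations$islands$chrom == chroms[k], ]
    for (r in seq_len(nrow(isl))) {
      span <- (isl$start[r] + 1):isl$end[r]
      x[span] <- sample(names(p_cgi), length(span), replace = TRUE, prob = p_cgi)
    }
    paste(x, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- chroms
  out
}

#' Simulate H3K4me3 and H3K27me3 windowed enrichment tracks
#'
#' Promoter-level signals are drawn bimodally: H3K4me3 high for {active,
#' bivalent} and low for {repressed, low}; H3K27me3 elevated (Gaussian mode)
#' for {repressed, bivalent} and long-tailed background (exponential)
#' otherwise. Windows tile each chromosome in 200-bp steps; windows
#' overlapping a promoter carry that gene's signal plus window noise.
#' Overlapping promoters would share windows; the generator's spacing keeps
#' promoters disjoint, but sharing is tolerated by downstream averaging.
#'
#' @param promoters Promoter tibble (from [simulate_annotations()] or
#'   [define_promoters()]).
#' @param truth Truth tibble carrying `promoter_class`.
#' @inheritParams simulate_counts
#' @return A list with `k4` and `k27`, each a track tibble with columns
#'   `chrom`, `start`, `end`, `value`, `replicate`.
#' @export
simulate_chip <- function(promoters, truth, cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  stopifnot(all(promoters$gene_id %in% truth$gene_id))
  truth <- truth[match(promoters$gene_id, truth$gene_id), ]
  n <- nrow(promoters)

  k4_mode <- ifelse(truth$promoter_class %in% c("active", "bivalent"),
    cfg$k4_high, cfg$k4_low
  )
  k4_gene <- stats::rnorm(n, k4_mode, cfg$k4_mode_sd)
  k27_hot <- truth$promoter_class %in% c("repressed", "bivalent")
  k27_gene <- ifelse(k27_hot,
    stats::rnorm(n, cfg$k27_high, cfg$k27_mode_sd),
    stats::rexp(n, rate = 1 / cfg$k27_bg_mean)
  )

  win <- purrr::map_dfr(unique(promoters$chrom), function(ch) {
    hi <- max(promoters$end[promoters$chrom == ch])
    n_win <- ceiling(hi / 200)
    tibble(chrom = ch, start = (seq_len(n_win) - 1L) * 200L)
  })
  win$end <- win$start + 200L

  ov <- GenomicRanges::findOverlaps(
    granges0(win$chrom, win$start, win$end),
    granges0(promoters$chrom, promoters$start, promoters$end)
  )
  gene_of_window <- rep(NA_integer_, nrow(win))
  gene_of_window[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)

  one_mark <- function(gene_signal, bg_draw) {
    purrr::map_dfr(seq_len(cfg$n_replicates), function(rep_i) {
      v <- bg_draw(nrow(win))
      hit <- !is.na(gene_of_window)
      v[hit] <- stats::rnorm(
        sum(hit), gene_signal[gene_of_window[hit]], cfg$window_sd
      )
      dplyr::mutate(win, value = v, replicate = rep_i)
    })
  }
  list(
    k4 = one_mark(k4_gene, function(m) stats::rnorm(m, cfg$k4_low, cfg$window_sd)),
    k27 = one_mark(k27_gene, function(m) stats::rexp(m, rate = 1 / cfg$k27_bg_mean)),
    truth = tibble(
      gene_id = promoters$gene_id,
      k4_true = k4_gene, k27_true = k27_gene,
      promoter_class = truth$promoter_class
    )
  )
}

#' Simulate a stimulation time course of log2 fold changes
#'
#' Per-gene log2 fold changes for consecutive time-point comparisons
#' (`fc_0v1`, `fc_1v2`, ...). A positive `effect` boosts the earliest
#' comparison for genes with a short CpG island (size below the median of
#' island-bearing genes), planting the early-response bias; `effect = 0`
#' makes early and late exchangeable; a negative effect favours long
#' islands early.
#'
#' @param genes Character vector of gene ids.
#' @param cgi_sizes Integer vector of island sizes (0 = no island), parallel
#'   to `genes`.
#' @param effect Log2 fold-change boost for short-island genes in the
#'   earliest comparison.
#' @param n_timepoints Number of time points (>= 3, so there is an early and
#'   a late comparison).
#' @inheritParams simulate_counts
#' @return A tibble with `gene_id`, `cgi_size_bp` and `fc_*` columns.
#' @export
simulate_timeseries <- function(genes, cgi_sizes, effect = 0,
                                n_timepoints = 3, cfg = sim_config(),
                                seed = 1L) {
  if (n_timepoints < 3) {
    abort("need at least 3 timepoints (an early and a late comparison)")
  }
  stopifnot(length(genes) == length(cgi_sizes))
  set.seed(seed)
  n <- length(genes)
  with_isl <- cgi_sizes > 0
  short <- with_isl & cgi_sizes < stats::median(cgi_sizes[with_isl])
  out <- tibble(gene_id = genes, cgi_size_bp = as.integer(cgi_sizes))
  for (k in seq_len(n_timepoints - 1)) {
    fc <- stats::rnorm(n, 0, cfg$fc_sd)
    if (k == 1) fc <- fc + effect * short
    out[[sprintf("fc_%dv%d", k - 1, k)]] <- fc
  }
  out
}
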