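#' Pipeline configuration
#'
#' Bundles every stage threshold with its default: cells need 100000 total
#' counts, genes must be detected in 1% of cells, thresholds are multiplied
#' by 1.5 for chromatin calls, island sizes are binned in 0.5-kb steps, the
#' top 250 ranked genes enter the enrichment test, islands are assigned to
#' peaks within a 500-bp centred window, CAGE peaks must be detected in
#' more than 75% of samples and RNA-seq genes must average more than 5
#' counts. The demo bundle is simulated at desk scale, so its stored
#' config lowers `min_total` to match its shallower cells.
#'
#' @param in_dir,out_dir Input and output directories.
#' @param stages Stages to run, in order, among `"annotate"`, `"noise"`,
#'   `"screen"`, `"chromatin"`, `"respond"`.
#' @param min_total,min_cell_fraction Cell and gene filters (see
#'   [filter_cells()], [filter_genes()]).
#' @param sf_method Size-factor method (see [size_factors()]).
#' @param pseudocount,mu_floor,cv2_on Noise-statistic parameters (see
#'   [gene_moments()]).
#' @param multiplier Chromatin threshold multiplier.
#' @param bin_width,top_n,flank,fdr Response-stage parameters.
#' @param detect_fraction,min_mean_count Time-series filters.
#' @param alpha Screen significance level.
#' @param early,late Fold-change columns for the enrichment test.
#' @param seed Seed fixed at pipeline start.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(in_dir = ".", out_dir = ".",
                       stages = c(
                         "annotate", "noise", "screen", "chromatin",
                         "respond"
                       ),
                       min_total = 100000, min_cell_fraction = 0.01,
                       sf_method = "deconvolution",
                       pseudocount = 1, mu_floor = 0.1, cv2_on = "normalized",
                       multiplier = 1.5, bin_width = 500, top_n = 250,
                       flank = 500, fdr = 0.05,
                       detect_fraction = 0.75, min_mean_count = 5,
                       alpha = 0.05,
                       early = "fc_0v1", late = "fc_1v2",
                       seed = 1L) {
  cfg <- as.list(environment())
  # the hash fingerprints the analysis parameters, not where files live
  structure(cfg,
    class = "run_config",
    hash = config_hash(cfg[setdiff(names(cfg), c("in_dir", "out_dir"))])
  )
}

#' Write a demo fixture bundle with known planted truth
#'
#' Calls all synthetic generators under one scenario -- larger CpG islands
#' damp NB dispersion, bivalent promoters carry a four-fold dispersion
#' excess, and short-island genes are boosted in the earliest time-point
#' comparison -- and writes every file the pipeline consumes, plus the
#' ground truth, a README describing the plants, and a file manifest.
#'
#' @param seed Integer seed; the bundle is a pure function of it.
#' @param out_dir Output directory (created if needed).
#' @param n_genes,n_cells Scale of the simulated matrix.
#' @param cfg Simulation parameters from [sim_config()].
#' @param ts_effect Early-comparison boost for short-island genes.
#' @return The manifest tibble, invisibly.
#' @export
make_demo <- function(seed = 1L, out_dir, n_genes = 800, n_cells = 200,
                      cfg = sim_config(), ts_effect = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(n_genes, n_cells, cfg, seed = seed)
  ann <- simulate_annotations(n_genes, cfg, seed = seed + 1L, truth = sim$truth)
  chip <- simulate_chip(ann$promoters, sim$truth, cfg, seed = seed + 2L)
  ts <- simulate_timeseries(sim$truth$gene_id, sim$truth$cgi_size_bp,
    effect = ts_effect, n_timepoints = 3, cfg = cfg, seed = seed + 3L
  )

  fp <- function(x) file.path(out_dir, x)
  write_counts_tsv(sim$counts, fp("counts.tsv"))
  write_gtf(ann$gene_models, fp("genes.gtf"))
  write_cgi_bed(ann$islands, fp("cgi.bed"))
  for (mark in c("k4", "k27")) {
    tr <- chip[[mark]]
    for (r in unique(tr$replicate)) {
      write_bedgraph(
        tr[tr$replicate == r, c("chrom", "start", "end", "value")],
        fp(sprintf("%s_rep%d.bedgraph", mark, r))
      )
    }
  }
  write_timeseries_tsv(ts, fp("timeseries.tsv"))
  readr::write_tsv(sim$truth, fp("truth.tsv"), progress = FALSE)

  # synthetic cells are far shallower than real libraries; scale the cell
  # filter to the bundle. Paths are stored relative to the bundle so the
  # config is location-independent (read_demo_config resolves them).
  demo_cfg <- run_config(
    in_dir = ".", out_dir = ".", min_total = 1000, seed = seed
  )
  jsonlite::write_json(unclass(demo_cfg), fp("config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  writeLines(c(
    "# Demo bundle (synthetic)",
    "",
    "All files are generated by cginoise::make_demo() with a fixed seed.",
    "Planted ground truth (see truth.tsv):",
    sprintf(
      "- NB dispersion decreases with CpG island size (%.2f per kb on the log scale)",
      cfg$effect_cgi_size
    ),
    sprintf(
      "- bivalent promoters carry a %.2gx dispersion excess",
      exp(cfg$effect_bivalent)
    ),
    sprintf(
      "- early responders carry a %.2gx dispersion excess",
      exp(cfg$effect_early)
    ),
    sprintf(
      "- short-island genes gain +%.2g log2FC in the earliest time-point comparison",
      ts_effect
    )
  ), fp("README.md"))

  files <- c(
    "counts.tsv", "genes.gtf", "cgi.bed",
    sprintf("%s_rep%d.bedgraph", rep(c("k4", "k27"), each = cfg$n_replicates),
      rep(seq_len(cfg$n_replicates), 2)
    ),
    "timeseries.tsv", "truth.tsv", "config.json", "README.md"
  )
  manifest <- tibble(file = files)
  readr::write_tsv(manifest, fp("manifest.tsv"), progress = FALSE)
  invisible(manifest)
}

#' Read a pipeline configuration from JSON
#'
#' Relative `in_dir`/`out_dir` entries are resolved against the config
#' file's own directory, so a bundle written by [make_demo()] can be run
#' from anywhere.
#'
#' @param path Path to a config JSON (e.g. the demo bundle's
#'   `config.json`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- cfg[setdiff(names(cfg), "hash")]
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  }
  cfg$in_dir <- resolve(cfg$in_dir %||% ".")
  cfg$out_dir <- resolve(cfg$out_dir %||% ".")
  do.call(run_config, cfg)
}

#' Run the analysis pipeline end to end
#'
#' Executes the toggled stages in order -- annotate, noise, screen,
#' chromatin, respond -- on the files in `config$in_dir`, writing one TSV
#' or JSON per stage plus a run report (`report.json`) holding the config
#' hash, per-stage row counts and all fitted parameters. A stage failure
#' aborts with the failing stage named; outputs of completed stages are
#' retained. Outputs carry no timestamps, so a rerun with the same seed
#' and config is byte-identical.
#'
#' @param config A `run_config`.
#' @return The run report list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fin <- function(x) file.path(config$in_dir, x)
  fout <- function(x) file.path(config$out_dir, x)
  report <- list(
    package = "cginoise",
    config_hash = attr(config, "hash") %||% config_hash(unclass(config)),
    stages = list(), parameters = list()
  )
  state <- new.env()

  stage_fns <- list(
    annotate = function() {
      gm <- read_gtf(fin("genes.gtf"))
      islands <- read_cgi_bed(fin("cgi.bed"))
      promoters <- define_promoters(gm)
      parts <- list(
        assign_cgi(promoters, islands),
        gene_structure_features(gm)
      )
      fa <- fin("genome.fa")
      if (file.exists(fa)) {
        parts <- c(parts, list(promoter_gc(promoters, fa)))
      }
      features <- do.call(build_feature_table, c(parts, list(standardize = TRUE)))
      readr::write_tsv(features, fout("features.tsv"), progress = FALSE)
      state$features <- features
      state$promoters <- promoters
      list(n_genes = nrow(features), n_islands = nrow(islands))
    },
    noise = function() {
      counts <- read_counts_tsv(fin("counts.tsv"))
      res <- compute_noise(counts,
        min_total = config$min_total,
        min_cell_fraction = config$min_cell_fraction,
        method = config$sf_method,
        pseudocount = config$pseudocount, mu_floor = config$mu_floor,
        cv2_on = config$cv2_on
      )
      readr::write_tsv(res$noise, fout("noise.tsv"), progress = FALSE)
      jsonlite::write_json(
        as.list(glance(res$fit)), fout("fit.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      state$noise <- res$noise
      report$parameters$a0 <<- res$fit$a0
      report$parameters$a1 <<- res$fit$a1
      list(n_genes = nrow(res$noise), n_cells = nrow(res$size_factors))
    },
    screen = function() {
      if (is.null(state$noise)) state$noise <- readr::read_tsv(
        fout("noise.tsv"), show_col_types = FALSE, progress = FALSE
      )
      if (is.null(state$features)) state$features <- readr::read_tsv(
        fout("features.tsv"), show_col_types = FALSE, progress = FALSE
      )
      cols <- grep("_z$", names(state$features), value = TRUE)
      screen <- dplyr::bind_rows(
        univariate_screen(state$noise, state$features,
          columns = cols, alpha = config$alpha
        ),
        multivariate_screen(state$noise, state$features,
          columns = cols, alpha = config$alpha
        )
      )
      readr::write_tsv(screen, fout("screen.tsv"), progress = FALSE)
      report$parameters$screen_beta <<- stats::setNames(
        as.list(screen$beta), paste(screen$model_kind, screen$feature, sep = ".")
      )
      list(n_models = nrow(screen))
    },
    chromatin = function() {
      if (is.null(state$promoters)) {
        state$promoters <- define_promoters(read_gtf(fin("genes.gtf")))
      }
      read_mark <- function(mark) {
        paths <- sort(list.files(config$in_dir,
          pattern = sprintf("^%s_rep\\d+\\.bedgraph$", mark),
          full.names = TRUE
        ))
        if (length(paths) == 0) abort(paste("no", mark, "bedgraph files"))
        tracks <- lapply(paths, read_bedgraph)
        names(tracks) <- paths
        promoter_signal(tracks, state$promoters)
      }
      classes <- classify_bivalency(
        read_mark("k4"), read_mark("k27"),
        multiplier = config$multiplier
      )
      readr::write_tsv(
        dplyr::as_tibble(classes), fout("chromatin.tsv"),
        progress = FALSE
      )
      th <- chromatin_thresholds(classes)
      report$parameters$k4_threshold <<- th$k4_threshold
      report$parameters$k27_threshold <<- th$k27_threshold
      if (!is.null(state$noise) && !is.null(state$features)) {
        fit <- category_regression(state$noise, classes, state$features)
        report$parameters$category_beta <<- stats::setNames(
          as.list(fit$coefficients$beta), fit$coefficients$term
        )
      }
      list(n_classified = nrow(classes))
    },
    respond = function() {
      ts <- read_timeseries_tsv(fin("timeseries.tsv"))
      enr <- cgi_size_enrichment(ts,
        early = config$early, late = config$late, top_n = config$top_n
      )
      jsonlite::write_json(
        as.list(tidy(enr)), fout("enrichment.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      report$parameters$enrichment_p <<- enr$p_one_tailed
      report$parameters$enrichment_direction <<- enr$direction
      list(n_pairs = enr$n_pairs)
    }
  )

  for (st in config$stages) {
    if (!st %in% names(stage_fns)) abort(paste("unknown stage:", st))
    inform(paste("stage:", st))
    res <- tryCatch(stage_fns[[st]](), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", st, conditionMessage(e)))
    })
    report$stages[[st]] <- res
  }
  jsonlite::write_json(report, fout("report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(report)
}
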