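#' Define promoter intervals from gene models
#'
#' Promoters span -1 kb to +500 bp around the transcriptional start site,
#' accounting for strand: on the + strand the TSS is the gene start and the
#' promoter is `[tss - 1000, tss + 500)`; on the - strand the TSS is the
#' gene end and the promoter is `[tss - 500, tss + 1000)`. Promoters that
#' would extend past position 0 are clipped and flagged. Coordinates are
#' 0-based half-open.
#'
#' @param gene_models Gene-model tibble as returned by [read_gtf()] or
#'   [simulate_annotations()]; `gene` records are used, or exon extents per
#'   gene when no `gene` records exist.
#' @return A promoter tibble: `gene_id`, `chrom`, `strand`, `tss`, `start`,
#'   `end`, `clipped`.
#' @export
define_promoters <- function(gene_models) {
  genes <- dplyr::filter(gene_models, .data$type == "gene")
  if (nrow(genes) == 0) {
    genes <- gene_models |>
      dplyr::filter(.data$type == "exon") |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        chrom = .data$chrom[1], start = min(.data$start),
        end = max(.data$end), strand = .data$strand[1], .groups = "drop"
      )
  }
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    warn(sprintf(
      "dropping %d gene record(s) without a usable strand: %s",
      sum(bad), paste(utils::head(genes$gene_id[bad], 5), collapse = ", ")
    ))
    genes <- genes[!bad, ]
  }
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  start <- ifelse(plus, tss - 1000L, tss - 500L)
  end <- ifelse(plus, tss + 500L, tss + 1000L)
  clipped <- start < 0
  start <- pmax(start, 0L)
  tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = as.integer(tss), start = as.integer(start), end = as.integer(end),
    clipped = clipped
  )
}

#' Gene-structure features from gene models
#'
#' Computes, per gene, the total transcript length (sum of exon lengths of
#' the longest annotated transcript), the exon count and mean exon length of
#' that transcript. Genes with a `gene` record but no exons get missing
#' values, not zeros.
#'
#' @inheritParams define_promoters
#' @return A tibble: `gene_id`, `transcript_length_bp`, `n_exons`,
#'   `mean_exon_length_bp`.
#' @export
gene_structure_features <- function(gene_models) {
  exons <- dplyr::filter(gene_models, .data$type == "exon")
  if (nrow(exons) == 0) {
    return(tibble(
      gene_id = character(), transcript_length_bp = double(),
      n_exons = double(), mean_exon_length_bp = double()
    ))
  }
  per_tx <- exons |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(
      transcript_length_bp = sum(.data$end - .data$start),
      n_exons = dplyr::n(), .groups = "drop"
    )
  out <- per_tx |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(.data$transcript_length_bp, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      mean_exon_length_bp = .data$transcript_length_bp / .data$n_exons,
      n_exons = as.double(.data$n_exons)
    ) |>
    dplyr::select(
      "gene_id", "transcript_length_bp", "n_exons", "mean_exon_length_bp"
    )
  no_exon <- setdiff(
    unique(gene_models$gene_id[gene_models$type == "gene"]), out$gene_id
  )
  if (length(no_exon) > 0) {
    out <- dplyr::bind_rows(out, tibble(gene_id = no_exon))
  }
  out
}

# Shared overlap rule: the island with maximal overlap wins; ties go to the
# longer island. Returns 0 size / FALSE flag for intervals with no overlap.
overlap_max_island <- function(query, islands, id_col = "gene_id") {
  out <- tibble(
    !!id_col := query[[id_col]],
    cgi_overlap = FALSE, cgi_size_bp = 0L
  )
  shared <- intersect(unique(query$chrom), unique(islands$chrom))
  missing_chrom <- setdiff(unique(query$chrom), shared)
  if (length(missing_chrom) > 0) {
    inform(sprintf(
      "no islands on chromosome(s): %s",
      paste(missing_chrom, collapse = ", ")
    ))
  }
  if (nrow(islands) == 0 || length(shared) == 0) {
    return(out)
  }
  q <- granges0(query$chrom, query$start, query$end)
  s <- granges0(islands$chrom, islands$start, islands$end)
  hits <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L)
  if (length(hits) == 0) {
    return(out)
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov_width <- GenomicRanges::width(IRanges::pintersect(q[qi], s[si]))
  isl_len <- islands$end[si] - islands$start[si]
  best <- tibble(qi = qi, ov = ov_width, len = isl_len) |>
    dplyr::group_by(.data$qi) |>
    dplyr::arrange(dplyr::desc(.data$ov), dplyr::desc(.data$len),
      .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  out$cgi_overlap[best$qi] <- TRUE
  out$cgi_size_bp[best$qi] <- as.integer(best$len)
  out
}

#' Assign CpG islands to promoters
#'
#' A promoter is island-positive when at least 1 bp of a CpG island overlaps
#' its interval (half-open coordinates, so touching intervals do not
#' overlap). When several islands overlap, the island with the maximal
#' overlap is taken; ties go to the longer island. Its full length is
#' recorded as `cgi_size_bp`.
#'
#' @param promoters Promoter tibble from [define_promoters()].
#' @param islands Island tibble from [read_cgi_bed()] (needs `chrom`,
#'   `start`, `end`).
#' @return A tibble: `gene_id`, `cgi_overlap`, `cgi_size_bp` (0 if none).
#' @export
assign_cgi <- function(promoters, islands) {
  overlap_max_island(promoters, islands)
}

#' Promoter GC content
#'
#' Fraction of G or C among unambiguous bases (A, C, G, T) of the promoter
#' sequence; ambiguous bases are excluded from both numerator and
#' denominator. Promoters outside the sequence bounds get a missing value.
#'
#' @param promoters Promoter tibble.
#' @param sequences A [Biostrings::DNAStringSet] of chromosome sequences
#'   (named by chromosome) or a path to a FASTA file.
#' @return A tibble: `gene_id`, `gc_fraction`.
#' @export
promoter_gc <- function(promoters, sequences) {
  if (is.character(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  gc <- rep(NA_real_, nrow(promoters))
  widths <- stats::setNames(Biostrings::width(sequences), names(sequences))
  ok <- promoters$chrom %in% names(sequences) &
    promoters$end <= widths[promoters$chrom] & promoters$start >= 0
  if (any(!ok)) {
    inform(sprintf("%d promoter(s) outside sequence bounds", sum(!ok)))
  }
  if (any(ok)) {
    sub <- Biostrings::subseq(
      sequences[promoters$chrom[ok]],
      start = promoters$start[ok] + 1L, end = promoters$end[ok]
    )
    freq <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc[ok] <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
  }
  tibble(gene_id = promoters$gene_id, gc_fraction = gc)
}

#' Assemble the per-gene feature table
#'
#' Outer-joins partial feature tables on `gene_id` and optionally adds
#' z-scored copies (`<name>_z`) of continuous columns so regression
#' coefficients are comparable across features. Zero-variance columns are
#' flagged and left unstandardized. Logical columns are carried as 0/1.
#'
#' @param ... Partial feature tibbles, each keyed by `gene_id`.
#' @param standardize Add z-scored copies of numeric columns?
#' @return The joined feature tibble. A missingness report (count of `NA`
#'   per column) is attached as attribute `"missingness"`.
#' @export
build_feature_table <- function(..., standardize = TRUE) {
  parts <- list(...)
  stopifnot(length(parts) > 0)
  for (p in parts) {
    if (!"gene_id" %in% names(p)) abort("every part needs a `gene_id` column")
    if (anyDuplicated(p$gene_id)) abort("duplicated gene_id within a part")
  }
  out <- purrr::reduce(parts, function(a, b) {
    common <- setdiff(intersect(names(a), names(b)), "gene_id")
    joined <- dplyr::full_join(a, b, by = "gene_id", suffix = c(".a", ".b"))
    for (cc in common) {
      va <- joined[[paste0(cc, ".a")]]
      vb <- joined[[paste0(cc, ".b")]]
      conflict <- !is.na(va) & !is.na(vb) & va != vb
      if (any(conflict)) {
        abort(sprintf(
          "conflicting values for column `%s` (e.g. gene %s)",
          cc, joined$gene_id[which(conflict)[1]]
        ))
      }
      joined[[cc]] <- dplyr::coalesce(va, vb)
      joined[[paste0(cc, ".a")]] <- NULL
      joined[[paste0(cc, ".b")]] <- NULL
    }
    joined
  })
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.logical), as.numeric))
  if (standardize) {
    num_cols <- setdiff(
      names(out)[vapply(out, is.numeric, logical(1))], "gene_id"
    )
    for (cc in num_cols) {
      z <- zscore_guard(out[[cc]])
      if (isTRUE(attr(z, "constant"))) {
        warn(sprintf("column `%s` has zero variance; not standardized", cc))
      } else {
        out[[paste0(cc, "_z")]] <- as.numeric(z)
      }
    }
  }
  miss <- vapply(out, function(x) sum(is.na(x)), integer(1))
  attr(out, "missingness") <- miss
  out
}
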