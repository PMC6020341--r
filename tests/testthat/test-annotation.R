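test_that("promoters span -1 kb/+500 bp around the TSS, strand-aware", {
  gm <- rbind(
    gm_row("gene", "gplus", "chr1", 10000, 12000, "+"),
    gm_row("gene", "gminus", "chr1", 8000, 10000, "-"),
    gm_row("gene", "gclip", "chr1", 300, 2000, "+")
  )
  pr <- define_promoters(gm)
  plus <- pr[pr$gene_id == "gplus", ]
  expect_equal(c(plus$start, plus$end), c(9000, 10500))
  minus <- pr[pr$gene_id == "gminus", ]
  expect_equal(c(minus$start, minus$end), c(9500, 11000))
  clip <- pr[pr$gene_id == "gclip", ]
  expect_equal(c(clip$start, clip$end), c(0, 800))
  expect_true(clip$clipped)
  # width conservation for unclipped promoters
  unclipped <- pr[!pr$clipped, ]
  expect_true(all(unclipped$end - unclipped$start == 1500))
})

test_that("records without a usable strand are dropped with a warning", {
  gm <- rbind(
    gm_row("gene", "ok", "chr1", 5000, 6000, "+"),
    gm_row("gene", "bad", "chr1", 7000, 8000, "*")
  )
  expect_warning(pr <- define_promoters(gm), "strand")
  expect_equal(pr$gene_id, "ok")
})

test_that("gene-structure features follow the longest-transcript rule", {
  gm <- rbind(
    gm_row("exon", "g1", "chr1", 1000, 1100, "+", tx = "t1"),
    gm_row("exon", "g1", "chr1", 1300, 1600, "+", tx = "t1"),
    gm_row("exon", "g2", "chr1", 5000, 5400, "+", tx = "t2a"),
    gm_row("exon", "g2", "chr1", 7000, 7900, "+", tx = "t2b"),
    gm_row("gene", "g3", "chr1", 9000, 9500, "+")
  )
  fs <- gene_structure_features(gm)
  g1 <- fs[fs$gene_id == "g1", ]
  expect_equal(g1$transcript_length_bp, 400)
  expect_equal(g1$n_exons, 2)
  expect_equal(g1$mean_exon_length_bp, 200)
  expect_equal(fs$transcript_length_bp[fs$gene_id == "g2"], 900)
  # gene with no exons: present with missing values, not zeros
  expect_true(is.na(fs$transcript_length_bp[fs$gene_id == "g3"]))
  empty <- gene_structure_features(gm[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("island assignment uses >=1 bp overlap and maximal-overlap ties", {
  pr <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+",
    tss = 10000, start = 9000, end = 10500, clipped = FALSE
  )
  isl <- function(s, e) {
    tibble::tibble(
      chrom = "chr1", start = s, end = e,
      name = paste0("i", s), length_bp = e - s
    )
  }
  hit <- quietly(assign_cgi(pr, isl(10400, 10900)))
  expect_true(hit$cgi_overlap)
  expect_equal(hit$cgi_size_bp, 500)
  # half-open: an island starting exactly at the promoter end is no overlap
  miss <- quietly(assign_cgi(pr, isl(10500, 11000)))
  expect_false(miss$cgi_overlap)
  expect_equal(miss$cgi_size_bp, 0)
  # equal 50-bp overlaps: the longer island wins
  two <- rbind(isl(8750, 9050), isl(10450, 11250))
  tie <- quietly(assign_cgi(pr, two))
  expect_equal(tie$cgi_size_bp, 800)
  # symmetric under island order permutation
  tie2 <- quietly(assign_cgi(pr, two[2:1, ]))
  expect_identical(tie$cgi_size_bp, tie2$cgi_size_bp)
})

test_that("unmatched chromosomes give island-negative genes, with a note", {
  pr <- tibble::tibble(
    gene_id = "g1", chrom = "chrX", strand = "+",
    tss = 10000, start = 9000, end = 10500, clipped = FALSE
  )
  isl <- tibble::tibble(
    chrom = "chr1", start = 9000, end = 9500, name = "i", length_bp = 500
  )
  expect_message(out <- assign_cgi(pr, isl), "chrX")
  expect_false(out$cgi_overlap)
})

test_that("promoter GC counts unambiguous bases only", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = "ATGCGGGGATNN"))
  pr <- tibble::tibble(
    gene_id = c("a", "b", "c", "oob"),
    chrom = "chr1", strand = "+", tss = 0,
    start = c(0, 4, 8, 5), end = c(4, 8, 12, 2000),
    clipped = FALSE
  )
  gc <- quietly(promoter_gc(pr, seqs))
  expect_equal(gc$gc_fraction[gc$gene_id == "a"], 0.5) # ATGC
  expect_equal(gc$gc_fraction[gc$gene_id == "b"], 1.0) # GGGG
  expect_equal(gc$gc_fraction[gc$gene_id == "c"], 0.0) # ATNN, denominator 2
  expect_true(is.na(gc$gc_fraction[gc$gene_id == "oob"]))
})

test_that("feature assembly joins, standardizes and guards", {
  a <- tibble::tibble(gene_id = c("g1", "g2"), x = c(1, 2))
  b <- tibble::tibble(gene_id = c("g2", "g3"), y = c(5, 9))
  ft <- quietly(build_feature_table(a, b))
  expect_equal(nrow(ft), 3)
  expect_true(is.na(ft$y[ft$gene_id == "g1"]))
  expect_true(all(c("x_z", "y_z") %in% names(ft)))
  expect_equal(mean(ft$x_z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(ft$x_z, na.rm = TRUE), 1, tolerance = 1e-12)

  const <- tibble::tibble(gene_id = c("g1", "g2"), k = c(3, 3))
  expect_warning(ft2 <- build_feature_table(a, const), "zero variance")
  expect_false("k_z" %in% names(ft2))

  conflict <- tibble::tibble(gene_id = "g1", x = 99)
  expect_error(quietly(build_feature_table(a, conflict)), "conflicting")
  dup <- tibble::tibble(gene_id = c("g1", "g1"), z = c(1, 2))
  expect_error(build_feature_table(a, dup), "duplicated")
})

test_that("annotations survive a full file round trip", {
  cfg <- sim_config()
  ann <- simulate_annotations(40, cfg, seed = 9)
  td <- withr::local_tempdir()
  write_gtf(ann$gene_models, file.path(td, "g.gtf"))
  write_cgi_bed(ann$islands, file.path(td, "i.bed"))
  gm2 <- read_gtf(file.path(td, "g.gtf"))
  isl2 <- read_cgi_bed(file.path(td, "i.bed"))
  pr2 <- define_promoters(gm2)
  got <- quietly(assign_cgi(pr2, isl2))
  got <- got[match(ann$features$gene_id, got$gene_id), ]
  expect_equal(got$cgi_size_bp, ann$features$cgi_size_bp)
  fs2 <- gene_structure_features(gm2)
  fs2 <- fs2[match(ann$features$gene_id, fs2$gene_id), ]
  expect_equal(fs2$transcript_length_bp, ann$features$transcript_length_bp)
  expect_equal(fs2$n_exons, ann$features$n_exons)

  # feature-table TSV round trip
  ft <- quietly(build_feature_table(ann$features, standardize = FALSE))
  readr::write_tsv(ft, file.path(td, "ft.tsv"))
  ft2 <- readr::read_tsv(file.path(td, "ft.tsv"), show_col_types = FALSE)
  expect_equal(as.data.frame(ft2), as.data.frame(ft), ignore_attr = TRUE)
})
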