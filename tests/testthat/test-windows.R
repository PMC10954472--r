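test_that("count_features counts only exonic features inside windows", {
  windows <- genomic_intervals("chr1", c(0L, 5000L), c(5000L, 10000L))
  exons <- genomic_intervals("chr1", 1000L, 2000L)
  g4s <- genomic_intervals("chr1", c(1500L, 3000L), c(1530L, 3030L))
  csnvs <- tibble::tibble(chrom = "chr1", pos = c(1100L, 4000L, 6000L),
                          patient_id = "p", cancer_type = "A", tissue = "t")
  wt <- count_features(windows, g4s, csnvs, NULL, exons)
  # the G4 at 3000 and the cSNVs at 4000/6000 are outside exons: not counted
  expect_equal(wt$g4_count, c(1L, 0L))
  expect_equal(wt$csnv_count, c(1L, 0L))
  expect_equal(wt$dbsnv_count, c(0L, 0L))   # all-zero row retained
})

test_that("count_features matches a brute-force nested-loop counter", {
  withr::local_seed(23)
  for (k in 1:25) {
    windows <- random_interval_set(30, max_pos = 5000L, max_len = 400L)
    exons <- random_interval_set(20, max_pos = 5000L, max_len = 300L)
    g4s <- random_interval_set(40, max_pos = 5000L, max_len = 30L)
    wt <- count_features(windows, g4s, NULL, NULL, exons)
    expect_equal(wt$g4_count, oracle_count_window(windows, g4s, exons))
  }
})

test_that("count_features computes GC and errors outside the genome", {
  genome <- tibble::tibble(name = "chr1",
                           sequence = strrep("GCAT", 2500))  # 10 kb, GC 0.5
  windows <- genomic_intervals("chr1", c(0L, 4000L), c(4000L, 10000L))
  exons <- genomic_intervals("chr1", 0L, 10000L)
  wt <- count_features(windows, NULL, NULL, NULL, exons, genome = genome)
  expect_equal(wt$gc_bp, c(2000L, 3000L))
  bad <- genomic_intervals("chr1", 9000L, 10001L)
  expect_error(
    count_features(bad, NULL, NULL, NULL, exons, genome = genome),
    "outside"
  )
})

test_that("stratified enrichment reproduces closed-form group statistics", {
  wt <- tibble::tibble(
    g4_count = c(0L, 0L, 0L, 1L, 2L, 10L),
    csnv_count = c(0L, 0L, 2L, 3L, 5L, 10L),
    dbsnv_count = 0L
  )
  res <- stratify_enrichment(wt, "cSNV")
  expect_equal(res$mean_snv[res$group == "0"], 2 / 3, tolerance = 1e-12)
  expect_equal(res$mean_snv[res$group == "1+"], 6)
  expect_equal(res$median_snv[res$group == "1+"], 5)
  # direct Welch t for 0 vs 1+
  tt <- t.test(c(0, 0, 2), c(3, 5, 10))
  expect_equal(res$t_statistic[res$group == "1+"], unname(tt$statistic))
  expect_lt(res$t_statistic[res$group == "1+"], 0)

  # identical distributions: t near zero
  same <- tibble::tibble(g4_count = rep(c(0L, 1L), each = 50),
                         csnv_count = rep(c(1L, 2L), 50),
                         dbsnv_count = 0L)
  expect_warning(res2 <- stratify_enrichment(same, "cSNV"), "empty")
  expect_lt(abs(res2$t_statistic[res2$group == "1+"]), 0.5)
  expect_gt(res2$t_p_value[res2$group == "1+"], 0.5)

  # per-count grouping returns one row per category
  pc <- stratify_enrichment(wt, "cSNV", grouping = "per_count")
  expect_equal(pc$group, c("0", "1", "2", "10"))
})

test_that("planted slope orders the stratum means; overall mean is conserved", {
  wt <- simulate_window_table(n_per_category = 300L, intercept = 2,
                              slope = 3, seed = 6L)
  res <- suppressWarnings(stratify_enrichment(wt, "cSNV"))
  m <- setNames(res$mean_snv, res$group)
  expect_gt(m[["10+"]], m[["1+"]])
  expect_gt(m[["1+"]], m[["0"]])
  # group means are weighted-consistent with the overall mean
  res_pc <- stratify_enrichment(wt, "cSNV", grouping = "per_count")
  overall <- sum(res_pc$mean_snv * res_pc$n_windows) / sum(res_pc$n_windows)
  expect_equal(overall, mean(wt$csnv_count), tolerance = 1e-12)
  # dbSNV strata stay flat: all pairwise mean gaps within 3 SE
  resd <- suppressWarnings(stratify_enrichment(wt, "dbSNV"))
  se <- sqrt(10 / 300)
  expect_lt(max(dist(resd$mean_snv)), 3 * se * sqrt(2))
})

test_that("gc_normalized_counts flags zero-GC windows", {
  wt <- tibble::tibble(g4_count = c(4L, 2L, 1L), gc_bp = c(2000L, 0L, 1000L))
  out <- gc_normalized_counts(wt)
  expect_equal(out$g4_per_gc, c(0.002, NA, 0.001))
  expect_equal(out$gc_zero, c(FALSE, TRUE, FALSE))
  # doubling GC halves the rate
  wt2 <- dplyr::mutate(wt, gc_bp = gc_bp * 2L)
  out2 <- gc_normalized_counts(wt2)
  expect_equal(out2$g4_per_gc[1], out$g4_per_gc[1] / 2)
})

test_that("partial_correlation reduces to r_xy under exact orthogonality", {
  withr::local_seed(31)
  x <- rnorm(200)
  y <- 0.5 * x + rnorm(200)
  z0 <- rnorm(200)
  z <- residuals(lm(z0 ~ x + y))   # sample-orthogonal to x and y
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r_xy_given_z, cor(x, y), tolerance = 1e-10)
  # y essentially equal to z, x independent: partial correlation vanishes
  xx <- rnorm(2000)
  z2 <- rnorm(2000)
  pc2 <- partial_correlation(xx, z2 + 0.01 * rnorm(2000), z2)
  expect_lt(abs(pc2$r_xy_given_z), 0.1)
  # exactly collinear z is rejected (the formula is undefined there)
  expect_error(partial_correlation(x, y, y), "collinear")
  expect_error(partial_correlation(1:4, 1:4 + 0.5, rep(1, 4)), "variance")
})

test_that("partial_correlation matches lm-residual correlation", {
  withr::local_seed(41)
  n <- 3000
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- 0.3 * z + 0.2 * x + rnorm(n)
  pc <- partial_correlation(x, y, z)
  # independent route: correlate the residuals of x ~ z and y ~ z
  alt <- cor(residuals(lm(x ~ z)), residuals(lm(y ~ z)))
  expect_equal(pc$r_xy_given_z, alt, tolerance = 1e-10)
})

test_that("gene_exon_analysis normalises densities and correlates", {
  exons <- genomic_intervals("chr1", c(0L, 1000L, 3000L),
                             c(500L, 2000L, 3500L))
  g4s <- genomic_intervals("chr1", c(100L, 150L), c(130L, 180L))
  csnvs <- tibble::tibble(chrom = "chr1",
                          pos = c(10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L,
                                  90L, 110L, 1500L))
  res <- gene_exon_analysis(exons, g4s, csnvs)
  expect_equal(res$exon_table$csnv_count, c(10L, 1L, 0L))
  expect_equal(res$exon_table$csnv_per_bp, c(10 / 500, 1 / 1000, 0))
  expect_equal(res$exon_table$g4_count, c(2L, 0L, 0L))
  # cSNVs concentrated in the G4-bearing exon: strong positive correlation
  expect_gt(res$correlation$r, 0.9)
  # an exon with neither feature contributes the (0, 0) point
  expect_equal(res$exon_table$csnv_count[3], 0L)
  expect_equal(res$exon_table$g4_count[3], 0L)
  # two exons: counts still emitted, correlation undefined
  res2 <- gene_exon_analysis(exons[1:2, ], g4s, csnvs)
  expect_null(res2$correlation)
  expect_equal(nrow(res2$exon_table), 2L)
})

test_that("gene_class_comparison recovers the planted G4 enrichment", {
  cfg <- synthetic_config(
    n_chroms = 1L, chrom_length = 2e6, n_genes = 20L, n_g4 = 3000L,
    cancer_gene_fraction = 0.2, g4_cancer_fraction = 0.412, seed = 16L
  )
  ds <- place_g4s(simulate_genome(cfg), cfg)
  gene_class <- tibble::tibble(
    name = ds$genes$name,
    gene_class = ifelse(ds$genes$name %in% ds$cancer_genes,
                        "cancer", "non-cancer")
  )
  wins <- restrict_windows_to_genes(ds$genes, ds$exons, 5000, flank = 2000,
                                    chrom_lengths = c(chr1 = 2e6))
  wt <- count_features(wins, ds$g4s, NULL, NULL, ds$exons,
                       genes = ds$genes, gene_class = gene_class)
  res <- suppressWarnings(
    gene_class_comparison(wt, ds$genes, gene_class, ds$g4s)
  )
  gg <- res$gene_g4
  ratio <- gg$median_g4[gg$gene_class == "cancer"] /
    gg$median_g4[gg$gene_class == "non-cancer"]
  # planted 2.8-fold enrichment recovered within 20%
  expect_lt(abs(ratio - 2.8) / 2.8, 0.2)
  expect_true(all(c("cancer", "non-cancer") %in% res$strata$gene_class))
})
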