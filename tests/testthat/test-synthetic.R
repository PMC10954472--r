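# A small shared study for the structural checks.
small_cfg <- synthetic_config(
  n_chroms = 1L, chrom_length = 4e5, n_genes = 12L, n_g4 = 120L,
  n_patients = 80L, n_cancer_types = 4L, csnv_per_patient_mean = 25,
  n_dbsnv = 3000L, seed = 5L
)

test_that("simulate_genome builds disjoint genes with exons inside them", {
  ds <- simulate_genome(small_cfg)
  expect_equal(nrow(ds$genes), 12L)
  expect_equal(nrow(ds$exons), 12L * small_cfg$exons_per_gene)
  g <- sort_intervals(ds$genes)
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))        # genes disjoint
  gene_of <- sub("_ex\\d+$", "", ds$exons$name)
  idx <- match(gene_of, ds$genes$name)
  expect_true(all(ds$exons$start >= ds$genes$start[idx]))
  expect_true(all(ds$exons$end <= ds$genes$end[idx]))
  e <- ds$exons
  expect_true(all(e$start[-1] >= e$end[-nrow(e)]))        # exons disjoint
  # same seed, identical sequence; realized GC near the requested fraction
  ds2 <- simulate_genome(small_cfg)
  expect_identical(ds$genome, ds2$genome)
  gc <- gc_count(ds$genome$sequence[1], 0, 4e5) / 4e5
  expect_lt(abs(gc - small_cfg$gc_fraction), 0.02)
})

test_that("genes that cannot fit raise an error", {
  bad <- synthetic_config(n_chroms = 1L, chrom_length = 1e4, n_genes = 10L)
  expect_error(simulate_genome(bad), "fit")
})

test_that("place_g4s respects exon containment and the clustering knob", {
  ds <- place_g4s(simulate_genome(small_cfg))
  expect_equal(nrow(ds$g4s), 120L)
  expect_true(all(intersect_count(ds$g4s, ds$exons) >= 1))

  # no clustering: per-gene counts consistent with a uniform multinomial
  flat_cfg <- synthetic_config(
    n_chroms = 1L, chrom_length = 2e6, n_genes = 20L, n_g4 = 2000L,
    cancer_gene_fraction = 0, seed = 9L
  )
  flat <- place_g4s(simulate_genome(flat_cfg))
  per_gene <- intersect_count(flat$genes, flat$g4s)
  ct <- suppressWarnings(chisq.test(per_gene))
  expect_gt(ct$p.value, 0.01)

  # 80% of G4s into 20% of genes: expected 16:1 mean count ratio
  clust_cfg <- synthetic_config(
    n_chroms = 1L, chrom_length = 2e6, n_genes = 20L, n_g4 = 4000L,
    cancer_gene_fraction = 0.2, g4_cancer_fraction = 0.8, seed = 10L
  )
  cl <- place_g4s(simulate_genome(clust_cfg))
  per_gene <- intersect_count(cl$genes, cl$g4s)
  cancer <- cl$genes$name %in% cl$cancer_genes
  ratio <- mean(per_gene[cancer]) / mean(per_gene[!cancer])
  expect_lt(abs(ratio - 16) / 16, 0.15)

  # degenerate: zero G4s still yields a usable (empty) set
  none <- place_g4s(simulate_genome(small_cfg),
                    synthetic_config(n_g4 = 0L))
  expect_equal(nrow(none$g4s), 0L)
})

test_that("place_snvs plants offset structure with the right signs", {
  cfg <- synthetic_config_spatial(
    n_patients = 100L, csnv_per_patient_mean = 100,
    n_dbsnv = 10000L, seed = 21L
  )
  ds <- place_g4s(simulate_genome(cfg), cfg)
  ds <- place_snvs(ds, cfg, "cSNV")
  ds <- place_snvs(ds, cfg, "dbSNV")
  d_c <- closest_distance(
    genomic_intervals(ds$csnvs$chrom, ds$csnvs$pos, ds$csnvs$pos + 1L),
    ds$g4s
  )$distance
  d_d <- closest_distance(
    genomic_intervals(ds$dbsnvs$chrom, ds$dbsnvs$pos, ds$dbsnvs$pos + 1L),
    ds$g4s
  )$distance
  # planted means recovered within a few standard errors
  expect_lt(abs(mean(d_c) - cfg$offset_mean_csnv),
            5 * cfg$offset_sd_csnv / sqrt(length(d_c)) + 2)
  expect_gt(mean(d_c), 0)
  expect_lt(mean(d_d), 0)
  expect_lt(abs(mean(d_d) - cfg$offset_mean_dbsnv),
            5 * cfg$offset_sd_dbsnv / sqrt(length(d_d)) + 2)
  # patient labels only on the cancer cohort
  expect_true(all(!is.na(ds$csnvs$patient_id)))
  expect_true(all(is.na(ds$dbsnvs$patient_id)))
})

test_that("assoc_fraction zero yields a uniform-like distance distribution", {
  cfg <- synthetic_config_spatial(
    assoc_fraction = 0, n_patients = 50L, csnv_per_patient_mean = 400,
    seed = 31L
  )
  ds <- place_g4s(simulate_genome(cfg), cfg)
  ds <- place_snvs(ds, cfg, "cSNV")
  d <- closest_distance(
    genomic_intervals(ds$csnvs$chrom, ds$csnvs$pos, ds$csnvs$pos + 1L),
    ds$g4s
  )$distance
  # null reference distribution: uniform placement over the same exon space
  null_pos <- random_intervals(ds$exons, 1, length(d), seed = 32L)
  d0 <- closest_distance(null_pos, ds$g4s)$distance
  ks <- suppressWarnings(ks.test(d, d0))
  expect_gt(ks$p.value, 0.01)
  # requesting association without G4s is an error
  empty <- ds
  empty$g4s <- genomic_intervals(character(), integer(), integer())
  cfg2 <- synthetic_config_spatial(assoc_fraction = 0.5)
  expect_error(place_snvs(empty, cfg2, "cSNV"), "G4")
})

test_that("the full dataset is byte-identical under a fixed seed", {
  a <- simulate_study(small_cfg)
  b <- simulate_study(small_cfg)
  for (part in c("genome", "genes", "exons", "g4s", "csnvs", "dbsnvs",
                 "patients", "windows")) {
    expect_identical(a[[part]], b[[part]], label = part)
  }
  # truth record round-trips the generating config
  expect_identical(a$truth$seed, small_cfg$seed)
  expect_identical(a$truth$linear_slope, small_cfg$linear_slope)
})

test_that("simulate_window_table plants the linear relation exactly", {
  wt <- simulate_window_table(n_per_category = 2000L, intercept = 2,
                              slope = 3, seed = 4L)
  means <- tapply(wt$csnv_count, wt$g4_count, mean)
  cats <- as.numeric(names(means))
  fit <- fit_linear(tibble::tibble(g4_count = cats, value = as.numeric(means)))
  expect_lt(abs(fit$slope - 3), 0.05)
  expect_lt(abs(fit$intercept - 2), 0.4)
  # dbSNV column is flat in the G4 category
  dmeans <- tapply(wt$dbsnv_count, wt$g4_count, mean)
  expect_lt(diff(range(dmeans)), 6 * sqrt(10 / 2000) * 2)
})

test_that("simulate_survival plants a proportional-hazards effect", {
  # null: survival independent of the covariate
  cohort0 <- simulate_survival_cohort(2000L, cox_beta = 0,
                                      censor_rate = 0.3, seed = 8L)
  f0 <- fit_cox(cohort0, "g4_average")
  expect_gt(f0$coefficients$p_value[1], 0.01)
  # all-censored degenerate input cannot be fitted
  allc <- simulate_survival_cohort(100L, censor_rate = 1, seed = 8L)
  expect_equal(sum(allc$event), 0L)
  expect_error(fit_cox(allc, "g4_average"), "event")
  expect_error(
    simulate_survival(tibble::tibble(g4_average = 1), 0.3, -1),
    "positive"
  )
})
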