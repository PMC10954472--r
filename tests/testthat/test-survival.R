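test_that("patient metrics follow the window-selection arithmetic", {
  windows <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 5000L, 10000L),
    end = c(5000L, 10000L, 15000L),
    g4_count = c(2L, 4L, 0L)
  )
  csnvs <- tibble::tibble(
    chrom = "chr1",
    pos = c(100L, 5100L, 5200L, 5300L, 12000L),
    patient_id = c("a", "a", "a", "a", "b")
  )
  m <- patient_g4_metrics(windows, csnvs)
  a <- m[m$patient_id == "a", ]
  expect_equal(a$g4_average, 3)                 # mean of (2, 4)
  expect_equal(a$normalized_g4_average, 0.5)    # 3 / (2 + 4)
  expect_equal(a$csnv_average, 2)               # counts (1, 3)
  b <- m[m$patient_id == "b", ]
  expect_equal(b$g4_average, 0)
  expect_true(is.na(b$normalized_g4_average))   # zero G4 sum is undefined
  expect_equal(b$csnv_average, 1)
  expect_true(all(m$csnv_average >= 1))

  # a patient whose cSNVs hit no table window is excluded with a warning
  csnvs2 <- rbind(csnvs,
                  tibble::tibble(chrom = "chr9", pos = 1L, patient_id = "c"))
  expect_warning(m2 <- patient_g4_metrics(windows, csnvs2), "excluded")
  expect_false("c" %in% m2$patient_id)
})

test_that("duplicating every window preserves the mean, halves the normalized average", {
  windows <- tibble::tibble(
    chrom = "chr1", start = c(0L, 5000L), end = c(5000L, 10000L),
    g4_count = c(2L, 4L)
  )
  csnvs <- tibble::tibble(chrom = "chr1", pos = c(100L, 5100L),
                          patient_id = "a")
  dup_windows <- rbind(
    windows,
    dplyr::mutate(windows, chrom = "chr1dup")
  )
  dup_csnvs <- rbind(
    csnvs,
    dplyr::mutate(csnvs, chrom = "chr1dup")
  )
  m1 <- patient_g4_metrics(windows, csnvs)
  m2 <- patient_g4_metrics(dup_windows, dup_csnvs)
  expect_equal(m2$g4_average, m1$g4_average)
  expect_equal(m2$normalized_g4_average, m1$normalized_g4_average / 2)
})

test_that("intra-cancer variance is the scale-free sd/mean", {
  s <- tibble::tibble(
    cancer_type = c("A", "A", "A", "B", "B", "C"),
    g4_average = c(1, 1, 1, 2, 4, 5)
  )
  v <- intra_cancer_variance(s)
  expect_equal(v$normalized_std[v$cancer_type == "A"], 0)
  b <- v[v$cancer_type == "B", ]
  expect_equal(b$sd_g4_average, sqrt(2), tolerance = 1e-6)
  expect_equal(round(b$normalized_std, 4), 0.4714)
  # singleton group is flagged
  expect_true(v$flagged[v$cancer_type == "C"])
  # scale invariance
  v10 <- intra_cancer_variance(dplyr::mutate(s, g4_average = g4_average * 10))
  expect_equal(v10$normalized_std, v$normalized_std)
})

test_that("survival cohort selection drops non-cancer deaths and incomplete records", {
  pats <- tibble::tibble(
    patient_id = c("a", "b", "c", "d", "e"),
    time = c(10, 20, NA, 40, 50),
    vital_status = c("dead", "dead", "dead", "alive", "dead"),
    death_cause = c("cancer", "other", "cancer", NA, "cancer")
  )
  sel <- select_survival_cohort(pats)
  expect_equal(sel$patients$patient_id, c("a", "d", "e"))
  expect_equal(sel$patients$event, c(1L, 0L, 1L))
  expect_equal(sel$report$n_noncancer_death, 1L)
  expect_equal(sel$report$n_missing, 1L)
  expect_equal(sel$report$n_retained + sel$report$n_missing +
                 sel$report$n_noncancer_death, 5L)
})

test_that("fit_cox equals the grid-search partial-likelihood oracle", {
  toy <- tibble::tibble(
    time = c(1, 2, 3, 4, 5),
    event = c(1L, 1L, 1L, 1L, 1L),
    g4_average = c(1, 0, 1, 0, 0)
  )
  f <- fit_cox(toy, "g4_average")
  oracle <- oracle_cox_grid(toy$time, toy$event, toy$g4_average)
  expect_equal(f$coefficients$estimate, oracle, tolerance = 1e-4)
  expect_equal(f$coefficients$hazard_ratio,
               exp(f$coefficients$estimate), tolerance = 1e-12)

  # with tied event times, Breslow still matches the oracle
  tied <- tibble::tibble(
    time = c(1, 1, 2, 3, 3, 4),
    event = c(1L, 1L, 1L, 0L, 1L, 1L),
    g4_average = c(2, 1, 0, 1, 3, 0)
  )
  ft <- fit_cox(tied, "g4_average")
  expect_equal(ft$coefficients$estimate,
               oracle_cox_grid(tied$time, tied$event, tied$g4_average),
               tolerance = 1e-4)
  # Efron mode runs and differs only modestly on these ties
  fe <- fit_cox(tied, "g4_average", ties = "efron")
  expect_lt(abs(fe$coefficients$estimate - ft$coefficients$estimate), 0.5)
})

test_that("fit_cox rejects degenerate inputs", {
  ok <- tibble::tibble(time = 1:10, event = rep(1L, 10),
                       g4_average = rnorm(10))
  expect_error(fit_cox(dplyr::mutate(ok, event = 0L), "g4_average"), "event")
  expect_error(fit_cox(dplyr::mutate(ok, g4_average = 1), "g4_average"),
               "variance")
  expect_error(fit_cox(ok, "nope"), "not in table")
})

test_that("a perfectly ordering risk score has concordance 1", {
  time <- c(5, 4, 3, 2, 1)
  event <- rep(1L, 5)
  risk <- c(1, 2, 3, 4, 5)     # shortest survival = highest risk
  expect_equal(concordance_index(time, event, risk), 1)
  expect_equal(concordance_index(time, event, -risk), 0)
  expect_equal(concordance_index(time, event, rep(0, 5)), 0.5)
  # coxph's reported concordance agrees with the direct count
  cohort <- simulate_survival_cohort(300L, cox_beta = 0.5, seed = 17L)
  f <- fit_cox(cohort, "g4_average")
  ci <- concordance_index(cohort$time, cohort$event,
                          cohort$g4_average * f$coefficients$estimate)
  expect_equal(f$concordance, ci, tolerance = 0.01)
})

test_that("concordance grows monotonically with the planted effect", {
  cs <- vapply(c(0, 0.2, 0.4, 0.8), function(beta) {
    cohort <- simulate_survival_cohort(1500L, cox_beta = beta, seed = 18L)
    fit_cox(cohort, "g4_average")$concordance
  }, numeric(1))
  expect_true(all(diff(cs) > 0))
  expect_lt(abs(cs[1] - 0.5), 0.03)
})

test_that("null covariates give coefficients centred at zero", {
  est <- vapply(1:40, function(s) {
    cohort <- simulate_survival_cohort(400L, cox_beta = 0, seed = 500L + s)
    fit_cox(cohort, "g4_average")$coefficients$estimate
  }, numeric(1))
  expect_lt(abs(mean(est)), 2 * sd(est) / sqrt(length(est)))
})
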