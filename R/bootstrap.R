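# Incomplete categorical bootstrapping and linear-regression modelling on
# window tables.
#
# Windows are stratified by their G4 count (categories 0..15 after the G4
# cap). Category sizes are wildly unequal, so each retained category
# contributes exactly n_permutations points: each point is the average of
# I windows resampled (with replacement) from that category. Averaging
# shrinks within-category variance like 1/I, so the linear fit through the
# resampled points converges to the fit through the category means as I
# grows.

#' Bootstrap configuration
#'
#' Three preset profiles bundle the published parameter lists
#' (permutations 250/500/1000, cycles 10/20/50, increments 10/5/1):
#' `"small"` (250, 10, step 10), `"medium"` (500, 20, step 5) and
#' `"large"` (1000, 50, step 1), each sweeping I up to 100.
#'
#' @param profile Preset name, or `NULL` when giving fields directly.
#' @param n_permutations Resampled points per category.
#' @param i_max Largest subsample size I.
#' @param i_step Increment of I across the sweep.
#' @param cycles Independent repeats of the whole sweep.
#' @param seed Integer seed.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(profile = NULL, n_permutations = 500L,
                             i_max = 100L, i_step = 5L, cycles = 20L,
                             seed = 1L) {
  if (!is.null(profile)) {
    preset <- switch(match.arg(profile, c("small", "medium", "large")),
      small = list(n_permutations = 250L, i_step = 10L, cycles = 10L),
      medium = list(n_permutations = 500L, i_step = 5L, cycles = 20L),
      large = list(n_permutations = 1000L, i_step = 1L, cycles = 50L)
    )
    n_permutations <- preset$n_permutations
    i_step <- preset$i_step
    cycles <- preset$cycles
  }
  stopifnot(n_permutations >= 1, i_max >= 1, i_step >= 1, i_step <= i_max,
            cycles >= 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 i_max = as.integer(i_max), i_step = as.integer(i_step),
                 cycles = as.integer(cycles), seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Incomplete categorical bootstrap of a window table
#'
#' For each G4 category present in the table, draws `n_permutations`
#' subsets of `I` windows (with replacement by default) and reduces each
#' subset to its mean SNV count, yielding `n_permutations` points per
#' category regardless of category size.
#'
#' @param windows Counted window tibble.
#' @param snv_kind `"cSNV"` or `"dbSNV"`.
#' @param config A [bootstrap_config()]; its `n_permutations` and `seed`
#'   are used.
#' @param I Subsample size (>= 1). `I = 1` returns raw resampled values.
#' @param replace Sample with replacement (bootstrap semantics). Without
#'   replacement requires category size >= I.
#' @return Tibble with `g4_count` (the category, used as x) and `value`
#'   (the averaged resample); empty categories are absent (a warning is
#'   raised if any category between 0 and the maximum observed count has
#'   no windows).
#' @export
categorical_bootstrap <- function(windows, snv_kind = c("cSNV", "dbSNV"),
                                  config = bootstrap_config(), I = 10L,
                                  replace = TRUE) {
  snv_kind <- match.arg(snv_kind)
  if (I < 1) abort("I must be >= 1")
  v <- if (snv_kind == "cSNV") windows$csnv_count else windows$dbsnv_count
  cats <- sort(unique(windows$g4_count))
  missing_cats <- setdiff(seq(0L, max(cats)), cats)
  if (length(missing_cats) > 0) {
    warn(paste0("no windows in G4 categories: ",
                paste(missing_cats, collapse = ", ")))
  }
  draw <- function() {
    purrr::map(cats, function(cat) {
      vals <- v[windows$g4_count == cat]
      if (!replace && length(vals) < I) {
        abort(sprintf(
          "category %d has %d windows < I = %d (without replacement)",
          cat, length(vals), I))
      }
      m <- matrix(
        vals[sample.int(length(vals), config$n_permutations * I,
                        replace = replace)],
        nrow = I
      )
      tibble(g4_count = cat, value = colMeans(m))
    }) %>% bind_rows()
  }
  withr::with_seed(config$seed, draw())
}

#' Ordinary least-squares fit of bootstrapped points
#'
#' @param points Tibble with `g4_count` (x) and `value` (y) columns, or
#'   any tibble whose first two columns are x and y.
#' @return A `g4_regression` tibble row: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
fit_linear <- function(points) {
  x <- if ("g4_count" %in% names(points)) points$g4_count else points[[1]]
  y <- if ("value" %in% names(points)) points$value else points[[2]]
  if (length(unique(x)) < 2) abort("need at least 2 distinct x values")
  fit <- lm(y ~ x)
  rss <- sum(residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(
    tibble(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      n_points = length(x)
    ),
    class = c("g4_regression", "tbl_df", "tbl", "data.frame")
  )
}

#' Sweep the bootstrap over increasing subsample sizes
#'
#' For `I = i_step, 2 i_step, ..., i_max` and each of `cycles` repeats,
#' runs [categorical_bootstrap()] followed by [fit_linear()] and collects
#' the slope, intercept and r-squared traces. Cycle seeds are derived
#' deterministically from `config$seed`.
#'
#' @inheritParams categorical_bootstrap
#' @return A `g4_bootstrap_sweep` tibble with one row per (cycle, I):
#'   `cycle`, `I`, `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
bootstrap_sweep <- function(windows, snv_kind = c("cSNV", "dbSNV"),
                            config = bootstrap_config()) {
  snv_kind <- match.arg(snv_kind)
  i_grid <- seq(config$i_step, config$i_max, by = config$i_step)
  grid <- tidyr::expand_grid(cycle = seq_len(config$cycles), I = i_grid)
  rows <- purrr::pmap(grid, function(cycle, I) {
    cfg_i <- config
    cfg_i$seed <- seq_seed(config$seed, 1000L * cycle + I)
    pts <- suppressWarnings(
      categorical_bootstrap(windows, snv_kind, cfg_i, I = I)
    )
    fit <- fit_linear(pts)
    tibble(cycle = cycle, I = I, slope = fit$slope,
           intercept = fit$intercept, r_squared = fit$r_squared,
           n_points = fit$n_points)
  })
  out <- bind_rows(rows)
  structure(out, class = c("g4_bootstrap_sweep", class(out)),
            snv_kind = snv_kind, config = config)
}

#' Summarise a bootstrap sweep per subsample size
#'
#' Median (and quantile band) of slope and r-squared over cycles at each
#' I; analytic OLS standard errors are not meaningful on resampled
#' points, so quantiles over cycles are used instead.
#'
#' @param sweep A [bootstrap_sweep()] result.
#' @return Tibble per I: `median_slope`, `median_r_squared`, and 10/90%
#'   quantiles.
#' @export
summarise_sweep <- function(sweep) {
  sweep %>%
    as_tibble() %>%
    group_by(.data$I) %>%
    summarise(
      median_slope = median(.data$slope),
      slope_q10 = quantile(.data$slope, 0.1),
      slope_q90 = quantile(.data$slope, 0.9),
      median_r_squared = median(.data$r_squared),
      r2_q10 = quantile(.data$r_squared, 0.1),
      r2_q90 = quantile(.data$r_squared, 0.9),
      .groups = "drop"
    )
}

#' Train/test linear regression on the whole window table
#'
#' Ordinary least squares of the SNV count on the G4 count, fitted on a
#' random 70% training split with r-squared reported on the held-out 30%
#' (relative to the test-set mean).
#'
#' @param windows Counted window tibble (>= 10 rows).
#' @param snv_kind `"cSNV"` or `"dbSNV"`.
#' @param train_fraction Fraction of windows used for fitting.
#' @param seed Integer seed controlling the split.
#' @return A `g4_regression` row with `slope`, `intercept`, `r_squared`
#'   (held-out), `n_points` (test-set size).
#' @export
whole_table_regression <- function(windows, snv_kind = c("cSNV", "dbSNV"),
                                   train_fraction = 0.7, seed = 1L) {
  snv_kind <- match.arg(snv_kind)
  if (nrow(windows) < 10) abort("need at least 10 windows")
  v <- if (snv_kind == "cSNV") windows$csnv_count else windows$dbsnv_count
  x <- windows$g4_count
  withr::with_seed(seed, {
    n <- length(v)
    tr <- sample.int(n, floor(train_fraction * n))
    if (length(tr) < 2 || length(tr) >= n) abort("degenerate train/test split")
    if (length(unique(x[tr])) < 2) abort("training split has a single x value")
    fit <- lm(y ~ x, data = data.frame(x = x[tr], y = v[tr]))
    pred <- predict(fit, newdata = data.frame(x = x[-tr]))
    rss <- sum((v[-tr] - pred)^2)
    tss <- sum((v[-tr] - mean(v[-tr]))^2)
    structure(
      tibble(
        slope = unname(coef(fit)[2]),
        intercept = unname(coef(fit)[1]),
        r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
        n_points = n - length(tr)
      ),
      class = c("g4_regression", "tbl_df", "tbl", "data.frame")
    )
  })
}

#' @export
tidy.g4_regression <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.g4_regression <- function(x, ...) {
  as_tibble(unclass(x))
}
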