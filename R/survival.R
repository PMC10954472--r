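# Patient-level G4 statistics and Cox proportional-hazards survival
# modelling.

#' Per-patient G4-average, normalized G4-average and cSNV-average
#'
#' For each patient, the windows of the (filtered) window table in which
#' that patient has at least one cSNV are selected. The G4-average is the
#' mean G4 count over those windows; the normalized G4-average divides it
#' by the summed G4 count over the same windows (undefined, `NA`, when
#' the sum is zero); the cSNV-average is the mean of the patient's
#' per-window cSNV counts (always >= 1 since every selected window holds
#' at least one of the patient's cSNVs).
#'
#' @param windows Counted (and typically G4-capped) window tibble.
#' @param csnvs SNV tibble with `chrom`, `pos`, `patient_id`.
#' @return Tibble per patient: `patient_id`, `n_windows`, `g4_average`,
#'   `normalized_g4_average`, `csnv_average`. Patients none of whose
#'   cSNVs fall into a table window are excluded with a warning.
#' @export
patient_g4_metrics <- function(windows, csnvs) {
  stopifnot(all(c("g4_count") %in% names(windows)),
            all(c("chrom", "pos", "patient_id") %in% names(csnvs)))
  pts <- genomic_intervals(csnvs$chrom, csnvs$pos, csnvs$pos + 1L)
  widx <- window_index_of(pts, windows)
  assigned <- tibble(patient_id = csnvs$patient_id, window = widx) %>%
    filter(!is.na(.data$window))
  lost <- setdiff(unique(csnvs$patient_id), unique(assigned$patient_id))
  if (length(lost) > 0) {
    warn(sprintf("%d patient(s) have no cSNV-bearing window and are excluded",
                 length(lost)))
  }
  per_window <- assigned %>%
    count(.data$patient_id, .data$window, name = "patient_csnvs")
  per_window %>%
    mutate(g4 = windows$g4_count[.data$window]) %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_windows = n(),
      g4_average = mean(.data$g4),
      normalized_g4_average = ifelse(sum(.data$g4) > 0,
                                     mean(.data$g4) / sum(.data$g4),
                                     NA_real_),
      csnv_average = mean(.data$patient_csnvs),
      .groups = "drop"
    )
}

#' Intra-cancer variance of patient G4-averages
#'
#' Patients are grouped by cancer type; the normalized standard deviation
#' is the group (sample) standard deviation divided by the group mean --
#' a scale-free index of within-diagnosis heterogeneity.
#'
#' @param summaries Patient tibble with `cancer_type` and `g4_average`.
#' @param population Use the population (divide by n) instead of the
#'   sample standard deviation.
#' @return Tibble per cancer type: `n_patients`, `mean_g4_average`,
#'   `sd_g4_average`, `normalized_std` (`NA`, flagged, for singleton
#'   groups or zero means).
#' @export
intra_cancer_variance <- function(summaries, population = FALSE) {
  stopifnot(all(c("cancer_type", "g4_average") %in% names(summaries)))
  summaries %>%
    group_by(.data$cancer_type) %>%
    summarise(
      n_patients = n(),
      mean_g4_average = mean(.data$g4_average),
      sd_g4_average = if (population) {
        sqrt(mean((.data$g4_average - mean(.data$g4_average))^2))
      } else {
        sd(.data$g4_average)
      },
      .groups = "drop"
    ) %>%
    mutate(
      normalized_std = ifelse(
        .data$n_patients < 2 | .data$mean_g4_average == 0,
        NA_real_,
        .data$sd_g4_average / .data$mean_g4_average
      ),
      flagged = .data$n_patients < 2 | .data$mean_g4_average == 0
    )
}

#' Select the survival-analysis cohort
#'
#' Keeps patients who died of cancer (event = 1) or remained alive
#' (event = 0, censored at last follow-up); drops records with missing
#' survival time or vital status and deaths from non-cancer causes.
#'
#' @param patients Tibble with `time`, `vital_status` (`"dead"`/
#'   `"alive"`) and `death_cause` (`"cancer"`/`"other"`/`NA`) columns.
#' @return List with `patients` (filtered, with an `event` column) and
#'   `report` (counts of dropped records by reason).
#' @export
select_survival_cohort <- function(patients) {
  stopifnot(all(c("time", "vital_status") %in% names(patients)))
  cause <- if ("death_cause" %in% names(patients)) {
    patients$death_cause
  } else {
    ifelse(patients$vital_status == "dead", "cancer", NA_character_)
  }
  missing <- is.na(patients$time) | is.na(patients$vital_status) |
    !patients$vital_status %in% c("dead", "alive")
  noncancer <- !missing & patients$vital_status == "dead" &
    (is.na(cause) | cause != "cancer")
  keep <- !missing & !noncancer
  out <- patients[keep, , drop = FALSE]
  out$event <- as.integer(out$vital_status == "dead")
  list(
    patients = out,
    report = tibble(
      n_input = nrow(patients),
      n_missing = sum(missing),
      n_noncancer_death = sum(noncancer),
      n_retained = sum(keep),
      n_events = sum(out$event),
      n_censored = sum(out$event == 0)
    )
  )
}

#' Fit Cox's proportional-hazards model on patient summaries
#'
#' Maximises the Cox partial likelihood (via [survival::coxph()]) for the
#' given covariates, with the Breslow approximation for tied event times
#' by default (Efron available). Covariates enter unstandardised so that
#' the coefficient reads as the log-hazard change per one-unit increase.
#'
#' @param summaries Patient tibble with `time`, `event` and the covariate
#'   columns.
#' @param covariates Character vector of covariate column names (e.g.
#'   `c("g4_average", "csnv_average")`).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param standardize Z-score the covariates before fitting.
#' @return A `g4_cox_fit` list: `coefficients` tibble (term, estimate =
#'   log hazard, hazard_ratio, std_error, p_value, conf_low, conf_high),
#'   `concordance` (Harrell's C over comparable pairs), `n_patients`,
#'   `n_events`, and the underlying `coxph` fit.
#' @export
fit_cox <- function(summaries, covariates = "g4_average",
                    ties = c("breslow", "efron"), standardize = FALSE) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(summaries)))
  miss <- setdiff(covariates, names(summaries))
  if (length(miss) > 0) {
    abort(paste0("covariate(s) not in table: ", paste(miss, collapse = ", ")))
  }
  dat <- summaries[c("time", "event", covariates)]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (sum(dat$event) < 2) abort("need at least 2 events to fit the model")
  for (cv in covariates) {
    if (sd(dat[[cv]]) == 0) abort(paste0("covariate has zero variance: ", cv))
    if (standardize) dat[[cv]] <- as.numeric(scale(dat[[cv]]))
  }
  fml <- stats::as.formula(
    paste("survival::Surv(time, event) ~",
          paste(sprintf("`%s`", covariates), collapse = " + "))
  )
  fit <- survival::coxph(fml, data = dat, ties = ties)
  if (!is.null(fit$info) && any(is.na(coef(fit)))) {
    abort("Cox model did not converge")
  }
  s <- summary(fit)
  coefs <- tibble(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, "coef"],
    hazard_ratio = s$coefficients[, "exp(coef)"],
    std_error = s$coefficients[, "se(coef)"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    conf_low = s$coefficients[, "coef"] - 1.96 * s$coefficients[, "se(coef)"],
    conf_high = s$coefficients[, "coef"] + 1.96 * s$coefficients[, "se(coef)"]
  )
  coefs$term <- gsub("`", "", coefs$term)
  structure(
    list(
      coefficients = coefs,
      concordance = unname(s$concordance["C"]),
      n_patients = nrow(dat),
      n_events = sum(dat$event),
      ties = ties,
      fit = fit
    ),
    class = "g4_cox_fit"
  )
}

#' @export
print.g4_cox_fit <- function(x, ...) {
  cat(sprintf("<Cox PH fit: %d patients, %d events, %s ties>\n",
              x$n_patients, x$n_events, x$ties))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  cat(sprintf("  concordance = %.3f\n", x$concordance))
  invisible(x)
}

#' @export
tidy.g4_cox_fit <- function(x, ...) {
  x$coefficients
}

#' @export
glance.g4_cox_fit <- function(x, ...) {
  tibble(
    n_patients = x$n_patients,
    n_events = x$n_events,
    concordance = x$concordance,
    ties = x$ties
  )
}

#' Harrell's concordance index of a risk score
#'
#' Fraction of comparable patient pairs (the earlier time an event) whose
#' risk ordering matches their survival ordering; ties in risk count 1/2.
#' Exposed mainly for validation of fitted models.
#'
#' @param time,event Survival times and event indicators.
#' @param risk Risk scores (higher = shorter expected survival).
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(time, event, risk) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  conc <- 0
  comp <- 0
  for (i in which(event == 1)) {
    later <- which(time > time[i])
    comp <- comp + length(later)
    conc <- conc + sum(risk[i] > risk[later]) +
      0.5 * sum(risk[i] == risk[later])
  }
  if (comp == 0) return(NA_real_)
  conc / comp
}
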