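# Orchestration: write a synthetic study to disk, run the full analysis
# chain, and render summary tables.

#' Write a synthetic study to disk
#'
#' Generates a dataset with [simulate_study()] and writes every component
#' in a plain-text exchange format: FASTA genome, BED interval files, TSV
#' SNV/patient tables, a JSON truth record and a checksum manifest.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory.
#' @param force Overwrite a non-empty directory.
#' @return The dataset, invisibly; side effect: files in `outdir`.
#' @export
run_simulate <- function(config = synthetic_config(), outdir,
                         force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    abort(paste0("output directory not empty (use force = TRUE): ", outdir))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_study(config)

  write_fasta(ds$genome, file.path(outdir, "genome.fasta"))
  write_bed(ds$genes, file.path(outdir, "genes.bed"))
  write_bed(ds$exons, file.path(outdir, "exons.bed"))
  write_bed(ds$g4s, file.path(outdir, "g4s.bed"))
  readr::write_tsv(ds$csnvs, file.path(outdir, "csnvs.tsv"))
  readr::write_tsv(ds$dbsnvs, file.path(outdir, "dbsnvs.tsv"))
  readr::write_tsv(ds$patients, file.path(outdir, "patients.tsv"))
  writeLines(ds$cancer_genes, file.path(outdir, "cancer_genes.txt"))
  jsonlite::write_json(ds$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- c("genome.fasta", "genes.bed", "exons.bed", "g4s.bed",
             "csnvs.tsv", "dbsnvs.tsv", "patients.tsv", "cancer_genes.txt",
             "truth.json")
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ds)
}

#' Load a study previously written by [run_simulate()]
#'
#' @param dir Directory containing the study files.
#' @return A `g4_dataset` list (without a recomputed window table).
#' @export
read_study <- function(dir) {
  need <- c("genome.fasta", "genes.bed", "exons.bed", "g4s.bed",
            "csnvs.tsv", "dbsnvs.tsv", "patients.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss) > 0) {
    abort(paste0("study directory lacks: ", paste(miss, collapse = ", ")))
  }
  snv_cols <- readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    patient_id = readr::col_character(),
    cancer_type = readr::col_character(), tissue = readr::col_character()
  )
  structure(
    list(
      genome = read_fasta(file.path(dir, "genome.fasta")),
      genes = read_bed(file.path(dir, "genes.bed")),
      exons = read_bed(file.path(dir, "exons.bed")),
      g4s = read_bed(file.path(dir, "g4s.bed")),
      csnvs = readr::read_tsv(file.path(dir, "csnvs.tsv"),
                              col_types = snv_cols),
      dbsnvs = readr::read_tsv(file.path(dir, "dbsnvs.tsv"),
                               col_types = snv_cols),
      patients = readr::read_tsv(file.path(dir, "patients.tsv"),
                                 show_col_types = FALSE),
      cancer_genes = if (file.exists(file.path(dir, "cancer_genes.txt"))) {
        readLines(file.path(dir, "cancer_genes.txt"))
      } else {
        character()
      },
      config = NULL
    ),
    class = "g4_dataset"
  )
}

#' Run the full analysis chain on a study
#'
#' Pipeline order: cohort preprocessing (germline filter, cancer-type
#' exclusion) -> gene-restricted window tiling with exonic feature counts
#' and the G4 cap -> distance profiles and Gaussian fits (cSNV and dbSNV)
#' -> stratified enrichment, GC-controlled partial correlation and
#' gene-class comparison -> incomplete categorical bootstrap sweeps and
#' whole-table regression -> patient G4 metrics, intra-cancer variance,
#' survival-cohort selection and the Cox model. All stochastic stages are
#' seeded, so a re-run with the same inputs reproduces the summary
#' byte-identically.
#'
#' @param x A `g4_dataset` (from [simulate_study()] / [run_simulate()]) or
#'   a directory path for [read_study()].
#' @param window_size,flank Window tiling parameters (bp).
#' @param max_g4 G4 cap per window.
#' @param min_samples Cancer-type exclusion threshold.
#' @param range,binwidth Distance-profile parameters (bp).
#' @param bootstrap_profile Preset for [bootstrap_config()].
#' @param i_max Largest bootstrap subsample size.
#' @param seed Seed for the bootstrap and the train/test split.
#' @param outdir Optional directory for the JSON summary and TSV tables.
#' @return A `g4_analysis` list of stage results (see Details in the
#'   package vignette).
#' @export
run_analyze <- function(x, window_size = 5000L, flank = 2000L,
                        max_g4 = 15L, min_samples = 10L,
                        range = 5000L, binwidth = 50L,
                        bootstrap_profile = "small", i_max = 100L,
                        seed = 1L, outdir = NULL) {
  ds <- if (is.character(x)) read_study(x) else x
  stopifnot(inherits(ds, "g4_dataset"))

  pre <- preprocess_cohort(ds$csnvs, ds$dbsnvs, ds$patients, min_samples)
  csnvs <- pre$csnvs

  gene_class <- tibble(
    name = ds$genes$name,
    gene_class = ifelse(ds$genes$name %in% ds$cancer_genes,
                        "cancer", "non-cancer")
  )
  wins <- restrict_windows_to_genes(
    ds$genes, ds$exons, window_size, flank = flank,
    chrom_lengths = chrom_lengths(ds$genome)
  )
  windows <- count_features(wins, ds$g4s, csnvs, ds$dbsnvs, ds$exons,
                            genome = ds$genome, genes = ds$genes,
                            gene_class = gene_class)
  windows <- cap_window_g4(windows, max_g4)
  windows <- gc_normalized_counts(windows)

  safe_fit <- function(profile) {
    tryCatch(suppressWarnings(fit_gaussian(profile)),
             error = function(e) NULL)
  }
  prof_csnv <- distance_profile(csnvs, ds$g4s, range, binwidth)
  prof_dbsnv <- distance_profile(ds$dbsnvs, ds$g4s, range, binwidth)
  fit_csnv <- safe_fit(prof_csnv)
  fit_dbsnv <- safe_fit(prof_dbsnv)

  enrich_csnv <- suppressWarnings(stratify_enrichment(windows, "cSNV"))
  enrich_dbsnv <- suppressWarnings(stratify_enrichment(windows, "dbSNV"))
  pearson_csnv <- window_pearson(windows$g4_count, windows$csnv_count)
  pearson_dbsnv <- window_pearson(windows$g4_count, windows$dbsnv_count)
  gc_frac <- windows$gc_bp / (windows$end - windows$start)
  partial <- partial_correlation(windows$g4_count, windows$csnv_count,
                                 gc_frac)
  classes <- suppressWarnings(
    gene_class_comparison(windows, ds$genes, gene_class, ds$g4s, "cSNV")
  )

  bcfg <- bootstrap_config(bootstrap_profile, i_max = i_max, seed = seed)
  sweep_csnv <- bootstrap_sweep(windows, "cSNV", bcfg)
  sweep_dbsnv <- bootstrap_sweep(windows, "dbSNV", bcfg)
  regression <- whole_table_regression(windows, "cSNV", seed = seed)

  metrics <- suppressWarnings(patient_g4_metrics(windows, csnvs))
  summaries <- dplyr::inner_join(
    pre$patients, metrics, by = "patient_id",
    suffix = c("_given", "")
  )
  variance <- intra_cancer_variance(summaries)
  cox <- NULL
  cohort <- NULL
  if (all(c("time", "vital_status") %in% names(summaries))) {
    sel <- select_survival_cohort(summaries)
    cohort <- sel$report
    cox <- tryCatch(
      fit_cox(sel$patients, c("g4_average", "csnv_average")),
      error = function(e) NULL
    )
  }

  res <- structure(
    list(
      filter_report = pre$report,
      windows = windows,
      profile_csnv = prof_csnv,
      profile_dbsnv = prof_dbsnv,
      fit_csnv = fit_csnv,
      fit_dbsnv = fit_dbsnv,
      fit_comparison = if (!is.null(fit_csnv) && !is.null(fit_dbsnv)) {
        compare_fits(fit_csnv, fit_dbsnv)
      } else {
        NULL
      },
      enrichment_csnv = enrich_csnv,
      enrichment_dbsnv = enrich_dbsnv,
      pearson_csnv = pearson_csnv,
      pearson_dbsnv = pearson_dbsnv,
      partial_correlation = partial,
      gene_class = classes,
      sweep_csnv = sweep_csnv,
      sweep_dbsnv = sweep_dbsnv,
      regression = regression,
      patient_metrics = metrics,
      intra_cancer_variance = variance,
      survival_cohort = cohort,
      cox = cox,
      params = list(window_size = window_size, flank = flank,
                    max_g4 = max_g4, min_samples = min_samples,
                    range = range, binwidth = binwidth,
                    bootstrap_profile = bootstrap_profile, i_max = i_max,
                    seed = seed)
    ),
    class = "g4_analysis"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(analysis_summary(res),
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_tsv(windows, file.path(outdir, "windows.tsv"))
    readr::write_tsv(metrics, file.path(outdir, "patient_metrics.tsv"))
    readr::write_tsv(as_tibble(sweep_csnv),
                     file.path(outdir, "sweep_csnv.tsv"))
  }
  res
}

#' Condense an analysis into a flat summary list
#'
#' The JSON-ready digest written by [run_analyze()]: fit parameters,
#' correlations, sweep endpoints, Cox coefficients and the filter
#' accounting. Deterministic given the analysis object.
#'
#' @param res A `g4_analysis`.
#' @return A named list of scalars and small tables.
#' @export
analysis_summary <- function(res) {
  stopifnot(inherits(res, "g4_analysis"))
  sw <- summarise_sweep(res$sweep_csnv)
  last <- sw[which.max(sw$I), ]
  swd <- summarise_sweep(res$sweep_dbsnv)
  lastd <- swd[which.max(swd$I), ]
  list(
    filter = unclass(res$filter_report),
    n_windows = nrow(res$windows),
    gaussian_csnv = if (!is.null(res$fit_csnv)) {
      as.list(glance(res$fit_csnv))
    },
    gaussian_dbsnv = if (!is.null(res$fit_dbsnv)) {
      as.list(glance(res$fit_dbsnv))
    },
    sigma_fold_compression = if (!is.null(res$fit_comparison)) {
      res$fit_comparison$sigma_ratio
    },
    pearson_csnv = as.list(res$pearson_csnv),
    pearson_dbsnv = as.list(res$pearson_dbsnv),
    partial_correlation = as.list(res$partial_correlation),
    enrichment_csnv = res$enrichment_csnv,
    enrichment_dbsnv = res$enrichment_dbsnv,
    gene_g4_content = res$gene_class$gene_g4,
    bootstrap_csnv_at_imax = as.list(last),
    bootstrap_dbsnv_at_imax = as.list(lastd),
    regression = as.list(glance(res$regression)),
    intra_cancer_variance = res$intra_cancer_variance,
    survival_cohort = if (!is.null(res$survival_cohort)) {
      as.list(res$survival_cohort)
    },
    cox = if (!is.null(res$cox)) {
      list(coefficients = res$cox$coefficients,
           concordance = res$cox$concordance,
           n_patients = res$cox$n_patients,
           n_events = res$cox$n_events)
    },
    params = res$params
  )
}

#' @export
print.g4_analysis <- function(x, ...) {
  cat("<g4_analysis>\n")
  cat(sprintf("  windows: %d (after G4 cap)\n", nrow(x$windows)))
  if (!is.null(x$fit_csnv)) {
    cat(sprintf("  cSNV Gaussian:  mu %7.1f  sigma %7.1f  CI [%.0f, %.0f]\n",
                x$fit_csnv$mu, x$fit_csnv$sigma, x$fit_csnv$ci95_low,
                x$fit_csnv$ci95_high))
  }
  if (!is.null(x$fit_dbsnv)) {
    cat(sprintf("  dbSNV Gaussian: mu %7.1f  sigma %7.1f  CI [%.0f, %.0f]\n",
                x$fit_dbsnv$mu, x$fit_dbsnv$sigma, x$fit_dbsnv$ci95_low,
                x$fit_dbsnv$ci95_high))
  }
  if (!is.null(x$fit_comparison)) {
    cat(sprintf("  fold-compression (cSNV vs dbSNV): %.2f\n",
                x$fit_comparison$sigma_ratio))
  }
  cat(sprintf("  Pearson r (cSNV ~ G4): %.3f;  partial r | GC: %.3f\n",
              x$pearson_csnv$r, x$partial_correlation$r_xy_given_z))
  if (!is.null(x$cox)) {
    b <- x$cox$coefficients
    g <- b[b$term == "g4_average", ]
    if (nrow(g) == 1) {
      cat(sprintf("  Cox: beta(G4-average) = %.3f (HR %.2f, p = %.3g), C = %.3f\n",
                  g$estimate, g$hazard_ratio, g$p_value, x$cox$concordance))
    }
  }
  invisible(x)
}

#' Render human-readable report tables from an analysis
#'
#' Tabular mirrors of the figure panels: the distance profiles and fits,
#' stratified enrichment, gene-class G4 content, bootstrap traces,
#' per-cancer-type G4-averages and the Cox coefficients.
#'
#' @param res A `g4_analysis` object, or a path to a `summary.json`
#'   written by [run_analyze()].
#' @param outdir Optional directory; each table is also written as TSV.
#' @return Named list of tibbles.
#' @export
run_report <- function(res, outdir = NULL) {
  if (is.character(res)) {
    if (!file.exists(res)) abort(paste0("no such summary: ", res))
    s <- jsonlite::read_json(res, simplifyVector = TRUE)
    if (is.null(s$params)) abort("not a pipeline summary (no params echo)")
    tables <- list(
      enrichment_csnv = as_tibble(s$enrichment_csnv),
      enrichment_dbsnv = as_tibble(s$enrichment_dbsnv),
      gene_g4_content = as_tibble(s$gene_g4_content),
      intra_cancer_variance = as_tibble(s$intra_cancer_variance),
      cox = if (!is.null(s$cox)) as_tibble(s$cox$coefficients)
    )
  } else {
    stopifnot(inherits(res, "g4_analysis"))
    fits <- bind_rows(
      if (!is.null(res$fit_csnv)) {
        mutate(glance(res$fit_csnv), kind = "cSNV")
      },
      if (!is.null(res$fit_dbsnv)) {
        mutate(glance(res$fit_dbsnv), kind = "dbSNV")
      }
    )
    tables <- list(
      gaussian_fits = fits,
      enrichment_csnv = res$enrichment_csnv,
      enrichment_dbsnv = res$enrichment_dbsnv,
      gene_g4_content = res$gene_class$gene_g4,
      sweep_csnv = summarise_sweep(res$sweep_csnv),
      sweep_dbsnv = summarise_sweep(res$sweep_dbsnv),
      intra_cancer_variance = res$intra_cancer_variance,
      cox = if (!is.null(res$cox)) res$cox$coefficients
    )
  }
  tables <- tables[!vapply(tables, is.null, TRUE)]
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    purrr::iwalk(tables, function(tb, nm) {
      readr::write_tsv(tb, file.path(outdir, paste0(nm, ".tsv")))
    })
  }
  tables
}
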