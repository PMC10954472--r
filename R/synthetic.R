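# Synthetic-study generator.
#
# Produces complete artificial studies -- genome, gene/exon structure, a G4
# map, cSNV/dbSNV cohorts with planted spatial and window-level structure,
# patient metadata and survival outcomes -- so that every downstream stage
# of the pipeline can be validated against known ground truth.

#' Configuration for a synthetic study
#'
#' All planted quantities of the generator in one place. Defaults define
#' the package's standard study conditions: a compact exome-like genome
#' with G4s concentrated in a "cancer" gene class (2.8-fold planted
#' enrichment), cSNVs placed downstream of G4s (+200 +/- 150 bp) on top of
#' a window-level linear relation, dbSNVs placed upstream with a broader
#' spread (-1300 +/- 780 bp) and no linear relation, and survival times
#' from a proportional-hazards model on the patient G4-average.
#'
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param gc_fraction Genome-wide GC fraction of the random sequence.
#' @param n_genes Total genes, distributed round-robin across chromosomes.
#' @param exons_per_gene,exon_length,intron_length Gene architecture (bp);
#'   `intron_length = 0` makes genes fully exonic.
#' @param flank Flanking region (bp) added around genes when tiling
#'   analysis windows.
#' @param window_size Analysis window size in bp.
#' @param n_g4 Number of G4 intervals to place inside exons.
#' @param g4_length G4 interval length (bp).
#' @param g4_min_spacing Minimum start-to-start spacing between G4s on a
#'   chromosome (0 = none). Sparse spacing makes the nearest G4 of an SNV
#'   its anchoring G4, which the spatial-recovery preset relies on.
#' @param cancer_gene_fraction Fraction of genes labelled "cancer".
#' @param g4_cancer_fraction Fraction of G4s placed into cancer genes.
#'   The default 0.412 with 20% cancer genes plants a 2.8-fold per-gene
#'   G4 enrichment in the cancer class.
#' @param n_patients,n_cancer_types Cohort dimensions.
#' @param type_skew Skew of the patient-to-cancer-type assignment
#'   (0 = uniform); type k receives weight `(k / n_types)^type_skew`.
#' @param csnv_per_patient_mean Poisson mean of cSNV counts per patient.
#' @param n_dbsnv Total number of dbSNVs (population variants, no patient).
#' @param assoc_fraction Fraction of SNVs placed relative to a G4 (the
#'   rest are uniform background over exon space).
#' @param assoc_concentration Beta concentration of per-patient
#'   association propensities around `assoc_fraction`; `Inf` gives every
#'   patient exactly `assoc_fraction`.
#' @param offset_mean_csnv,offset_sd_csnv Planted Gaussian offset (bp) of
#'   associated cSNVs relative to the anchoring G4 (positive =
#'   downstream of the G4 end).
#' @param offset_mean_dbsnv,offset_sd_dbsnv Same for dbSNVs (negative =
#'   upstream of the G4 start).
#' @param linear_intercept,linear_slope Planted window-level relation:
#'   background cSNVs are allocated to windows with probability
#'   proportional to `intercept + slope * g4_count`.
#' @param cox_beta Planted log-hazard coefficient on the G4-average.
#' @param baseline_hazard Baseline event rate (events per time unit).
#' @param censor_rate Expected fraction of censored patients.
#' @param noncancer_death_rate Fraction of deaths relabelled as
#'   non-cancer deaths (exercised by [select_survival_cohort()]).
#' @param missing_rate Fraction of patients with survival time blanked.
#' @param seed Integer seed; the entire dataset is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_chroms = 2L,
                             chrom_length = 2e6,
                             gc_fraction = 0.5,
                             n_genes = 60L,
                             exons_per_gene = 8L,
                             exon_length = 1500L,
                             intron_length = 500L,
                             flank = 2000L,
                             window_size = 5000L,
                             n_g4 = 600L,
                             g4_length = 30L,
                             g4_min_spacing = 0L,
                             cancer_gene_fraction = 0.2,
                             g4_cancer_fraction = 0.412,
                             n_patients = 300L,
                             n_cancer_types = 8L,
                             type_skew = 0,
                             csnv_per_patient_mean = 40,
                             n_dbsnv = 12000L,
                             assoc_fraction = 0.5,
                             assoc_concentration = 3,
                             offset_mean_csnv = 200,
                             offset_sd_csnv = 150,
                             offset_mean_dbsnv = -1300,
                             offset_sd_dbsnv = 780,
                             linear_intercept = 2,
                             linear_slope = 3,
                             cox_beta = 0.32,
                             baseline_hazard = 0.01,
                             censor_rate = 0.3,
                             noncancer_death_rate = 0.05,
                             missing_rate = 0.02,
                             seed = 42L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(
      n_chroms > 0, chrom_length > 0, n_genes > 0, exons_per_gene > 0,
      exon_length > 0, intron_length >= 0, window_size > 0, n_g4 >= 0,
      g4_length > 0, n_patients > 0, n_cancer_types > 0,
      csnv_per_patient_mean > 0, n_dbsnv >= 0,
      assoc_fraction >= 0, assoc_fraction <= 1,
      offset_sd_csnv > 0, offset_sd_dbsnv > 0,
      gc_fraction > 0, gc_fraction < 1,
      censor_rate >= 0, censor_rate <= 1
    )
  })
  structure(cfg, class = "synthetic_config")
}

#' Sparse-G4 preset for spatial-recovery experiments
#'
#' A single exon-dense chromosome with widely spaced G4s, so that the
#' nearest G4 of every planted SNV is its anchoring G4 and Gaussian
#' offset parameters are recoverable from the distance profile.
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_config_spatial <- function(...) {
  preset <- list(
    n_chroms = 1L, chrom_length = 1e7, n_genes = 12L,
    exons_per_gene = 50L, exon_length = 15000L, intron_length = 0L,
    n_g4 = 300L, g4_min_spacing = 15000L,
    cancer_gene_fraction = 0, g4_cancer_fraction = 0,
    assoc_fraction = 1, assoc_concentration = Inf,
    linear_slope = 0, linear_intercept = 1
  )
  do.call(synthetic_config, utils::modifyList(preset, list(...)))
}

seq_seed <- function(seed, k) (as.integer(seed) + 7919L * k) %% 2147483647L

random_dna <- function(n, gc_fraction) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate the genome scaffold: sequence, genes and exons
#'
#' Genes are placed non-overlapping with random intergenic gaps; exons are
#' tiled within each gene (`exons_per_gene` exons of `exon_length`
#' separated by `intron_length`). Deterministic under `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `g4_dataset` list with `genome` (tibble of `name`,
#'   `sequence`), `genes`, `exons`, `cancer_genes` (character vector of
#'   gene names) and the config echo.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(seq_seed(config$seed, 1L), {
    gene_len <- config$exons_per_gene * config$exon_length +
      (config$exons_per_gene - 1L) * config$intron_length
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    genes_per_chrom <- tabulate(
      rep(seq_len(config$n_chroms), length.out = config$n_genes),
      nbins = config$n_chroms
    )
    if (any(genes_per_chrom * gene_len > config$chrom_length)) {
      abort("genes do not fit on the chromosome; increase chrom_length")
    }
    genes <- purrr::map2(chroms, genes_per_chrom, function(chr, k) {
      if (k == 0) return(NULL)
      slack <- config$chrom_length - k * gene_len
      # k+1 random gaps summing to the slack
      cuts <- sort(runif(k, 0, slack))
      starts <- as.integer(floor(cuts + (seq_len(k) - 1L) * gene_len))
      genomic_intervals(chr, starts, starts + gene_len)
    }) %>% bind_rows()
    genes$name <- sprintf("gene%03d", seq_len(nrow(genes)))
    n_cancer <- round(config$cancer_gene_fraction * nrow(genes))
    cancer_genes <- if (n_cancer > 0) {
      sample(genes$name, n_cancer)
    } else {
      character()
    }
    exon_pitch <- config$exon_length + config$intron_length
    exons <- purrr::pmap(
      list(genes$chrom, genes$start, genes$name),
      function(chr, gs, gname) {
        es <- gs + (seq_len(config$exons_per_gene) - 1L) * exon_pitch
        genomic_intervals(chr, es, es + config$exon_length,
                          name = sprintf("%s_ex%d", gname,
                                         seq_len(config$exons_per_gene)))
      }
    ) %>% bind_rows()
    genome <- tibble(
      name = chroms,
      sequence = vapply(chroms, function(.)
        random_dna(config$chrom_length, config$gc_fraction), "",
        USE.NAMES = FALSE)
    )
    structure(
      list(genome = genome, genes = genes, exons = sort_intervals(exons),
           cancer_genes = cancer_genes, g4s = NULL, csnvs = NULL,
           dbsnvs = NULL, patients = NULL, config = config),
      class = "g4_dataset"
    )
  })
}

#' Place G4 intervals inside exons
#'
#' `g4_cancer_fraction` of the G4s go to cancer-class genes and the rest
#' to the remaining genes (uniform within class); within a gene, a random
#' exon and a uniform start inside it. With `g4_min_spacing > 0`,
#' placements closer than the spacing to an accepted G4 are rejected and
#' redrawn, yielding a sparse map.
#'
#' @param dataset Output of [simulate_genome()].
#' @param config The same [synthetic_config()].
#' @return The dataset with a `g4s` interval tibble (strand random).
#' @export
place_g4s <- function(dataset, config = dataset$config) {
  stopifnot(inherits(dataset, "g4_dataset"))
  if (config$n_g4 == 0) {
    dataset$g4s <- genomic_intervals(character(), integer(), integer())
    return(dataset)
  }
  if (config$exon_length <= config$g4_length) {
    abort("exon_length must exceed g4_length")
  }
  withr::with_seed(seq_seed(config$seed, 2L), {
    exons <- dataset$exons
    exon_gene <- sub("_ex\\d+$", "", exons$name)
    is_cancer <- exon_gene %in% dataset$cancer_genes
    w <- rep(1, nrow(exons))
    if (any(is_cancer) && any(!is_cancer)) {
      w[is_cancer] <- config$g4_cancer_fraction / sum(is_cancer)
      w[!is_cancer] <- (1 - config$g4_cancer_fraction) / sum(!is_cancer)
    }
    draw_batch <- function(n) {
      ei <- sample.int(nrow(exons), n, replace = TRUE, prob = w)
      starts <- exons$start[ei] +
        floor(runif(n) * (config$exon_length - config$g4_length))
      tibble(chrom = exons$chrom[ei], start = as.integer(starts))
    }
    if (config$g4_min_spacing > 0) {
      kept <- tibble(chrom = character(), start = integer())
      for (round in 1:50) {
        need <- config$n_g4 - nrow(kept)
        if (need <= 0) break
        cand <- bind_rows(kept, draw_batch(need * 2L))
        cand <- cand[order(cand$chrom, cand$start), ]
        ok <- c(TRUE, cand$chrom[-1] != cand$chrom[-nrow(cand)] |
                  diff(cand$start) >= config$g4_min_spacing)
        # greedy: drop every candidate too close to its accepted predecessor
        keep <- logical(nrow(cand))
        last_chrom <- ""
        last_start <- -Inf
        for (i in seq_len(nrow(cand))) {
          if (cand$chrom[i] != last_chrom ||
              cand$start[i] - last_start >= config$g4_min_spacing) {
            keep[i] <- TRUE
            last_chrom <- cand$chrom[i]
            last_start <- cand$start[i]
          }
        }
        kept <- cand[keep, ][seq_len(min(sum(keep), config$n_g4)), ]
      }
      if (nrow(kept) < config$n_g4) {
        abort("could not place n_g4 G4s at the requested min spacing")
      }
      placed <- kept
    } else {
      placed <- draw_batch(config$n_g4)
    }
    g4s <- genomic_intervals(
      placed$chrom, placed$start, placed$start + config$g4_length,
      strand = sample(c("+", "-"), nrow(placed), replace = TRUE)
    )
    g4s <- sort_intervals(g4s)
    g4s$name <- sprintf("g4_%04d", seq_len(nrow(g4s)))
    dataset$g4s <- g4s
    dataset
  })
}

# Move positions outside exon space to the nearest exonic base.
snap_to_exons <- function(chrom, pos, exons) {
  out <- pos
  for (chr in unique(chrom)) {
    qi <- which(chrom == chr)
    ex <- exons[exons$chrom == chr, ]
    if (nrow(ex) == 0) next
    ex <- ex[order(ex$start), ]
    p <- pos[qi]
    i <- findInterval(p, ex$start)
    inside <- i >= 1L & p < ex$end[pmax(i, 1L)]
    prev_end <- ifelse(i >= 1L, ex$end[pmax(i, 1L)] - 1L, NA_integer_)
    nxt_start <- ifelse(i < nrow(ex), ex$start[pmin(i + 1L, nrow(ex))],
                        NA_integer_)
    d_prev <- ifelse(is.na(prev_end), Inf, p - prev_end)
    d_next <- ifelse(is.na(nxt_start), Inf, nxt_start - p)
    snapped <- ifelse(d_prev <= d_next, prev_end, nxt_start)
    out[qi] <- ifelse(inside, p, snapped)
  }
  as.integer(out)
}

make_patients <- function(config) {
  types <- sprintf("type%02d", seq_len(config$n_cancer_types))
  tissues <- sprintf("tissue%02d", ceiling(seq_len(config$n_cancer_types) / 2))
  wt <- (seq_len(config$n_cancer_types) / config$n_cancer_types)^config$type_skew
  ti <- sample.int(config$n_cancer_types, config$n_patients, replace = TRUE,
                   prob = wt)
  tibble(
    patient_id = sprintf("P%04d", seq_len(config$n_patients)),
    cancer_type = types[ti],
    tissue = tissues[ti]
  )
}

#' Place SNVs with planted spatial and window-level structure
#'
#' Two-layer generative model. Per SNV, with probability equal to the
#' patient's association propensity (centred on `assoc_fraction`) the SNV
#' is anchored to a G4 drawn with window-level weights and offset by a
#' Gaussian draw (`offset_mean_*`, `offset_sd_*`; the anchor is the G4
#' end for non-negative offsets and the G4 start for negative ones, so
#' the signed nearest-distance equals the rounded draw when G4s are
#' sparse). Otherwise the SNV is background, allocated to an exon with
#' probability proportional to the planted window rate
#' `linear_intercept + linear_slope * g4_count` (cSNVs only; dbSNV
#' background is uniform over exon space). Positions falling outside exon
#' space are snapped to the nearest exonic base.
#'
#' @param dataset Dataset with genes, exons and `g4s`.
#' @param config The [synthetic_config()].
#' @param kind `"cSNV"` (per-patient counts, Poisson) or `"dbSNV"`
#'   (`n_dbsnv` population variants without patients).
#' @return The dataset with `csnvs` or `dbsnvs` filled in: a tibble of
#'   `chrom`, `pos` (0-based), `patient_id`, `cancer_type`, `tissue`.
#' @export
place_snvs <- function(dataset, config = dataset$config,
                       kind = c("cSNV", "dbSNV")) {
  stopifnot(inherits(dataset, "g4_dataset"))
  kind <- match.arg(kind)
  if (config$assoc_fraction > 0 &&
      (is.null(dataset$g4s) || nrow(dataset$g4s) == 0)) {
    abort("assoc_fraction > 0 requires a non-empty G4 set; run place_g4s()")
  }
  withr::with_seed(seq_seed(config$seed, if (kind == "cSNV") 3L else 4L), {
    exons <- dataset$exons
    g4s <- dataset$g4s

    if (kind == "cSNV") {
      if (is.null(dataset$patients)) dataset$patients <- make_patients(config)
      counts <- rpois(config$n_patients, config$csnv_per_patient_mean)
      patient_idx <- rep(seq_len(config$n_patients), counts)
      n <- length(patient_idx)
      prop <- if (is.finite(config$assoc_concentration)) {
        m <- config$assoc_fraction
        k <- config$assoc_concentration
        if (m == 0 || m == 1) rep(m, config$n_patients)
        else rbeta(config$n_patients, k * m, k * (1 - m))
      } else {
        rep(config$assoc_fraction, config$n_patients)
      }
      assoc <- runif(n) < prop[patient_idx]
      mu <- config$offset_mean_csnv
      sdev <- config$offset_sd_csnv
    } else {
      n <- config$n_dbsnv
      patient_idx <- rep(NA_integer_, n)
      assoc <- runif(n) < config$assoc_fraction
      mu <- config$offset_mean_dbsnv
      sdev <- config$offset_sd_dbsnv
    }

    # window-level weights for the planted linear relation (cSNV only)
    windows <- make_windows(
      flank_regions(dataset$genes, config$flank,
                    chrom_lengths(dataset$genome)),
      config$window_size
    )
    windows$g4_count <- if (is.null(g4s) || nrow(g4s) == 0) {
      0L
    } else {
      intersect_count(windows, g4s)
    }
    win_weight <- pmax(0, config$linear_intercept +
                         config$linear_slope * windows$g4_count)

    # map exons and G4s to their (midpoint) window
    exon_mid <- genomic_intervals(
      exons$chrom, (exons$start + exons$end) %/% 2L,
      (exons$start + exons$end) %/% 2L + 1L
    )
    exon_win <- window_index_of(exon_mid, windows)
    exon_w_lin <- ifelse(is.na(exon_win), 0, win_weight[exon_win]) *
      (exons$end - exons$start)
    exon_w_unif <- as.numeric(exons$end - exons$start)

    chrom <- character(n)
    pos <- integer(n)

    if (any(assoc)) {
      na <- sum(assoc)
      g4_mid <- genomic_intervals(
        g4s$chrom, (g4s$start + g4s$end) %/% 2L,
        (g4s$start + g4s$end) %/% 2L + 1L
      )
      g4_win <- window_index_of(g4_mid, windows)
      g4_w <- if (kind == "cSNV") {
        ifelse(is.na(g4_win), 0, win_weight[g4_win])
      } else {
        rep(1, nrow(g4s))
      }
      gi <- sample.int(nrow(g4s), na, replace = TRUE, prob = g4_w)
      off <- round(rnorm(na, mu, sdev))
      p <- ifelse(off >= 0, g4s$end[gi] + off, g4s$start[gi] + off - 1L)
      chrom[assoc] <- g4s$chrom[gi]
      pos[assoc] <- as.integer(p)
    }
    if (any(!assoc)) {
      nb <- sum(!assoc)
      ew <- if (kind == "cSNV") exon_w_lin else exon_w_unif
      if (all(ew == 0)) ew <- exon_w_unif
      ei <- sample.int(nrow(exons), nb, replace = TRUE, prob = ew)
      chrom[!assoc] <- exons$chrom[ei]
      pos[!assoc] <- exons$start[ei] +
        as.integer(floor(runif(nb) * (exons$end[ei] - exons$start[ei])))
    }

    # clamp to chromosome bounds, then snap into exon space
    clen <- chrom_lengths(dataset$genome)
    pos <- pmin(pmax(pos, 0L), clen[chrom] - 1L)
    pos <- snap_to_exons(chrom, pos, exons)

    snvs <- tibble(
      chrom = chrom,
      pos = pos,
      patient_id = if (kind == "cSNV") {
        dataset$patients$patient_id[patient_idx]
      } else {
        NA_character_
      },
      cancer_type = if (kind == "cSNV") {
        dataset$patients$cancer_type[patient_idx]
      } else {
        NA_character_
      },
      tissue = if (kind == "cSNV") {
        dataset$patients$tissue[patient_idx]
      } else {
        NA_character_
      }
    )
    if (kind == "cSNV") dataset$csnvs <- snvs else dataset$dbsnvs <- snvs
    dataset
  })
}

chrom_lengths <- function(genome) {
  setNames(nchar(genome$sequence), genome$name)
}

# gene bodies +/- flank, clipped to chromosome bounds
flank_regions <- function(genes, flank, clen) {
  genomic_intervals(
    genes$chrom,
    pmax(genes$start - flank, 0L),
    pmin(genes$end + flank, as.integer(clen[genes$chrom])),
    name = genes$name
  )
}

# index of the window containing each (point) query, NA if none;
# assumes non-overlapping windows
window_index_of <- function(points, windows) {
  out <- rep(NA_integer_, nrow(points))
  wsplit <- split(seq_len(nrow(windows)), windows$chrom)
  psplit <- split(seq_len(nrow(points)), points$chrom)
  for (chr in names(psplit)) {
    wi <- wsplit[[chr]]
    if (is.null(wi)) next
    o <- order(windows$start[wi])
    wi <- wi[o]
    i <- findInterval(points$start[psplit[[chr]]], windows$start[wi])
    hit <- i >= 1L & points$start[psplit[[chr]]] < windows$end[wi][pmax(i, 1L)]
    out[psplit[[chr]]] <- ifelse(hit, wi[pmax(i, 1L)], NA_integer_)
  }
  out
}

#' Simulate a window table with a planted linear relation
#'
#' Direct substrate for validating the bootstrap-regression stage: for
#' each G4 category `c` in `0..max_g4`, `n_per_category` windows receive
#' cSNV counts from `Poisson(intercept + slope * c)` and dbSNV counts
#' from `Poisson(dbsnv_mean)` (no relation to `c`). GC base pairs are
#' binomial around `gc_fraction * window_size`.
#'
#' @param n_per_category Windows per G4 category.
#' @param max_g4 Largest G4 category (default 15).
#' @param intercept,slope Planted linear relation for cSNV counts.
#' @param dbsnv_mean Flat dbSNV mean per window.
#' @param window_size,gc_fraction Window geometry for the `gc_bp` column.
#' @param seed Integer seed.
#' @return A window tibble with `chrom`, `start`, `end`, `g4_count`,
#'   `csnv_count`, `dbsnv_count`, `gc_bp`.
#' @export
simulate_window_table <- function(n_per_category = 500L, max_g4 = 15L,
                                  intercept = 2, slope = 3, dbsnv_mean = 10,
                                  window_size = 5000L, gc_fraction = 0.5,
                                  seed = 1L) {
  withr::with_seed(seed, {
    g4 <- rep(0:max_g4, each = n_per_category)
    nw <- length(g4)
    tibble(
      chrom = "sim",
      start = (seq_len(nw) - 1L) * window_size,
      end = seq_len(nw) * window_size,
      g4_count = as.integer(g4),
      csnv_count = rpois(nw, intercept + slope * g4),
      dbsnv_count = rpois(nw, dbsnv_mean),
      gc_bp = rbinom(nw, window_size, gc_fraction)
    )
  })
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(cox_beta * g4_average)`; censoring times are
#' independent exponentials calibrated so that about `censor_rate` of
#' patients are censored.
#'
#' @param patients Tibble with a `g4_average` column (one row per patient).
#' @param cox_beta Planted log-hazard coefficient.
#' @param baseline_hazard Baseline hazard (> 0).
#' @param censor_rate Expected censored fraction in `[0, 1]`.
#' @param seed Integer seed, or `NULL`.
#' @return `patients` with `time` and `event` (1 = died of cancer,
#'   0 = censored) columns added.
#' @export
simulate_survival <- function(patients, cox_beta, baseline_hazard,
                              censor_rate = 0.3, seed = NULL) {
  if (baseline_hazard <= 0) abort("baseline_hazard must be positive")
  stopifnot("g4_average" %in% names(patients))
  draw <- function() {
    n <- nrow(patients)
    haz <- baseline_hazard * exp(cox_beta * patients$g4_average)
    t_event <- rexp(n, haz)
    if (censor_rate >= 1) {
      patients$time <- t_event
      patients$event <- 0L
    } else if (censor_rate <= 0) {
      patients$time <- t_event
      patients$event <- 1L
    } else {
      rate_c <- baseline_hazard *
        exp(cox_beta * mean(patients$g4_average)) *
        censor_rate / (1 - censor_rate)
      t_cens <- rexp(n, rate_c)
      patients$time <- pmin(t_event, t_cens)
      patients$event <- as.integer(t_event <= t_cens)
    }
    patients
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a stand-alone survival cohort
#'
#' Patient G4-averages are drawn from a gamma distribution (defaults:
#' mean 4, sd 2, matching the spread of patient-level G4-averages the
#' full generator produces under heterogeneous association propensities),
#' then survival is generated via [simulate_survival()]. Used for Cox
#' parameter-recovery experiments where the covariate distribution must
#' be controlled directly.
#'
#' @param n Number of patients.
#' @param cox_beta,baseline_hazard,censor_rate See [simulate_survival()].
#' @param covariate_shape,covariate_scale Gamma parameters of the
#'   G4-average distribution.
#' @param seed Integer seed.
#' @return Tibble with `patient_id`, `g4_average`, `time`, `event`.
#' @export
simulate_survival_cohort <- function(n = 3000L, cox_beta = 0.32,
                                     baseline_hazard = 0.01,
                                     censor_rate = 0.3,
                                     covariate_shape = 4,
                                     covariate_scale = 1,
                                     seed = 1L) {
  withr::with_seed(seed, {
    pts <- tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      g4_average = rgamma(n, shape = covariate_shape, scale = covariate_scale)
    )
    simulate_survival(pts, cox_beta, baseline_hazard, censor_rate,
                      seed = NULL)
  })
}

#' Generate a complete synthetic study
#'
#' Runs the full generative chain: genome scaffold, G4 map, cSNV and
#' dbSNV cohorts, patient metadata, the analysis window table (windows
#' over genes +/- flank, exonic feature counts, G4 cap) and survival
#' outcomes driven by each patient's realised G4-average. The returned
#' `truth` element records every planted parameter.
#'
#' @param config A [synthetic_config()].
#' @return A `g4_dataset` with `genome`, `genes`, `exons`, `cancer_genes`,
#'   `g4s`, `csnvs`, `dbsnvs`, `patients` (with `time`, `event`,
#'   `vital_status`, `death_cause`), `windows` (counted, capped) and
#'   `truth`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  ds <- simulate_genome(config)
  ds <- place_g4s(ds, config)
  ds <- place_snvs(ds, config, "cSNV")
  ds <- place_snvs(ds, config, "dbSNV")

  wins <- restrict_windows_to_genes(ds$genes, ds$exons, config$window_size,
                                    flank = config$flank,
                                    chrom_lengths = chrom_lengths(ds$genome))
  gene_class <- tibble(
    name = ds$genes$name,
    gene_class = ifelse(ds$genes$name %in% ds$cancer_genes,
                        "cancer", "non-cancer")
  )
  wt <- count_features(wins, ds$g4s, ds$csnvs, ds$dbsnvs, ds$exons,
                       genome = ds$genome, genes = ds$genes,
                       gene_class = gene_class)
  ds$windows <- cap_window_g4(wt)

  withr::with_seed(seq_seed(config$seed, 5L), {
    met <- suppressWarnings(patient_g4_metrics(ds$windows, ds$csnvs))
    pats <- dplyr::inner_join(ds$patients, met, by = "patient_id")
    pats <- simulate_survival(pats, config$cox_beta, config$baseline_hazard,
                              config$censor_rate, seed = NULL)
    # metadata imperfections for the cohort-selection filter
    pats$vital_status <- ifelse(pats$event == 1L, "dead", "alive")
    pats$death_cause <- ifelse(pats$event == 1L, "cancer", NA_character_)
    died <- which(pats$event == 1L)
    n_nc <- round(config$noncancer_death_rate * length(died))
    if (n_nc > 0) {
      nc <- sample(died, n_nc)
      pats$death_cause[nc] <- "other"
    }
    n_miss <- round(config$missing_rate * nrow(pats))
    if (n_miss > 0) {
      pats$time[sample.int(nrow(pats), n_miss)] <- NA_real_
    }
    ds$patients <- pats
  })

  ds$truth <- config[setdiff(names(config), "seed")]
  ds$truth$seed <- config$seed
  ds
}

#' @export
print.g4_dataset <- function(x, ...) {
  cat("<g4_dataset>\n")
  cat(sprintf("  genome:   %d chromosome(s), %s bp total\n",
              nrow(x$genome),
              format(sum(nchar(x$genome$sequence)), big.mark = ",")))
  cat(sprintf("  genes:    %d (%d cancer-class), exons: %d\n",
              nrow(x$genes), length(x$cancer_genes), nrow(x$exons)))
  if (!is.null(x$g4s)) cat(sprintf("  g4s:      %d\n", nrow(x$g4s)))
  if (!is.null(x$csnvs)) cat(sprintf("  csnvs:    %d\n", nrow(x$csnvs)))
  if (!is.null(x$dbsnvs)) cat(sprintf("  dbsnvs:   %d\n", nrow(x$dbsnvs)))
  if (!is.null(x$patients)) cat(sprintf("  patients: %d\n", nrow(x$patients)))
  if (!is.null(x$windows)) cat(sprintf("  windows:  %d\n", nrow(x$windows)))
  invisible(x)
}
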