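# Cohort-preprocessing rules: germline-coincidence filtering, exclusion of
# thinly sampled cancer types, the G4 cap on genomic windows, and the
# gene-restricted window set with the exon-gap exclusion.

new_filter_report <- function(n_input, n_germline_removed, n_type_excluded,
                              n_retained, excluded_types = character()) {
  stopifnot(n_input == n_germline_removed + n_type_excluded + n_retained)
  structure(
    list(n_input = n_input, n_germline_removed = n_germline_removed,
         n_type_excluded = n_type_excluded, n_retained = n_retained,
         excluded_types = excluded_types),
    class = "cohort_filter_report"
  )
}

#' @export
print.cohort_filter_report <- function(x, ...) {
  cat("<cohort filter report>\n")
  cat(sprintf("  input:            %d cSNVs\n", x$n_input))
  cat(sprintf("  germline removed: %d\n", x$n_germline_removed))
  cat(sprintf("  type excluded:    %d (%s)\n", x$n_type_excluded,
              if (length(x$excluded_types)) {
                paste(x$excluded_types, collapse = ", ")
              } else "none"))
  cat(sprintf("  retained:         %d\n", x$n_retained))
  invisible(x)
}

#' Remove cSNVs that coincide with known germline variants
#'
#' A cSNV is removed when its `(chrom, pos)` coincides with any dbSNV
#' position; allele identity is not considered (coordinate intersection).
#' Row order of the retained cSNVs is preserved and the operation is
#' idempotent.
#'
#' @param csnvs,dbsnvs SNV tibbles with `chrom` and `pos` columns.
#' @return List with `csnvs` (retained rows) and `report`
#'   (a `cohort_filter_report`).
#' @export
filter_germline <- function(csnvs, dbsnvs) {
  stopifnot(all(c("chrom", "pos") %in% names(csnvs)),
            all(c("chrom", "pos") %in% names(dbsnvs)))
  key <- function(x) paste(x$chrom, x$pos, sep = ":")
  hit <- key(csnvs) %in% key(dbsnvs)
  list(
    csnvs = csnvs[!hit, , drop = FALSE],
    report = new_filter_report(nrow(csnvs), sum(hit), 0L, sum(!hit))
  )
}

#' Drop cancer types with too few patients
#'
#' Cancer types represented by fewer than `min_samples` distinct patients
#' (strictly less than; exactly `min_samples` is retained) are excluded
#' together with their cSNVs.
#'
#' @param csnvs SNV tibble with `patient_id` and `cancer_type`.
#' @param patients Patient tibble with `patient_id` and `cancer_type`;
#'   every cSNV patient must appear here.
#' @param min_samples Minimum number of patients per retained type.
#' @return List with `csnvs`, `patients` (both filtered) and `report`.
#' @export
filter_cancer_types <- function(csnvs, patients, min_samples = 10L) {
  orphans <- setdiff(unique(csnvs$patient_id), patients$patient_id)
  if (length(orphans) > 0) {
    abort(paste0("cSNV patients missing from the patient table: ",
                 paste(head(orphans, 5), collapse = ", "),
                 if (length(orphans) > 5) ", ..." else ""))
  }
  by_type <- patients %>%
    distinct(.data$patient_id, .data$cancer_type) %>%
    count(.data$cancer_type)
  excluded <- by_type$cancer_type[by_type$n < min_samples]
  drop <- csnvs$cancer_type %in% excluded
  list(
    csnvs = csnvs[!drop, , drop = FALSE],
    patients = patients[!patients$cancer_type %in% excluded, , drop = FALSE],
    report = new_filter_report(nrow(csnvs), 0L, sum(drop), sum(!drop),
                               excluded_types = sort(excluded))
  )
}

#' Full cohort preprocessing
#'
#' Germline filtering followed by the cancer-type exclusion, with one
#' conserved accounting report (`n_input = n_germline_removed +
#' n_type_excluded + n_retained`).
#'
#' @inheritParams filter_germline
#' @inheritParams filter_cancer_types
#' @return List with `csnvs`, `patients`, `report`.
#' @export
preprocess_cohort <- function(csnvs, dbsnvs, patients, min_samples = 10L) {
  g <- filter_germline(csnvs, dbsnvs)
  t <- filter_cancer_types(g$csnvs, patients, min_samples)
  list(
    csnvs = t$csnvs,
    patients = t$patients,
    report = new_filter_report(
      nrow(csnvs), g$report$n_germline_removed, t$report$n_type_excluded,
      t$report$n_retained, excluded_types = t$report$excluded_types
    )
  )
}

#' Cap the G4 content of genomic windows
#'
#' Windows with more than `max_g4` G4s (strictly more; exactly `max_g4`
#' is retained) are removed from the window table.
#'
#' @param windows Window tibble with a `g4_count` column.
#' @param max_g4 Largest retained G4 count.
#' @return The filtered window tibble.
#' @export
cap_window_g4 <- function(windows, max_g4 = 15L) {
  stopifnot("g4_count" %in% names(windows))
  windows[windows$g4_count <= max_g4, , drop = FALSE]
}

#' Tile analysis windows over genes and apply the exon-gap exclusion
#'
#' Windows are tiled (via [make_windows()]) over each gene extended by
#' `flank` bp. A window is excluded when it overlaps no exon, or when the
#' gap between two consecutive exons overlapping it exceeds the window
#' size (such windows cannot carry a contiguous exonic signal).
#'
#' @param genes,exons Interval tibbles; exons must lie within genes and
#'   not overlap each other.
#' @param size Window size in bp.
#' @param step Step for sliding windows, or `NULL` for fixed-end tiling.
#' @param flank Flanking region in bp (2000 or 5000 in typical use).
#' @param chrom_lengths Optional named vector of chromosome lengths used
#'   to clip flanks at chromosome ends.
#' @return Interval tibble of retained windows.
#' @export
restrict_windows_to_genes <- function(genes, exons, size = 5000L,
                                      step = NULL, flank = 2000L,
                                      chrom_lengths = NULL) {
  validate_intervals(genes, "genes")
  validate_intervals(exons, "exons")
  regions <- genomic_intervals(
    genes$chrom,
    pmax(genes$start - flank, 0L),
    if (is.null(chrom_lengths)) {
      genes$end + flank
    } else {
      pmin(genes$end + flank, as.integer(chrom_lengths[genes$chrom]))
    },
    name = genes$name
  )
  windows <- make_windows(regions, size, step)
  exons <- sort_intervals(exons)

  keep <- logical(nrow(windows))
  esplit <- split(seq_len(nrow(exons)), exons$chrom)
  wsplit <- split(seq_len(nrow(windows)), windows$chrom)
  for (chr in names(wsplit)) {
    wi <- wsplit[[chr]]
    ei <- esplit[[chr]]
    if (is.null(ei)) next
    es <- exons$start[ei]
    ee <- exons$end[ei]
    ws <- windows$start[wi]
    we <- windows$end[wi]
    # exons overlapping a window form a contiguous run (exons disjoint,
    # sorted): lo = first exon ending after w.start, hi = last exon
    # starting before w.end
    lo <- findInterval(ws, ee) + 1L
    hi <- findInterval(we - 1L, es)
    ok <- hi >= lo
    gap_ok <- purrr::map2_lgl(lo, hi, function(l, h) {
      if (h <= l) return(TRUE)
      max(es[(l + 1):h] - ee[l:(h - 1)]) <= size
    })
    keep[wi] <- ok & gap_ok
  }
  windows[keep, , drop = FALSE]
}
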