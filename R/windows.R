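# Per-window feature counting and the window-level statistics: stratified
# enrichment, GC normalisation, partial correlation controlling for GC,
# gene-level exon analysis, and the cancer/non-cancer gene comparison.

#' Count exonic features per genomic window
#'
#' For every window, counts G4s, cSNVs and dbSNVs that fall inside exonic
#' sequence within the window (a feature outside exons is never counted,
#' even when it lies in the window), plus the window's G+C base pairs.
#' Windows are annotated with a gene class when a gene-class map is given.
#'
#' @param windows Interval tibble of windows.
#' @param g4s Interval tibble of G4s (or `NULL`).
#' @param csnvs,dbsnvs SNV tibbles with `chrom`/`pos` (or `NULL`).
#' @param exons Interval tibble of exons defining countable space.
#' @param genome Optional sequence tibble (`name`, `sequence`) for
#'   `gc_bp`; windows outside the genome raise an error.
#' @param genes Optional gene interval tibble used with `gene_class`.
#' @param gene_class Optional tibble (`name`, `gene_class`) mapping gene
#'   names to `"cancer"`/`"non-cancer"`.
#' @return Window tibble with `g4_count`, `csnv_count`, `dbsnv_count`,
#'   `gc_bp` (NA when no genome is given) and `gene_class` (`"none"` for
#'   intergenic windows).
#' @export
count_features <- function(windows, g4s = NULL, csnvs = NULL, dbsnvs = NULL,
                           exons, genome = NULL, genes = NULL,
                           gene_class = NULL) {
  validate_intervals(windows, "windows")
  validate_intervals(exons, "exons")
  out <- as_tibble(windows)

  exonic <- function(x) {
    if (is.null(x) || nrow(x) == 0) return(NULL)
    iv <- snvs_as_intervals(x)
    iv[intersect_count(iv, exons) > 0, , drop = FALSE]
  }
  count_in_windows <- function(feat) {
    if (is.null(feat) || nrow(feat) == 0) return(integer(nrow(out)))
    intersect_count(windows, feat)
  }
  out$g4_count <- count_in_windows(exonic(g4s))
  out$csnv_count <- count_in_windows(exonic(csnvs))
  out$dbsnv_count <- count_in_windows(exonic(dbsnvs))

  if (!is.null(genome)) {
    cums <- lapply(setNames(genome$sequence, genome$name), gc_cumsum)
    lens <- chrom_lengths(genome)
    if (any(!windows$chrom %in% genome$name) ||
        any(windows$end > lens[windows$chrom])) {
      abort("window outside the supplied genome")
    }
    out$gc_bp <- as.integer(purrr::pmap_dbl(
      list(windows$chrom, windows$start, windows$end),
      function(chr, s, e) cums[[chr]][e + 1L] - cums[[chr]][s + 1L]
    ))
  } else {
    out$gc_bp <- NA_integer_
  }

  if (!is.null(genes) && !is.null(gene_class)) {
    hits <- closest_distance(windows, genes)
    cls <- gene_class$gene_class[match(hits$ref_name, gene_class$name)]
    out$gene_class <- ifelse(!is.na(hits$distance) & hits$distance == 0,
                             cls, "none")
    out$gene_class[is.na(out$gene_class)] <- "none"
    # a window overlapping any cancer gene counts as cancer-class
    if (any(gene_class$gene_class == "cancer")) {
      cg <- genes[genes$name %in%
                    gene_class$name[gene_class$gene_class == "cancer"], ]
      if (nrow(cg) > 0) {
        out$gene_class[intersect_count(windows, cg) > 0] <- "cancer"
      }
    }
  } else {
    out$gene_class <- "none"
  }
  out
}

#' G4-stratified SNV enrichment across genomic windows
#'
#' Windows are grouped by G4 content -- either the three classical strata
#' (`0`, `1+`, `10+` G4s; `1+` contains `10+`) or per exact G4 count --
#' and per-group mean/median SNV counts are reported. For the three-group
#' mode, the zero-G4 group is compared against `1+` and against `10+`
#' with Welch's two-sample t-test (Student's by flag) and with a
#' chi-squared test on the SNV presence/absence contingency.
#'
#' @param windows Counted window tibble (see [count_features()]).
#' @param snv_kind `"cSNV"` or `"dbSNV"`.
#' @param grouping `"three_group"` or `"per_count"`.
#' @param var_equal Use Student's pooled-variance t-test instead of
#'   Welch's.
#' @return A tibble with one row per group: `group`, `n_windows`,
#'   `mean_snv`, `median_snv`, and for compared groups `t_statistic`,
#'   `t_p_value`, `chisq_statistic`, `chisq_p_value` (tests are versus
#'   the zero-G4 group; `NA` for the reference row and in per-count
#'   mode).
#' @export
stratify_enrichment <- function(windows, snv_kind = c("cSNV", "dbSNV"),
                                grouping = c("three_group", "per_count"),
                                var_equal = FALSE) {
  snv_kind <- match.arg(snv_kind)
  grouping <- match.arg(grouping)
  if (nrow(windows) == 0) abort("window table is empty")
  v <- if (snv_kind == "cSNV") windows$csnv_count else windows$dbsnv_count

  if (grouping == "per_count") {
    return(
      tibble(g4 = windows$g4_count, snv = v) %>%
        group_by(group = as.character(.data$g4)) %>%
        summarise(n_windows = n(), mean_snv = mean(.data$snv),
                  median_snv = median(.data$snv), .groups = "drop") %>%
        arrange(as.integer(.data$group)) %>%
        mutate(t_statistic = NA_real_, t_p_value = NA_real_,
               chisq_statistic = NA_real_, chisq_p_value = NA_real_)
    )
  }

  groups <- list(
    `0` = v[windows$g4_count == 0],
    `1+` = v[windows$g4_count >= 1],
    `10+` = v[windows$g4_count >= 10]
  )
  ref <- groups[["0"]]
  rows <- purrr::imap(groups, function(g, label) {
    if (length(g) == 0) {
      warn(sprintf("stratum '%s' is empty; comparison skipped", label))
      return(tibble(group = label, n_windows = 0L, mean_snv = NA_real_,
                    median_snv = NA_real_, t_statistic = NA_real_,
                    t_p_value = NA_real_, chisq_statistic = NA_real_,
                    chisq_p_value = NA_real_))
    }
    row <- tibble(group = label, n_windows = length(g), mean_snv = mean(g),
                  median_snv = median(g), t_statistic = NA_real_,
                  t_p_value = NA_real_, chisq_statistic = NA_real_,
                  chisq_p_value = NA_real_)
    if (label != "0" && length(ref) > 1 && length(g) > 1 &&
        (sd(ref) > 0 || sd(g) > 0)) {
      tt <- t.test(ref, g, var.equal = var_equal)
      row$t_statistic <- unname(tt$statistic)
      row$t_p_value <- tt$p.value
      tab <- rbind(c(sum(ref == 0), sum(ref > 0)),
                   c(sum(g == 0), sum(g > 0)))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        ct <- suppressWarnings(chisq.test(tab))
        row$chisq_statistic <- unname(ct$statistic)
        row$chisq_p_value <- ct$p.value
      }
    }
    row
  })
  out <- bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$t_p_value, method = "BH")
  out
}

#' GC-normalised G4 rates per window
#'
#' Adds `g4_per_gc = g4_count / gc_bp`; windows with `gc_bp == 0` are
#' flagged (`gc_zero`) and their rate is `NA`, to be excluded from
#' GC-normalised analyses.
#'
#' @param windows Window tibble with `g4_count` and `gc_bp`.
#' @return The window tibble with `g4_per_gc` and `gc_zero` columns.
#' @export
gc_normalized_counts <- function(windows) {
  stopifnot(all(c("g4_count", "gc_bp") %in% names(windows)))
  windows %>%
    mutate(
      gc_zero = !is.na(.data$gc_bp) & .data$gc_bp == 0,
      g4_per_gc = ifelse(is.na(.data$gc_bp) | .data$gc_bp == 0,
                         NA_real_, .data$g4_count / .data$gc_bp)
    )
}

#' Partial correlation controlling for a confounder
#'
#' First-order partial Pearson correlation
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with a
#' two-sided p-value from the t transform on `n - 3` degrees of freedom.
#' In this pipeline `x` is the per-window G4 count, `y` the cSNV count
#' and `z` the GC fraction of the window.
#'
#' @param x,y,z Numeric vectors of equal length (>= 4), non-zero variance.
#' @return Tibble with `r_xy`, `r_xz`, `r_yz`, `r_xy_given_z`, `p_value`,
#'   `n`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) abort("x, y, z must have equal length")
  if (n < 4) abort("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) abort("zero variance input")
  r_xy <- cor(x, y)
  r_xz <- cor(x, z)
  r_yz <- cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    abort("z is collinear with x or y; partial correlation undefined")
  }
  pr <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  p <- if (abs(pr) >= 1) {
    0
  } else {
    2 * pt(abs(pr) * sqrt((n - 3) / (1 - pr^2)), df = n - 3,
           lower.tail = FALSE)
  }
  tibble(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz, r_xy_given_z = pr,
         p_value = p, n = n)
}

#' Per-exon cSNV density versus G4 content within a gene
#'
#' Counts cSNVs and G4s per exon, normalises the cSNV count to the exon
#' length (cSNVs / bp) and correlates the density with the exon G4 count
#' across exons.
#'
#' @param exons Interval tibble of a gene's (non-overlapping) exons.
#' @param g4s Interval tibble of G4s.
#' @param csnvs SNV tibble.
#' @return List with `exon_table` (per-exon `csnv_count`, `csnv_per_bp`,
#'   `g4_count`) and `correlation` (a [window_pearson()] row, or `NULL`
#'   with fewer than 3 exons).
#' @export
gene_exon_analysis <- function(exons, g4s, csnvs) {
  validate_intervals(exons, "exons")
  tab <- as_tibble(exons) %>%
    mutate(
      csnv_count = intersect_count(exons, snvs_as_intervals(csnvs)),
      g4_count = intersect_count(exons, g4s),
      csnv_per_bp = .data$csnv_count / (.data$end - .data$start)
    )
  corr <- NULL
  if (nrow(tab) >= 3 && sd(tab$csnv_per_bp) > 0 && sd(tab$g4_count) > 0) {
    corr <- window_pearson(tab$csnv_per_bp, tab$g4_count)
  }
  list(exon_table = tab, correlation = corr)
}

#' Compare SNV load across G4 strata in cancer versus non-cancer genes
#'
#' For each gene class and each of the `0` and `10+` G4 strata, reports
#' per-window SNV summaries with a Welch t and a chi-squared
#' presence/absence test between the strata, plus per-gene G4-content
#' summaries for each class (raw counts and per-kbp rates).
#'
#' @param windows Counted window tibble with a `gene_class` column.
#' @param genes Gene interval tibble.
#' @param gene_class Tibble (`name`, `gene_class`) as in
#'   [count_features()].
#' @param g4s Interval tibble of G4s (for per-gene content).
#' @param snv_kind `"cSNV"` or `"dbSNV"`.
#' @return List with `strata` (per class x stratum summaries and tests)
#'   and `gene_g4` (per-class per-gene G4 content: median/mean raw and
#'   per kbp).
#' @export
gene_class_comparison <- function(windows, genes, gene_class, g4s,
                                  snv_kind = c("cSNV", "dbSNV")) {
  snv_kind <- match.arg(snv_kind)
  stopifnot("gene_class" %in% names(windows))
  v <- if (snv_kind == "cSNV") windows$csnv_count else windows$dbsnv_count

  strata <- purrr::map(c("cancer", "non-cancer"), function(cls) {
    wi <- windows$gene_class == cls
    if (!any(wi)) {
      warn(sprintf("gene class '%s' absent from window table", cls))
      return(NULL)
    }
    g0 <- v[wi & windows$g4_count == 0]
    g10 <- v[wi & windows$g4_count >= 10]
    row <- tibble(
      gene_class = cls,
      n_windows_0 = length(g0), n_windows_10plus = length(g10),
      mean_snv_0 = mean(g0), median_snv_0 = median(g0),
      mean_snv_10plus = if (length(g10)) mean(g10) else NA_real_,
      median_snv_10plus = if (length(g10)) median(g10) else NA_real_,
      t_statistic = NA_real_, t_p_value = NA_real_,
      chisq_statistic = NA_real_, chisq_p_value = NA_real_
    )
    if (length(g0) > 1 && length(g10) > 1 && (sd(g0) > 0 || sd(g10) > 0)) {
      tt <- t.test(g0, g10)
      row$t_statistic <- unname(tt$statistic)
      row$t_p_value <- tt$p.value
      tab <- rbind(c(sum(g0 == 0), sum(g0 > 0)),
                   c(sum(g10 == 0), sum(g10 > 0)))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        ct <- suppressWarnings(chisq.test(tab))
        row$chisq_statistic <- unname(ct$statistic)
        row$chisq_p_value <- ct$p.value
      }
    }
    row
  }) %>% bind_rows()

  per_gene <- as_tibble(genes) %>%
    mutate(
      g4_count = intersect_count(genes, g4s),
      g4_per_kbp = .data$g4_count / ((.data$end - .data$start) / 1000)
    ) %>%
    left_join(gene_class, by = "name")
  gene_g4 <- per_gene %>%
    filter(!is.na(.data$gene_class)) %>%
    group_by(.data$gene_class) %>%
    summarise(
      n_genes = n(),
      median_g4 = median(.data$g4_count),
      mean_g4 = mean(.data$g4_count),
      median_g4_per_kbp = median(.data$g4_per_kbp),
      mean_g4_per_kbp = mean(.data$g4_per_kbp),
      .groups = "drop"
    )
  list(strata = strata, gene_g4 = gene_g4)
}
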