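# ggplot2 views of the main result types.

#' Plot a distance-density profile
#'
#' Bar profile of the binned SNV density around G4s, optionally overlaid
#' with a fitted Gaussian and its 95% positional interval.
#'
#' @param object A [distance_profile()] result.
#' @param fit Optional [fit_gaussian()] result to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.g4_distance_profile <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
    ggplot2::geom_col(width = attr(object, "binwidth"), fill = "grey65") +
    ggplot2::labs(x = "signed distance to closest G4 (bp)",
                  y = paste0("density (", attr(object, "normalization"), ")")) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(object$bin_mid), max(object$bin_mid), length.out = 400)
    curve <- tibble(
      x = xs,
      y = fit$amplitude * exp(-(xs - fit$mu)^2 / (2 * fit$sigma^2))
    )
    p <- p +
      ggplot2::geom_line(data = curve, ggplot2::aes(.data$x, .data$y),
                         colour = "firebrick", linewidth = 0.8) +
      ggplot2::geom_vline(xintercept = c(fit$ci95_low, fit$ci95_high),
                          linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot a bootstrap sweep
#'
#' Median r-squared (band: 10-90% quantiles over cycles) of the linear
#' fit as the subsample size I grows.
#'
#' @param object A [bootstrap_sweep()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.g4_bootstrap_sweep <- function(object, ...) {
  s <- summarise_sweep(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$I, y = .data$median_r_squared)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$r2_q10,
                                      ymax = .data$r2_q90),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "subsample size I",
                  y = expression(median ~ r^2),
                  title = paste0("incomplete categorical bootstrap (",
                                 attr(object, "snv_kind"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot window-level SNV counts by G4 stratum
#'
#' Per-category mean SNV count with the whole-table linear fit, the
#' tabular twin of a stratified enrichment figure.
#'
#' @param windows Counted window tibble.
#' @param snv_kind `"cSNV"` or `"dbSNV"`.
#' @return A ggplot.
#' @export
plot_window_enrichment <- function(windows, snv_kind = c("cSNV", "dbSNV")) {
  snv_kind <- match.arg(snv_kind)
  v <- if (snv_kind == "cSNV") windows$csnv_count else windows$dbsnv_count
  d <- tibble(g4 = windows$g4_count, snv = v)
  means <- d %>%
    group_by(.data$g4) %>%
    summarise(mean_snv = mean(.data$snv), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$g4, y = .data$snv)) +
    ggplot2::geom_jitter(width = 0.25, height = 0, alpha = 0.15, size = 0.5) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(y = .data$mean_snv),
                        colour = "black", shape = 3, size = 2.5) +
    ggplot2::geom_smooth(data = means,
                         ggplot2::aes(y = .data$mean_snv),
                         method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = "G4s per window", y = paste0(snv_kind, "s per window")) +
    ggplot2::theme_minimal()
}
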