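# Independent brute-force oracles. These deliberately share no code with
# the implementation: exhaustive all-pairs scans, a hand-rolled partial
# likelihood, a different regex engine.

# Signed distance of one query to every reference, exhaustive minimum.
oracle_closest <- function(queries, references) {
  vapply(seq_len(nrow(queries)), function(i) {
    qs <- queries$start[i]
    qe <- queries$end[i]
    same <- references[references$chrom == queries$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) return(NA_real_)
    d <- numeric(nrow(same))
    for (j in seq_len(nrow(same))) {
      rs <- same$start[j]
      re <- same$end[j]
      d[j] <- if (rs < qe && re > qs) {
        0
      } else if (qs >= re) {
        qs - re          # query downstream of the reference
      } else {
        -(rs - qe)       # query upstream
      }
    }
    best <- which(abs(d) == min(abs(d)))
    # tie toward the leftmost reference: positive (left neighbour) wins
    if (length(best) > 1) d[best[which.max(d[best])]] else d[best]
  }, numeric(1))
}

# Overlap counts by exhaustive nested comparison.
oracle_intersect <- function(queries, references) {
  vapply(seq_len(nrow(queries)), function(i) {
    same <- references[references$chrom == queries$chrom[i], , drop = FALSE]
    sum(same$start < queries$end[i] & same$end > queries$start[i])
  }, numeric(1))
}

random_interval_set <- function(n, chroms = c("chrA", "chrB"),
                                max_pos = 10000L, max_len = 60L) {
  s <- sample.int(max_pos, n, replace = TRUE)
  genomic_intervals(
    chrom = sample(chroms, n, replace = TRUE),
    start = s,
    end = s + sample.int(max_len, n, replace = TRUE)
  )
}

# PQS matches through a different regex engine (ICU via stringi).
oracle_pqs <- function(sequence, min_g_run = 3, min_loop = 1, max_loop = 7) {
  pat <- sprintf("G{%d,}(?:[ACGT]{%d,%d}?G{%d,}){3}",
                 min_g_run, min_loop, max_loop, min_g_run)
  m <- stringi::stri_locate_all_regex(sequence, pat)[[1]]
  if (all(is.na(m))) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  tibble::tibble(start = m[, 1] - 1L, end = m[, 2])
}

# Breslow partial log-likelihood, direct sum over events.
oracle_cox_loglik <- function(beta, time, event, x) {
  sum(vapply(which(event == 1), function(i) {
    at_risk <- time >= time[i]
    x[i] * beta - log(sum(exp(x[at_risk] * beta)))
  }, numeric(1)))
}

# Two-stage grid maximisation of the partial likelihood.
oracle_cox_grid <- function(time, event, x, lo = -5, hi = 5) {
  coarse <- seq(lo, hi, by = 0.01)
  ll <- vapply(coarse, oracle_cox_loglik, numeric(1),
               time = time, event = event, x = x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, oracle_cox_loglik, numeric(1),
                time = time, event = event, x = x)
  fine[which.max(llf)]
}

# Exhaustive exonic-feature counter for windows (nested loops).
oracle_count_window <- function(windows, features, exons) {
  vapply(seq_len(nrow(windows)), function(i) {
    n <- 0L
    for (j in seq_len(nrow(features))) {
      if (features$chrom[j] != windows$chrom[i]) next
      in_window <- features$start[j] < windows$end[i] &&
        features$end[j] > windows$start[i]
      if (!in_window) next
      in_exon <- any(exons$chrom == features$chrom[j] &
                       exons$start < features$end[j] &
                       exons$end > features$start[j])
      if (in_exon) n <- n + 1L
    }
    n
  }, integer(1))
}
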