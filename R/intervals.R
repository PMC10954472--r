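# Genomic-interval arithmetic on plain tibbles.
#
# Conventions used throughout the package:
#  * coordinates are 0-based, half-open ([start, end)), BED dialect;
#  * SNVs are length-1 intervals [pos, pos + 1);
#  * chromosome names compare as exact strings (no "chr" harmonisation).

#' Construct a genomic-interval tibble
#'
#' The universal coordinate container of the package: one row per interval
#' with 0-based half-open coordinates. All interval operations accept and
#' return this layout, so results chain with the pipe.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `0 <= start < end`, half-open.
#' @param name Optional identifier per interval.
#' @param score Optional numeric score (BED column 5).
#' @param strand One of `"+"`, `"-"` or `"."` (unspecified).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @examples
#' genomic_intervals("chr1", c(100L, 500L), c(200L, 650L))
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = 0, strand = ".") {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand)
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval set") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0(what, " lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) {
    abort(paste0(what, ": chromosome names must be non-empty"))
  }
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid coordinates (need 0 <= start < end) at row %d",
                  what, bad[1]))
  }
  invisible(x)
}

# Ensure the optional BED columns exist so binds and writes are uniform.
complete_interval_cols <- function(x) {
  if (!"name" %in% names(x)) x$name <- NA_character_
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  as_tibble(x)
}

#' Read a BED file into an interval tibble
#'
#' Parses BED3/BED6 (and wider; extra columns are dropped). `track` and
#' `browser` lines and `#` comments are skipped. Malformed coordinates
#' raise an error naming the offending line.
#'
#' @param path Path to a tab-separated BED file.
#' @return Interval tibble (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED parse error at line %d: fewer than 3 columns",
                  idx[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("BED parse error at line %d: invalid coordinates", idx[bad[1]]))
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  score <- ifelse(nf >= 5,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) f[min(5L, length(f))], ""))),
                  0)
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6L, length(f))], ""),
                   ".")
  strand[!strand %in% c("+", "-")] <- "."
  genomic_intervals(chrom, start, end, name = name, score = score,
                    strand = strand)
}

#' Write an interval tibble as BED
#'
#' Emits BED6 when any `name`/`score`/`strand` is informative, BED3
#' otherwise. Round-trips through [read_bed()].
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x <- complete_interval_cols(x)
  bed6 <- nrow(x) > 0 &&
    (any(!is.na(x$name)) || any(x$score != 0) || any(x$strand != "."))
  if (bed6) {
    out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end,
                   ifelse(is.na(x$name), ".", x$name),
                   format(x$score, trim = TRUE, scientific = FALSE),
                   x$strand)
  } else {
    out <- sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
  }
  writeLines(out, path)
  invisible(path)
}

#' Sort intervals by (chrom, start, end)
#'
#' Stable for ties; chromosomes ordered lexicographically (C locale).
#'
#' @param x Interval tibble.
#' @return Sorted interval tibble.
#' @export
sort_intervals <- function(x) {
  validate_intervals(x)
  x[order(x$chrom, x$start, x$end, method = "radix"), , drop = FALSE]
}

is_sorted_intervals <- function(x) {
  if (nrow(x) < 2) return(TRUE)
  o <- order(x$chrom, x$start, x$end, method = "radix")
  all(o == seq_along(o))
}

#' Signed distance to the closest reference interval
#'
#' For every query interval, finds the reference interval on the same
#' chromosome minimising the edge-to-edge gap (bedtools `closest -d`
#' semantics: 0 on overlap or book-ended contact, otherwise the number of
#' base pairs strictly between the closest edges). The distance is signed
#' in reference-genome orientation: negative when the query lies 5' of the
#' reference (upstream), positive when 3' (downstream). Ties are broken
#' toward the genomically leftmost reference, so results are deterministic.
#'
#' @param queries,references Interval tibbles; sorted internally.
#' @param sign_by_strand If `TRUE`, distances of queries whose closest
#'   reference is on the `-` strand have their sign flipped, expressing
#'   up/downstream relative to the reference's own orientation.
#' @return A tibble with one row per query row (original order): the query
#'   coordinates plus `distance` (signed bp, `NA` when no reference shares
#'   the chromosome) and `ref_name`/`ref_start`/`ref_end`.
#' @export
closest_distance <- function(queries, references, sign_by_strand = FALSE) {
  validate_intervals(queries, "queries")
  validate_intervals(references, "references")
  if (nrow(references) == 0) abort("reference set is empty")
  queries <- complete_interval_cols(queries)
  references <- complete_interval_cols(references)

  out_dist <- rep(NA_real_, nrow(queries))
  out_ref <- rep(NA_integer_, nrow(queries))

  ref_split <- split(seq_len(nrow(references)), references$chrom)
  qry_split <- split(seq_len(nrow(queries)), queries$chrom)

  for (chr in names(qry_split)) {
    qi <- qry_split[[chr]]
    ri <- ref_split[[chr]]
    if (is.null(ri)) next
    rs <- references$start[ri]
    re <- references$end[ri]

    # order by (start, end): for equal starts the shorter (leftmost-ending)
    # interval wins right-neighbour ties
    o_start <- order(rs, re, method = "radix")
    starts_sorted <- rs[o_start]
    ends_by_start <- re[o_start]
    cummax_end <- cummax(ends_by_start)

    # order by (end, start): for equal ends the smaller start wins
    # left-neighbour ties
    o_end <- order(re, rs, method = "radix")
    ends_sorted <- re[o_end]

    qs <- queries$start[qi]
    qe <- queries$end[qi]

    # overlap: any reference with start < q.end and end > q.start.
    k <- findInterval(qe - 1L, starts_sorted)        # refs with start < q.end
    has_left_start <- k >= 1L
    ovl <- has_left_start & cummax_end[pmax(k, 1L)] > qs
    # leftmost overlapping reference: first index with cummax_end > q.start
    j <- findInterval(qs, cummax_end) + 1L
    ref_ovl <- ifelse(ovl, ri[o_start][pmin(j, length(o_start))], NA_integer_)

    # nearest fully-left reference: largest end <= q.start
    kl <- findInterval(qs, ends_sorted)
    dist_left <- ifelse(kl >= 1L, qs - ends_sorted[pmax(kl, 1L)], Inf)
    # among ties on end, the (end, start) order puts the leftmost start
    # first; walk back to the first element of the tie group
    ref_left <- rep(NA_integer_, length(qi))
    sel <- which(kl >= 1L)
    if (length(sel) > 0) {
      tie_first <- findInterval(ends_sorted[kl[sel]] - 1L, ends_sorted) + 1L
      ref_left[sel] <- ri[o_end][tie_first]
    }

    # nearest fully-right reference: smallest start >= q.end
    kr <- findInterval(qe - 1L, starts_sorted) + 1L
    in_range <- kr <= length(starts_sorted)
    dist_right <- ifelse(in_range, starts_sorted[pmin(kr, length(starts_sorted))] - qe,
                         Inf)
    ref_right <- ifelse(in_range, ri[o_start][pmin(kr, length(o_start))],
                        NA_integer_)

    d <- ifelse(ovl, 0,
                ifelse(dist_left <= dist_right, dist_left, -dist_right))
    ref <- ifelse(ovl, ref_ovl,
                  ifelse(dist_left <= dist_right, ref_left, ref_right))
    out_dist[qi] <- d
    out_ref[qi] <- ref
  }

  res <- tibble(
    chrom = queries$chrom,
    start = queries$start,
    end = queries$end,
    distance = out_dist,
    ref_name = references$name[out_ref],
    ref_start = references$start[out_ref],
    ref_end = references$end[out_ref]
  )
  if (sign_by_strand) {
    flip <- !is.na(out_ref) & references$strand[out_ref] == "-"
    res$distance[flip] <- -res$distance[flip]
  }
  res
}

#' Count overlapping references per query
#'
#' Half-open overlap semantics: reference overlaps query iff
#' `ref$start < q$end && ref$end > q$start`.
#'
#' @param queries,references Interval tibbles.
#' @return Integer vector, one count per query row.
#' @export
intersect_count <- function(queries, references) {
  validate_intervals(queries, "queries")
  validate_intervals(references, "references")
  out <- integer(nrow(queries))
  if (nrow(references) == 0) return(out)
  ref_split <- split(seq_len(nrow(references)), references$chrom)
  qry_split <- split(seq_len(nrow(queries)), queries$chrom)
  for (chr in names(qry_split)) {
    qi <- qry_split[[chr]]
    ri <- ref_split[[chr]]
    if (is.null(ri)) next
    starts <- sort(references$start[ri])
    ends <- sort(references$end[ri])
    # overlapping = (#starts < q.end) - (#ends <= q.start)
    out[qi] <- findInterval(queries$end[qi] - 1L, starts) -
      findInterval(queries$start[qi], ends)
  }
  out
}

#' Tile regions into fixed-end or sliding windows
#'
#' Follows the bedtools `makewindows` dialect: fixed-end tiling emits
#' consecutive non-overlapping windows of `size` bp with a truncated final
#' window; sliding tiling (when `step` is given) emits a window every
#' `step` bp, truncated at the region end.
#'
#' @param regions Interval tibble of regions to tile.
#' @param size Window size in bp (> 0).
#' @param step Step size in bp for sliding windows, or `NULL` for
#'   fixed-end tiling.
#' @return Interval tibble of windows; `name` records the source region
#'   row and window rank.
#' @export
make_windows <- function(regions, size, step = NULL) {
  validate_intervals(regions, "regions")
  if (size <= 0) abort("window size must be > 0")
  if (!is.null(step) && step <= 0) abort("step must be > 0")
  by <- if (is.null(step)) size else step
  pieces <- purrr::pmap(
    list(regions$chrom, regions$start, regions$end, seq_len(nrow(regions))),
    function(chrom, start, end, i) {
      ws <- seq.int(start, end - 1L, by = by)
      tibble(
        chrom = chrom,
        start = as.integer(ws),
        end = as.integer(pmin(ws + size, end)),
        name = sprintf("region%d_w%d", i, seq_along(ws)),
        score = 0,
        strand = "."
      )
    }
  )
  bind_rows(pieces)
}

#' Draw random fixed-length intervals inside a mask
#'
#' Start positions are uniform over all valid starts of the mask (mask
#' intervals are weighted by their number of valid starts), emulating
#' `bedtools random` restricted to a mask. Reproducible under `seed`.
#'
#' @param mask Interval tibble of allowed regions.
#' @param length Interval length in bp.
#' @param n Number of intervals to draw.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Interval tibble of `n` intervals, each fully inside the mask.
#' @export
random_intervals <- function(mask, length, n, seed = NULL) {
  validate_intervals(mask, "mask")
  if (n <= 0) abort("n must be > 0")
  widths <- mask$end - mask$start
  ok <- widths >= length
  if (!any(ok)) abort("mask has no interval of at least `length` bp")
  if (!all(ok)) {
    warn(sprintf("dropping %d mask interval(s) shorter than %d bp",
                 sum(!ok), as.integer(length)))
    mask <- mask[ok, , drop = FALSE]
  }
  n_starts <- mask$end - mask$start - length + 1L
  draw <- function() {
    idx <- sample.int(nrow(mask), n, replace = TRUE, prob = n_starts)
    off <- floor(runif(n) * n_starts[idx])
    genomic_intervals(
      chrom = mask$chrom[idx],
      start = mask$start[idx] + as.integer(off),
      end = mask$start[idx] + as.integer(off) + as.integer(length),
      name = sprintf("rand%d", seq_len(n))
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
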