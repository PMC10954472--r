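# FASTA access, GC counting and consensus PQS motif scanning.
#
# Sequences travel as a tibble with columns `name` and `sequence`
# (uppercase DNA over A/C/G/T/N), one row per record.

#' Read a FASTA file into a sequence tibble
#'
#' Backed by [Biostrings::readDNAStringSet()]. Multi-line records are
#' concatenated and case is normalised to uppercase.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `name` (first word of the header) and
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readDNAStringSet(path)
  tibble(
    name = vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L),
    sequence = unname(toupper(as.character(set)))
  )
}

#' Write a sequence tibble as FASTA
#'
#' @param seqs Tibble with `name` and `sequence` columns.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("name", "sequence") %in% names(seqs)))
  set <- Biostrings::DNAStringSet(seqs$sequence)
  names(set) <- seqs$name
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement a DNA string
#' @param sequence DNA string over A/C/G/T/N.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Count G+C bases within an interval of a sequence
#'
#' `N` (and any non-G/C character) contributes zero. Coordinates are
#' 0-based half-open, consistent with the interval tibbles.
#'
#' @param sequence DNA string.
#' @param start,end 0-based half-open span; must lie within the sequence.
#' @return Integer count of G and C characters in `[start, end)`.
#' @export
gc_count <- function(sequence, start, end) {
  n <- nchar(sequence)
  if (start < 0 || end > n || start >= end) {
    abort(sprintf("interval [%d,%d) out of bounds for sequence of length %d",
                  start, end, n))
  }
  piece <- substr(sequence, start + 1L, end)
  sum(charToRaw(piece) %in% charToRaw("GCgc"))
}

# Cumulative GC profile: gc_cum(seq)[end + 1] - gc_cum(seq)[start + 1]
# gives gc_count(seq, start, end). Used for bulk per-window counting.
gc_cumsum <- function(sequence) {
  c(0L, cumsum(charToRaw(sequence) %in% charToRaw("GCgc")))
}

#' Consensus PQS motif parameters
#'
#' The canonical intramolecular G4 consensus: four runs of at least
#' `min_g_run` guanines separated by three loops of `min_loop` to
#' `max_loop` nucleotides.
#'
#' @param min_g_run Minimum G-run length (>= 2; canonical 3).
#' @param min_loop,max_loop Loop length bounds (canonical 1 and 7).
#' @return A `pqs_params` list.
#' @export
pqs_params <- function(min_g_run = 3L, min_loop = 1L, max_loop = 7L) {
  if (min_g_run < 2) abort("min_g_run must be >= 2")
  if (min_loop < 1 || min_loop > max_loop) {
    abort("need 1 <= min_loop <= max_loop")
  }
  structure(list(min_g_run = as.integer(min_g_run),
                 min_loop = as.integer(min_loop),
                 max_loop = as.integer(max_loop)),
            class = "pqs_params")
}

pqs_regex <- function(params, base = "G", allow_n = FALSE) {
  loop_class <- if (allow_n) "[ACGTN]" else "[ACGT]"
  sprintf("%s{%d,}(?:%s{%d,%d}?%s{%d,}){3}",
          base, params$min_g_run, loop_class, params$min_loop,
          params$max_loop, base, params$min_g_run)
}

scan_pqs_one_strand <- function(sequence, params, base, allow_n) {
  pat <- pqs_regex(params, base = base, allow_n = allow_n)
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(start = integer(), end = integer()))
  }
  tibble(start = as.integer(m) - 1L,
         end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Scan a sequence for consensus PQS motifs
#'
#' Matches the G4 consensus GxNyGxNyGxNyGx (four G-runs of at least
#' `min_g_run`, loops of `min_loop..max_loop` nt). Scanning is greedy
#' left-to-right: G-runs are extended maximally, loops kept minimal, and
#' scanning resumes after each match so reported hits never overlap.
#' With `both_strands`, the complementary C-run motif is scanned as well
#' and reported with strand `-` (coordinates always on the given
#' sequence).
#'
#' @param sequence DNA string (uppercased internally).
#' @param name Chromosome/record name placed in the output `chrom` column.
#' @param params A [pqs_params()] object.
#' @param both_strands Also scan the reverse strand (C-run motif).
#' @param allow_n Permit `N` within loops (default `FALSE`: a match may
#'   not contain `N` anywhere).
#' @return Interval tibble of motif hits with `strand` set.
#' @export
scan_pqs <- function(sequence, name = "seq", params = pqs_params(),
                     both_strands = FALSE, allow_n = FALSE) {
  stopifnot(inherits(params, "pqs_params"))
  sequence <- toupper(sequence)
  plus <- scan_pqs_one_strand(sequence, params, "G", allow_n)
  hits <- if (nrow(plus) > 0) {
    genomic_intervals(name, plus$start, plus$end, strand = "+")
  } else {
    genomic_intervals(character(), integer(), integer())
  }
  if (both_strands) {
    minus <- scan_pqs_one_strand(sequence, params, "C", allow_n)
    if (nrow(minus) > 0) {
      hits <- bind_rows(
        hits,
        genomic_intervals(name, minus$start, minus$end, strand = "-")
      )
    }
  }
  if (nrow(hits) > 0) {
    hits <- sort_intervals(hits)
    hits$name <- sprintf("pqs%d", seq_len(nrow(hits)))
  }
  hits
}
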