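test_that("BED round-trip preserves coordinates, names and strands", {
  x <- genomic_intervals(
    c("chr1", "chr2", "chr1"), c(100L, 5L, 7L), c(200L, 10L, 9L),
    name = c("a", "g4_1", NA), strand = c(".", "-", "+")
  )
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path)
  expect_equal(y$chrom, x$chrom)
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
  expect_equal(y$strand, x$strand)
  expect_equal(y$name[1:2], c("a", "g4_1"))

  # BED3 for a plain set, empty set gives an empty file
  plain <- genomic_intervals("chr1", 1L, 5L)
  write_bed(plain, path)
  expect_equal(readLines(path), "chr1\t1\t5")
  write_bed(genomic_intervals(character(), integer(), integer()), path)
  expect_length(readLines(path), 0)
})

test_that("BED parsing rejects malformed coordinates with a line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# comment", "chr1\t100\t200", "chr1\t200\t100"), path)
  expect_error(read_bed(path), "line 3")
  writeLines(c("chr1\tabc\t200"), path)
  expect_error(read_bed(path), "line 1")
  expect_error(genomic_intervals("chr1", 5L, 5L), "start < end")
})

test_that("sorting is stable and groups chromosomes lexicographically", {
  x <- genomic_intervals(c("chr2", "chr1", "chr1"), c(5L, 50L, 10L),
                         c(9L, 60L, 20L))
  s <- sort_intervals(x)
  expect_equal(s$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(s$start, c(10L, 50L, 5L))
  expect_equal(sort_intervals(s), s)
})

test_that("closest_distance matches bedtools -d gap semantics and signs", {
  ref <- genomic_intervals("chr1", 100L, 120L, name = "g4a")
  d <- function(s, e) {
    closest_distance(genomic_intervals("chr1", s, e), ref)$distance
  }
  expect_equal(d(130L, 131L), 10)    # downstream, 10 bp gap
  expect_equal(d(105L, 106L), 0)     # overlap
  expect_equal(d(120L, 121L), 0)     # book-ended
  expect_equal(d(121L, 122L), 1)     # one intervening bp
  expect_equal(d(99L, 100L), 0)      # book-ended on the left
  expect_equal(d(90L, 95L), -5)      # upstream is negative

  # queries on a chromosome without references are flagged NA
  q <- genomic_intervals(c("chr1", "chrX"), c(0L, 0L), c(1L, 1L))
  res <- closest_distance(q, ref)
  expect_true(is.na(res$distance[2]))
  expect_equal(res$ref_name[1], "g4a")
  expect_error(
    closest_distance(q, genomic_intervals(character(), integer(), integer())),
    "empty"
  )
})

test_that("closest_distance ties go to the leftmost reference", {
  refs <- genomic_intervals("chr1", c(0L, 20L), c(5L, 25L),
                            name = c("left", "right"))
  q <- genomic_intervals("chr1", 12L, 13L)   # 7 bp from both
  res <- closest_distance(q, refs)
  expect_equal(res$distance, 7)
  expect_equal(res$ref_name, "left")
})

test_that("strand-aware mode flips the sign at minus-strand references", {
  refs <- genomic_intervals("chr1", 100L, 120L, strand = "-")
  q <- genomic_intervals("chr1", 130L, 131L)
  expect_equal(closest_distance(q, refs)$distance, 10)
  expect_equal(closest_distance(q, refs, sign_by_strand = TRUE)$distance, -10)
})

test_that("closest_distance agrees with the exhaustive oracle", {
  withr::local_seed(101)
  for (k in 1:200) {
    q <- random_interval_set(sample(1:60, 1))
    r <- random_interval_set(sample(1:60, 1))
    expect_equal(closest_distance(q, r)$distance, oracle_closest(q, r))
  }
})

test_that("intersect_count uses half-open semantics and matches the oracle", {
  q <- genomic_intervals("chr1", 0L, 10L)
  refs <- genomic_intervals("chr1", c(5L, 9L, 10L), c(6L, 10L, 11L))
  expect_equal(intersect_count(q, refs), 2L)
  expect_equal(
    intersect_count(refs, genomic_intervals("chr9", 0L, 100L)),
    c(0L, 0L, 0L)
  )
  withr::local_seed(202)
  for (k in 1:200) {
    q <- random_interval_set(sample(1:60, 1))
    r <- random_interval_set(sample(1:60, 1))
    expect_equal(intersect_count(q, r), as.integer(oracle_intersect(q, r)))
  }
})

test_that("interval engine agrees with GenomicRanges on a random instance", {
  skip_if_not_installed("GenomicRanges")
  withr::local_seed(7)
  q <- random_interval_set(150)
  r <- random_interval_set(150)
  gr <- function(x) {
    GenomicRanges::GRanges(x$chrom,
                           IRanges::IRanges(x$start + 1L, x$end))
  }
  expect_equal(
    intersect_count(q, r),
    GenomicRanges::countOverlaps(gr(q), gr(r))
  )
})

test_that("make_windows follows the makewindows tiling dialect", {
  region <- genomic_intervals("chr1", 0L, 12000L)
  fixed <- make_windows(region, 5000)
  expect_equal(fixed$start, c(0L, 5000L, 10000L))
  expect_equal(fixed$end, c(5000L, 10000L, 12000L))
  # coverage conservation: union of fixed tiles equals the region
  expect_equal(sum(fixed$end - fixed$start), 12000L)
  expect_equal(min(fixed$start), 0L)
  expect_equal(max(fixed$end), 12000L)

  sliding <- make_windows(genomic_intervals("chr1", 0L, 7000L), 5000, 1000)
  expect_equal(sliding$start, seq(0L, 6000L, by = 1000L))
  expect_equal(sliding$end, pmin(sliding$start + 5000L, 7000L))

  short <- make_windows(genomic_intervals("chr1", 10L, 900L), 5000)
  expect_equal(nrow(short), 1L)
  expect_equal(short$end - short$start, 890L)
  expect_error(make_windows(region, 0), "size")
})

test_that("random_intervals is reproducible, contained, and uniform", {
  mask <- genomic_intervals("chr1", 0L, 1000L)
  a <- random_intervals(mask, 200, 5, seed = 3)
  b <- random_intervals(mask, 200, 5, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$start >= 0 & a$end <= 1000))
  expect_true(all(a$end - a$start == 200))
  expect_error(
    random_intervals(genomic_intervals("chr1", 0L, 150L), 200, 5, seed = 1),
    "at least"
  )

  # two equal mask intervals each receive half of 1e5 draws (+/- 1%)
  mask2 <- genomic_intervals("chr1", c(0L, 10000L), c(5000L, 15000L))
  x <- random_intervals(mask2, 100, 1e5, seed = 11)
  frac <- mean(x$start < 5000)
  expect_lt(abs(frac - 0.5), 0.01)

  # chi-squared goodness of fit against uniform starts, 20 bins
  y <- random_intervals(genomic_intervals("chr1", 0L, 20000L), 1, 1e5,
                        seed = 12)
  ct <- suppressWarnings(chisq.test(tabulate(y$start %/% 1000 + 1, 20)))
  expect_gt(ct$p.value, 0.01)
})
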