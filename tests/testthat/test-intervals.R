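test_that("narrowPeak parsing is format-exact and round trips", {
  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t200\tp1\t60\t.\t5.0\t10.0\t8.0\t50", np)
  ps <- read_peaks(np, format = "narrowPeak")
  expect_equal(ps$intervals$start, 100L)
  expect_equal(ps$intervals$end, 200L)
  expect_equal(ps$intervals$summit, 150L)

  writeLines("chr1\t100\t200\tp1\t60\t.\t5.0\t10.0\t8.0\t-1", np)
  expect_true(is.na(read_peaks(np, format = "narrowPeak")$intervals$summit))

  empty <- tempfile()
  file.create(empty)
  expect_equal(length(read_peaks(empty, format = "narrowPeak")), 0L)

  set.seed(1)
  df <- random_peaks(50)
  ps <- peak_set(df)
  bed <- tempfile(fileext = ".bed")
  write_bed(ps, bed)
  back <- read_peaks(bed, format = "bed6")
  expect_equal(back$intervals[, c("chrom", "start", "end", "name")],
               ps$intervals[, c("chrom", "start", "end", "name")])
  npf <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(ps, npf)
  back2 <- read_peaks(npf, format = "narrowPeak")
  expect_equal(back2$intervals[, c("chrom", "start", "end", "name", "summit")],
               ps$intervals[, c("chrom", "start", "end", "name", "summit")])
})

test_that("malformed input is rejected with a line number", {
  f <- tempfile()
  writeLines(c("chr1\t0\t10\ta\t1\t.", "chr1\t20"), f)
  expect_error(read_peaks(f, format = "bed6"), "line 2")
  writeLines("chr1\t30\t10\ta\t1\t.", f)
  expect_error(read_peaks(f, format = "bed6"), "start >= end")
  expect_error(peak_set(data.frame(chrom = "chr1", start = 5L, end = 5L,
                                   name = "x")), "start < end")
})

test_that("overlaps_any respects half-open coordinates and min_bp", {
  q <- peak_set(data.frame(chrom = "chr1", start = 0L, end = 100L, name = "q"))
  r <- peak_set(data.frame(chrom = "chr1", start = 100L, end = 200L, name = "r"))
  expect_false(overlaps_any(q, r, min_bp = 1L)) # book-ended, no shared base
  expect_true(overlaps_any(q, q, min_bp = 100L))
  expect_false(overlaps_any(q, q, min_bp = 101L))
  expect_equal(overlaps_any(q, peak_set()), FALSE)
  expect_error(overlaps_any(q, r, min_bp = 0L), "min_bp")
})

test_that("overlaps_any matches the brute-force oracle on random sets", {
  for (seed in 1:10) {
    set.seed(seed)
    q <- random_peaks(200, prefix = "q")
    r <- random_peaks(200, prefix = "r")
    min_bp <- sample(c(1L, 5L, 25L), 1)
    got <- overlaps_any(peak_set(q), peak_set(r), min_bp = min_bp)
    qsorted <- peak_set(q)$intervals
    expect_equal(got, oracle_overlaps_any(qsorted, r, min_bp))
  }
})

test_that("merge_union equals the per-base occupancy oracle", {
  a <- peak_set(data.frame(chrom = "chr1", start = 0L, end = 10L, name = "a"))
  b <- peak_set(data.frame(chrom = "chr1", start = 5L, end = 15L, name = "b"))
  expect_equal(merge_union(list(a, b))$intervals$end, 15L)
  d <- peak_set(data.frame(chrom = "chr1", start = c(0L, 20L),
                           end = c(10L, 30L), name = c("a", "b")))
  expect_equal(nrow(merge_union(list(d))$intervals), 2L)

  for (seed in 1:8) {
    set.seed(seed)
    gap <- sample(c(0L, 0L, 3L), 1)
    sets <- lapply(1:3, function(i)
      peak_set(random_peaks(60, max_pos = 400, prefix = paste0("s", i))))
    got <- merge_union(sets, gap = gap)$intervals
    exp <- oracle_union(lapply(sets, `[[`, "intervals"), gap = gap)
    rownames(exp) <- NULL
    expect_equal(got[, c("chrom", "start", "end")], exp)
  }
})

test_that("summit windows are flank-sized, clipped, and validated", {
  sizes <- c(chr1 = 10000L)
  ps <- peak_set(data.frame(chrom = "chr1", start = 4900L, end = 5100L,
                            name = "a", score = 1, summit = 5000L))
  w <- summit_windows(ps, flank = 3000L, chrom_sizes = sizes)
  expect_equal(unlist(w$intervals[, c("start", "end")], use.names = FALSE),
               c(2000L, 8000L)) # +/- 3 kb window
  ps2 <- peak_set(data.frame(chrom = "chr1", start = 900L, end = 1100L,
                             name = "b", score = 1, summit = 1000L))
  w2 <- summit_windows(ps2, flank = 3000L, chrom_sizes = sizes)
  expect_equal(unlist(w2$intervals[, c("start", "end")], use.names = FALSE),
               c(0L, 4000L))
  expect_error(summit_windows(ps, flank = 0L, chrom_sizes = sizes), "flank")
  expect_error(summit_windows(ps, 100L, c(chrX = 5L)), "chrX|chr1")
  # midpoint fallback
  nos <- peak_set(data.frame(chrom = "chr1", start = 0L, end = 100L,
                             name = "c"))
  expect_equal(summit_windows(nos, 10L, sizes)$intervals$start, 40L)
  expect_error(summit_windows(nos, 10L, sizes, midpoint_fallback = FALSE),
               "summit")
})

test_that("duplicate coordinates are deduplicated with a warning", {
  df <- data.frame(chrom = "chr1", start = c(0L, 0L), end = c(10L, 10L),
                   name = c("a", "b"))
  expect_warning(ps <- peak_set(df), "duplicated coordinates")
  expect_equal(length(ps), 1L)
})
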