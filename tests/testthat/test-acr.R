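chip_key <- function(clone = "WT") sample_key(clone, "plus", "plus", "ChIP")
atac_key <- function(clone = "WT") sample_key(clone, "plus", "plus", "ATAC")

test_that("define_acr keeps exactly the ChIP peaks gated by ATAC", {
  chip <- peak_set(data.frame(chrom = "chr1", start = c(0L, 500L),
                              end = c(100L, 600L), name = c("a", "b")),
                   chip_key())
  atac <- peak_set(data.frame(chrom = "chr1", start = 0L, end = 1000L,
                              name = "open"), atac_key())
  acr <- define_acr(chip, atac)
  expect_equal(acr$intervals$name, c("a", "b")) # ChIP coordinates retained
  expect_equal(acr$intervals$end, c(100L, 600L))
  none <- peak_set(data.frame(chrom = "chr2", start = 0L, end = 10L,
                              name = "x"), atac_key())
  expect_equal(length(define_acr(chip, none)), 0L)
  expect_error(define_acr(atac, chip), "ChIP")
  expect_error(
    define_acr(chip, peak_set(empty_intervals <- data.frame(
      chrom = character(), start = integer(), end = integer(),
      name = character()), sample_key("K303R", "plus", "plus", "ATAC"))),
    "different")
})

test_that("define_acr membership equals the brute-force pairwise check", {
  for (seed in 1:10) {
    set.seed(seed)
    chip <- peak_set(random_peaks(150, prefix = "c"), chip_key())
    atac <- peak_set(random_peaks(150, prefix = "a"), atac_key())
    min_bp <- sample(c(1L, 10L), 1)
    acr <- define_acr(chip, atac, min_bp = min_bp)
    exp <- oracle_overlaps_any(chip$intervals, atac$intervals, min_bp)
    expect_equal(acr$intervals$name, chip$intervals$name[exp])
    expect_lte(length(acr), length(chip)) # |ACR| <= |ChIP|
  }
})

test_that("clone-specificity partition matches a 3-way overlap oracle and sums", {
  for (seed in 1:8) {
    set.seed(seed)
    sets <- list(WT = peak_set(random_peaks(80, prefix = "w")),
                 Y537S = peak_set(random_peaks(80, prefix = "y")),
                 K303R = peak_set(random_peaks(80, prefix = "k")))
    part <- partition_clone_specificity(sets)
    for (cl in names(sets)) {
      df <- part[[cl]]
      others <- setdiff(names(sets), cl)
      n_over <- 1L +
        oracle_overlaps_any(df, sets[[others[1]]]$intervals, 1L) +
        oracle_overlaps_any(df, sets[[others[2]]]$intervals, 1L)
      exp <- ifelse(n_over == 3L, "common",
             ifelse(n_over == 1L, paste0(cl, "_specific"), "shared_subset"))
      expect_equal(df$partition, exp)
      # labels partition the universe: counts sum to the set size
      expect_equal(sum(table(df$partition)), length(sets[[cl]]))
    }
  }
})

test_that("planted disjoint partitions are recovered exactly", {
  mk <- function(idx, nm) peak_set(data.frame(
    chrom = "chr1", start = idx * 1000L, end = idx * 1000L + 200L,
    name = paste0(nm, idx), stringsAsFactors = FALSE))
  # loci 1-10 common, 11-15 WT only, 16-20 in WT+K303R
  sets <- list(WT = mk(c(1:10, 11:15, 16:20), "w"),
               Y537S = mk(1:10, "y"),
               K303R = mk(c(1:10, 16:20), "k"))
  part <- partition_clone_specificity(sets)
  wt <- part$WT[order(part$WT$start), ]
  expect_equal(wt$partition,
               rep(c("common", "WT_specific", "shared_subset"),
                   c(10, 5, 5)))
  expect_true(all(part$Y537S$partition == "common"))
})

test_that("motif_rate counts and rejects empty sets", {
  expect_equal(motif_rate(rep(TRUE, 7)), 1)
  expect_equal(motif_rate(rep(FALSE, 3)), 0)
  set.seed(2)
  for (i in 1:20) {
    f <- stats::runif(100) < 0.3
    expect_equal(motif_rate(f), sum(f) / 100)
  }
  expect_error(motif_rate(logical(0)), "empty")
})

test_that("variable-motif selection implements the max/min rate filter", {
  rates <- data.frame(
    motif_id = rep(c("m1", "m2"), each = 3),
    clone = rep(c("WT", "Y537S", "K303R"), 2),
    rate = c(0.05, 0.05, 0.20, 0.10, 0.10, 0.12))
  expect_equal(select_variable_motifs(rates, ratio_min = 3,
                                      rate_min = 0.15), "m1")
  # zero-minimum guard uses 1/group_size
  r0 <- data.frame(motif_id = "z", rate = c(0, 0.16))
  expect_equal(select_variable_motifs(r0, group_size = 100L), "z")
  # brute-force recomputation on random tables
  set.seed(8)
  for (i in 1:10) {
    tab <- data.frame(motif_id = rep(paste0("m", 1:12), each = 6),
                      rate = round(stats::runif(72, 0, 0.4), 3))
    got <- select_variable_motifs(tab, group_size = 500L)
    exp <- sort(Filter(function(m) {
      r <- tab$rate[tab$motif_id == m]
      max(r) / max(min(r), 1 / 500) >= 3 && max(r) >= 0.15
    }, unique(tab$motif_id)))
    expect_equal(got, exp)
  }
})

test_that("high-enrichment selection thresholds any-cell p-values", {
  res <- data.frame(motif_id = c("a", "a", "b", "b"),
                    p_value = c(1e-25, 1e-3, 1e-5, 1e-5))
  expect_equal(select_high_enrichment_motifs(res, p_max = 1e-20), "a")
  expect_equal(select_high_enrichment_motifs(res, p_max = 1e-4),
               c("a", "b"))
  set.seed(4)
  for (i in 1:10) {
    tab <- data.frame(motif_id = rep(paste0("m", 1:10), each = 4),
                      p_value = 10^-stats::runif(40, 0, 30))
    got <- select_high_enrichment_motifs(tab)
    exp <- sort(unique(tab$motif_id[tab$p_value <= 1e-20]))
    expect_equal(got, exp)
  }
})
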