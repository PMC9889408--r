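test_that("JASPAR loading normalises counts and enforces unique ids", {
  motifs <- toy_motifs()
  expect_named(motifs, c("FOX", "ERE_half", "AP1", "GATA"))
  expect_equal(pwm_consensus(motifs$FOX), "TGTTTAC")
  expect_equal(pwm_consensus(motifs$ERE_half), "AGGTCA")
  for (m in motifs)
    expect_equal(colSums(m$matrix), rep(1, ncol(m$matrix)),
                 tolerance = 1e-9)
  dup <- tempfile()
  writeLines(c(">M1 x", "A [ 1 1 1 1 ]", "C [ 1 1 1 1 ]",
               "G [ 1 1 1 1 ]", "T [ 1 1 1 1 ]",
               ">M1 y", "A [ 1 1 1 1 ]", "C [ 1 1 1 1 ]",
               "G [ 1 1 1 1 ]", "T [ 1 1 1 1 ]"), dup)
  expect_error(load_motifs(dup, "jaspar"), "duplicate")
})

test_that("MEME minimal format parses with background frequencies", {
  f <- tempfile()
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.30 C 0.20 G 0.20 T 0.30", "",
               "MOTIF TOY1", "letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0",
               " 0.97 0.01 0.01 0.01", " 0.01 0.97 0.01 0.01",
               " 0.01 0.01 0.97 0.01", " 0.01 0.01 0.01 0.97"), f)
  m <- load_motifs(f, "meme")
  expect_length(m, 1L)
  expect_equal(pwm_consensus(m$TOY1), "ACGT")
  expect_equal(unname(m$TOY1$background), c(0.3, 0.2, 0.2, 0.3))
  expect_equal(colSums(m$TOY1$matrix), rep(1, 4), tolerance = 1e-9)
})

test_that("a background-equal PWM scores every window zero", {
  flat <- pwm("FLAT", matrix(25, 4, 5))
  hits <- scan_pwm(flat, random_dna(50), threshold_fraction = 1)
  expect_true(all(hits$score == 0))
  expect_equal(pwm_max_score(flat), 0)
})

test_that("perfect consensus matches are found at threshold 1", {
  fox <- toy_motifs()$FOX
  s <- paste0("AAAA", "TGTTTAC", "AAAA", "GTAAACA", "CCCC")
  hits <- scan_pwm(fox, s, threshold_fraction = 1)
  expect_equal(hits$offset, c(4L, 15L))
  expect_equal(hits$strand, c("+", "-"))
  # N poisons windows
  expect_equal(nrow(scan_pwm(fox, "TGTNTAC", 0.5)), 0L)
  # sequence shorter than motif
  expect_equal(nrow(scan_pwm(fox, "TGT", 0.5)), 0L)
})

test_that("scan_pwm matches the naive sliding-window oracle", {
  motifs <- toy_motifs()
  set.seed(5)
  for (i in 1:20) {
    s <- random_dna(200)
    m <- motifs[[sample(length(motifs), 1)]]
    thr <- sample(c(0.5, 0.8, 1.0), 1)
    got <- scan_pwm(m, s, thr)
    exp <- oracle_scan(m, s, thr)
    expect_equal(nrow(got), nrow(exp))
    if (nrow(exp)) {
      o <- order(exp$offset, exp$strand)
      expect_equal(got$offset, exp$offset[o])
      expect_equal(got$strand, exp$strand[o])
      expect_equal(got$score, exp$score[o], tolerance = 1e-9)
    }
  }
})

test_that("strand-swap symmetry: reverse complement mirrors hits", {
  motifs <- toy_motifs()
  set.seed(99)
  for (i in 1:10) {
    s <- random_dna(150)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    m <- motifs[[sample(length(motifs), 1)]]
    h1 <- scan_pwm(m, s, 0.8)
    h2 <- scan_pwm(m, rc, 0.8)
    expect_equal(nrow(h1), nrow(h2))
    if (nrow(h1)) {
      L <- ncol(m$matrix)
      mirrored <- sort(nchar(s) - L - h1$offset)
      expect_equal(sort(h2$offset), mirrored)
    }
  }
})

test_that("classify_ere distinguishes none, half, and full sites", {
  ere <- toy_motifs()$ERE_half
  expect_equal(classify_ere("TTTTAGGTCATCATGACCTGGGG", ere), "full")
  expect_equal(classify_ere("TTTTAGGTCATTTTTTTTTTTTT", ere), "half")
  expect_equal(classify_ere("TTTTTTTTCCCCCCGGGGGGGGG", ere), "none")
  # wrong spacer is not a full site
  expect_equal(classify_ere("TTTTAGGTCATCTGACCTGGGGG", ere), "half")
  # everted arrangement (RC arm first) is not palindromic
  expect_equal(classify_ere("TTTTGACCTTCATAGGTCAGGGG", ere), "half")
})

test_that("classify_ere matches the pair-enumeration oracle", {
  ere <- toy_motifs()$ERE_half
  set.seed(12)
  seqs <- c(replicate(30, random_dna(200)),
            replicate(10, paste0(random_dna(40), "AGGTCA", random_dna(20))),
            replicate(10, paste0(random_dna(40), "AGGTCATTATGACCT",
                                 random_dna(20))))
  got <- classify_ere_many(seqs, ere)
  exp <- vapply(seqs, oracle_classify_ere, "", half_pwm = ere,
                USE.NAMES = FALSE)
  expect_equal(got, exp)
})

test_that("hypergeometric enrichment equals exact pmf summation", {
  # spec example: N=30, K=10, n=10, k=8
  grp <- data.frame(name = paste0("g", 1:10),
                    has_motif = c(rep(TRUE, 8), FALSE, FALSE))
  bg <- data.frame(name = c(grp$name, paste0("b", 1:20)),
                   has_motif = c(grp$has_motif, rep(TRUE, 2), rep(FALSE, 18)))
  r <- enrichment_test(grp, bg)
  expect_equal(r$p_value, sum(stats::dhyper(8:10, 10, 20, 10)),
               tolerance = 1e-12)
  expect_equal(r$score, -log10(r$p_value), tolerance = 1e-9)

  # exhaustive small cases
  for (N in c(5L, 12L, 30L)) {
    for (K in c(0L, N %/% 3, N)) {
      for (n in c(1L, N %/% 2, N)) {
        for (k in unique(c(max(0, K + n - N), min(n, K)))) {
          grp <- data.frame(name = paste0("r", seq_len(n)),
                            has_motif = rep(c(TRUE, FALSE),
                                            c(k, n - k)))
          bgf <- rep(c(TRUE, FALSE), c(K - k, N - n - (K - k)))
          bg <- data.frame(name = paste0("r", seq_len(N)),
                           has_motif = c(grp$has_motif, bgf))
          r <- enrichment_test(grp, bg)
          exp_p <- sum(stats::dhyper(k:min(n, K), K, N - K, n))
          expect_equal(r$p_value, exp_p, tolerance = 1e-10)
        }
      }
    }
  }
  # degenerate anchors
  grp0 <- data.frame(name = "a", has_motif = FALSE)
  expect_equal(enrichment_test(grp0, grp0)$p_value, 1)
  expect_error(enrichment_test(data.frame(name = "z", has_motif = TRUE),
                               grp0), "subset")
})

test_that("enrichment score is monotone in k for fixed (N, K, n)", {
  N <- 40L; K <- 15L; n <- 12L
  scores <- vapply(0:12, function(k) {
    grp <- data.frame(name = paste0("r", 1:n),
                      has_motif = rep(c(TRUE, FALSE), c(k, n - k)))
    bg <- data.frame(name = paste0("r", 1:N),
                     has_motif = c(grp$has_motif,
                                   rep(c(TRUE, FALSE),
                                       c(K - k, N - n - (K - k)))))
    enrichment_test(grp, bg)$score
  }, 0)
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("differential enrichment flags, sorts, and warns on missing motifs", {
  mut <- data.frame(motif_id = c("A", "B", "C"), score = c(30, 5, 12))
  wt <- data.frame(motif_id = c("A", "B", "C"), score = c(5, 5, 11))
  d <- differential_enrichment(mut, wt, delta_min = 10)
  expect_equal(d$motif_id, c("A", "C", "B"))
  expect_equal(d$delta, c(25, 1, 0))
  expect_equal(d$flagged, c(TRUE, FALSE, FALSE))
  expect_warning(
    d2 <- differential_enrichment(mut,
                                  data.frame(motif_id = "A", score = 5)),
    "missing")
  expect_equal(d2$delta[d2$motif_id == "C"], 12)
  # identical tables flag nothing
  d3 <- differential_enrichment(wt, wt, delta_min = 1)
  expect_false(any(d3$flagged))
})

test_that("top_enriched honours k, ties, and short tables", {
  res <- data.frame(motif_id = c("b", "a", "c", "d"),
                    score = c(3, 3, 10, 1))
  expect_equal(top_enriched(res, 2)$motif_id, c("c", "a"))
  expect_equal(nrow(top_enriched(res, 10)), 4L)
  set.seed(3)
  big <- data.frame(motif_id = paste0("m", 1:50),
                    score = sample(1:10, 50, TRUE))
  got <- top_enriched(big, 5)
  o <- big[order(-big$score, big$motif_id), ]
  expect_equal(got$motif_id, utils::head(o$motif_id, 5))
})
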