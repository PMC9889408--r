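# Shared fixtures and independent brute-force oracles.

toy_motif_path <- function() {
  system.file("extdata", "toy_motifs.jaspar", package = "eracr")
}

toy_motifs <- function() load_motifs(toy_motif_path(), format = "jaspar")

# Random interval table on a small coordinate space (oracle-friendly).
random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L,
                         max_width = 60L, prefix = "p") {
  start <- sample.int(max_pos, n, replace = n > max_pos) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             name = paste0(prefix, seq_len(n)),
             score = round(stats::runif(n, 0, 100), 2),
             summit = NA_integer_, stringsAsFactors = FALSE)
}

# O(n*m) per-pair overlap oracle.
oracle_overlaps_any <- function(qdf, rdf, min_bp = 1L) {
  vapply(seq_len(nrow(qdf)), function(i) {
    same <- rdf$chrom == qdf$chrom[i]
    any(pmin(rdf$end[same], qdf$end[i]) -
          pmax(rdf$start[same], qdf$start[i]) >= min_bp)
  }, logical(1))
}

# Per-base occupancy oracle for interval union (small coordinates only).
oracle_union <- function(dfs, gap = 0L) {
  df <- do.call(rbind, lapply(dfs, function(d)
    d[, c("chrom", "start", "end")]))
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, , drop = FALSE]
    occ <- rep(FALSE, max(d$end) + gap + 2L)
    for (i in seq_len(nrow(d))) occ[(d$start[i] + 1L):d$end[i]] <- TRUE
    if (gap > 0) { # positions bridged by the gap tolerance
      r <- rle(occ)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in seq_along(r$values))
        if (!r$values[j] && r$lengths[j] <= gap &&
            j > 1 && j < length(r$values))
          occ[starts[j]:ends[j]] <- TRUE
    }
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep] - 1L,
                              end = ends[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Naive sliding-window PWM scan (independent of scan_pwm internals).
oracle_scan <- function(pwm, sequence, threshold_fraction = 0.8) {
  score_window <- function(mat, win) {
    if (any(!win %in% c("A", "C", "G", "T"))) return(-Inf)
    sum(vapply(seq_along(win), function(j)
      log2(mat[win[j], j] / pwm$background[win[j]]), 0))
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- ncol(pwm$matrix)
  maxs <- sum(apply(log2(pwm$matrix / pwm$background), 2, max))
  thr <- threshold_fraction * maxs
  rcmat <- pwm_reverse_complement(pwm)$matrix
  hits <- list()
  for (o in seq_len(max(length(chars) - L + 1L, 0L))) {
    win <- chars[o:(o + L - 1L)]
    sf <- score_window(pwm$matrix, win)
    sr <- score_window(rcmat, win)
    if (is.finite(sf) && sf >= thr)
      hits[[length(hits) + 1L]] <- data.frame(offset = o - 1L,
                                              strand = "+", score = sf)
    if (is.finite(sr) && sr >= thr)
      hits[[length(hits) + 1L]] <- data.frame(offset = o - 1L,
                                              strand = "-", score = sr)
  }
  if (!length(hits))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  do.call(rbind, hits)
}

# Exhaustive pair-enumeration ERE oracle on top of oracle_scan.
oracle_classify_ere <- function(sequence, half_pwm, spacer = 3L,
                                threshold_fraction = 0.8) {
  h <- oracle_scan(half_pwm, sequence, threshold_fraction)
  if (!nrow(h)) return("none")
  L <- ncol(half_pwm$matrix)
  fwd <- h$offset[h$strand == "+"]
  rev <- h$offset[h$strand == "-"]
  for (f in fwd) for (r in rev) if (r - f == L + spacer) return("full")
  "half"
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# The full fig4c scenario is expensive (~6 s to generate); build it once
# per test run and share across tests.
.scenario_cache <- new.env(parent = emptyenv())

fig4c_scenario <- function(seed = 11L) {
  key <- paste0("s", seed)
  if (is.null(.scenario_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("fig4c_", seed))
    plant_scenario(fig4c_config(seed = seed), dir)
    .scenario_cache[[key]] <- load_scenario(dir)
    .scenario_cache[[key]]$dir <- dir
  }
  .scenario_cache[[key]]
}

# Small scenario for structural/determinism tests.
small_config <- function(seed = 7L) {
  scenario_config(seed = seed, n_chroms = 2L, chrom_length = 400000L,
                  n_chip = 400L, n_common = 120L, n_background = 100L)
}

best_cluster_accuracy <- function(assign, truth, k) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(p[assign] == truth))
  best
}
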