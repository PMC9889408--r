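FOX_CONSENSUS <- "TGTTTAC"
ERE_HALF_CONSENSUS <- "AGGTCA"
ERA_CLONES <- c("WT", "Y537S", "K303R")

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Scenario configuration for the synthetic generator
#'
#' The defaults encode the `fig4c` scenario: a three-clone (WT, Y537S,
#' K303R) peak landscape whose planted Fox/ERE rates are the published
#' co-occurrence statistics, so every downstream analysis can be tested
#' as a round trip against known truth. All rates are Bernoulli
#' probabilities; all randomness flows from `seed`.
#'
#' @param seed Integer RNG seed (required; full determinism per seed).
#' @param n_chroms,chrom_length,gc Genome shape: number of chromosomes,
#'   length each (bp), GC fraction.
#' @param region_width,region_gap Planted peak width and inter-locus gap
#'   (bp); loci never overlap.
#' @param n_chip ChIP peaks per clone per Dox+ condition.
#' @param n_common Tri-clone common active regions per condition.
#' @param n_background Constitutively open (ATAC-only) loci present in
#'   every sample.
#' @param fox_fraction Named per-clone probability that a ChIP peak
#'   carries the Fox motif.
#' @param ere_free Named per-clone probability that a Fox-positive peak
#'   carries no ERE.
#' @param shared Probability that a WT Fox-positive peak is also a K303R
#'   Fox-positive peak (same locus).
#' @param opening Named chromatin-opening probabilities per Fox stratum
#'   plus the `filler` baseline for other ChIP peaks.
#' @param ere_half_rate,ere_full_rate Named per-condition (e2_minus,
#'   e2_plus) ERE label probabilities for the common regions.
#' @param ere_full_given_present Among ERE-carrying Fox peaks, the
#'   probability the ERE is a full site (rest are half sites).
#' @return A list of class `ScenarioConfig`.
#' @export
scenario_config <- function(seed,
                            n_chroms = 4L,
                            chrom_length = 1800000L,
                            gc = 0.41,
                            region_width = 200L,
                            region_gap = 100L,
                            n_chip = 4000L,
                            n_common = 1200L,
                            n_background = 1000L,
                            fox_fraction = c(WT = 0.165, Y537S = 0.10,
                                             K303R = 0.185),
                            ere_free = c(WT = 0.636, Y537S = 0.65,
                                         K303R = 0.681),
                            shared = 0.80,
                            opening = c(WT_specific = 0.085,
                                        K303R_specific = 0.452,
                                        shared_WT = 0.20,
                                        shared_K303R = 0.35,
                                        Y537S_fox = 0.25,
                                        filler = 0.60),
                            ere_half_rate = c(e2_minus = 0.11,
                                              e2_plus = 0.25),
                            ere_full_rate = c(e2_minus = 0.05,
                                              e2_plus = 0.15),
                            ere_full_given_present = 1 / 3) {
  if (missing(seed) || is.na(as.integer(seed)))
    stop("scenario_config: an integer seed is required")
  if (chrom_length < 10L * region_width)
    stop("scenario_config: chrom_length must be >= 10x region_width")
  rates <- c(fox_fraction, ere_free, shared, opening, ere_half_rate,
             ere_full_rate, ere_full_given_present, gc)
  if (any(rates < 0 | rates > 1))
    stop("scenario_config: all rates must be in [0, 1]")
  if (n_common >= n_chip)
    stop("scenario_config: n_common must be < n_chip")
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length), gc = gc,
                 region_width = as.integer(region_width),
                 region_gap = as.integer(region_gap),
                 n_chip = as.integer(n_chip),
                 n_common = as.integer(n_common),
                 n_background = as.integer(n_background),
                 fox_fraction = fox_fraction, ere_free = ere_free,
                 shared = shared, opening = opening,
                 ere_half_rate = ere_half_rate,
                 ere_full_rate = ere_full_rate,
                 ere_full_given_present = ere_full_given_present),
            class = "ScenarioConfig")
}

#' The fig4c default scenario configuration
#' @param seed Integer RNG seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return A `ScenarioConfig`.
#' @export
fig4c_config <- function(seed, ...) scenario_config(seed = seed, ...)

random_genome_chars <- function(config) {
  prob <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
            G = config$gc / 2, T = (1 - config$gc) / 2)
  lapply(seq_len(config$n_chroms), function(i)
    sample(DNA_BASES, config$chrom_length, replace = TRUE, prob = prob))
}

genome_chars_to_dss <- function(chars) {
  dss <- Biostrings::DNAStringSet(vapply(chars, paste, "", collapse = ""))
  names(dss) <- paste0("chr", seq_along(chars))
  dss
}

#' Simulate a random genome FASTA
#'
#' I.i.d. bases at the configured GC fraction; byte-identical output for
#' identical config (seeded).
#'
#' @param config A [scenario_config()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
simulate_genome <- function(config, path) {
  stopifnot(inherits(config, "ScenarioConfig"))
  set.seed(config$seed)
  dss <- genome_chars_to_dss(random_genome_chars(config))
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}

# Remove unintended occurrences of the tracked motif strings from a
# region, never touching planted (masked) bases. Mutates at most one
# base per offending match per sweep; bounded sweeps.
scrub_region <- function(chars, mask, strings) {
  for (iter in 1:25) {
    s <- paste(chars, collapse = "")
    offend <- NULL
    for (pat in strings) {
      m <- gregexpr(pat, s, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      for (p in as.integer(m)) {
        idx <- p:(p + nchar(pat) - 1L)
        if (!all(mask[idx])) offend <- c(offend, list(idx))
      }
    }
    if (is.null(offend)) return(chars)
    for (idx in offend) {
      free <- idx[!mask[idx]]
      pos <- free[ceiling(length(free) / 2)]
      chars[pos] <- sample(setdiff(DNA_BASES, chars[pos]), 1)
    }
  }
  warning("scrub_region: motif scrubbing did not converge in 25 sweeps")
  chars
}

draw_ere_label <- function(n, p_half, p_full) {
  if (!n) return(character(0))
  sample(c("full", "half", "none"), n, replace = TRUE,
         prob = c(p_full, p_half, 1 - p_half - p_full))
}

# ERE label for fox peaks from an ERE-free probability: free -> none,
# otherwise full with probability p_full_given, else half.
draw_fox_ere <- function(n, p_free, p_full_given) {
  if (!n) return(character(0))
  free <- stats::runif(n) < p_free
  full <- stats::runif(n) < p_full_given
  ifelse(free, "none", ifelse(full, "full", "half"))
}

#' Generate the full synthetic scenario (genome, peaks, truth manifest)
#'
#' Draws non-overlapping loci, writes motif instances into the genome
#' sequence (scrubbing chance occurrences of the tracked Fox/ERE
#' consensus strings from analysed loci), and emits one narrowPeak file
#' per clone x Dox x E2 x assay cell realising the planted presence,
#' sharing and opening structure by Bernoulli draws at the configured
#' probabilities. The manifest records every draw.
#'
#' Emitted samples: clones control, WT, Y537S, K303R; the control clone
#' has background-only ATAC and empty ChIP. Dox- ChIP files are empty
#' (no ectopic ERa); Dox- ATAC files hold the constitutive background
#' loci. The Fox co-occurrence structure lives in the Dox+/E2+ cell; the
#' condition-specific common active regions exist per E2 condition under
#' Dox+.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `dir`, `config`, `loci` (truth table),
#'   `motifs` (planted motif instances), `files` (sample sheet).
#' @export
plant_scenario <- function(config, out_dir) {
  stopifnot(inherits(config, "ScenarioConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  w <- config$region_width
  step <- w + config$region_gap

  genome <- random_genome_chars(config)

  # --- allocate loci -------------------------------------------------
  n_fox <- stats::setNames(
    vapply(ERA_CLONES, function(cl)
      stats::rbinom(1, config$n_chip, config$fox_fraction[[cl]]), 0L),
    ERA_CLONES)
  n_shared <- min(stats::rbinom(1, n_fox[["WT"]], config$shared),
                  n_fox[["K303R"]])
  groups <- list(
    common_e2_minus = config$n_common,
    common_e2_plus = config$n_common,
    fox_shared = n_shared,
    fox_WT = n_fox[["WT"]] - n_shared,
    fox_K303R = n_fox[["K303R"]] - n_shared,
    fox_Y537S = n_fox[["Y537S"]])
  for (cl in ERA_CLONES) {
    groups[[paste0("filler_plus_", cl)]] <-
      config$n_chip - config$n_common - n_fox[[cl]]
    groups[[paste0("filler_minus_", cl)]] <-
      config$n_chip - config$n_common
  }
  groups$background <- config$n_background
  total <- sum(unlist(groups))

  slots_per_chrom <- (config$chrom_length - w) %/% step + 1L
  capacity <- config$n_chroms * slots_per_chrom
  if (total > capacity)
    stop("plant_scenario: ", total, " loci exceed genome capacity of ",
         capacity, " slots")
  slot_idx <- sample.int(capacity, total)
  chrom_i <- (slot_idx - 1L) %/% slots_per_chrom + 1L
  start <- ((slot_idx - 1L) %% slots_per_chrom) * step
  grp <- rep(names(groups), unlist(groups))

  loci <- data.frame(
    id = sprintf("L%06d", seq_len(total)),
    chrom = paste0("chr", chrom_i),
    start = start, end = start + w,
    group = grp, stringsAsFactors = FALSE)
  loci$role <- ifelse(grepl("^common", grp), "common",
               ifelse(grepl("^fox", grp), "fox",
               ifelse(grepl("^filler", grp), "filler", "background")))
  loci$condition <- ifelse(grp == "common_e2_minus", "e2_minus",
                    ifelse(grp == "common_e2_plus", "e2_plus",
                    ifelse(grepl("^fox", grp), "e2_plus",
                    ifelse(grepl("minus", grp), "e2_minus",
                    ifelse(grepl("plus", grp), "e2_plus", "both")))))
  loci$stratum <- NA_character_
  loci$stratum[grp == "fox_shared"] <- "shared"
  loci$stratum[grp == "fox_WT"] <- "WT_specific"
  loci$stratum[grp == "fox_K303R"] <- "K303R_specific"
  loci$stratum[grp == "fox_Y537S"] <- "Y537S_fox"

  for (cl in ERA_CLONES)
    loci[[paste0("chip_", cl)]] <-
      grp %in% c("common_e2_minus", "common_e2_plus") |
      grp == "fox_shared" & cl %in% c("WT", "K303R") |
      grp == paste0("fox_", cl) |
      grp %in% paste0(c("filler_plus_", "filler_minus_"), cl)
  loci$fox <- loci$role == "fox"

  # --- ERE labels ----------------------------------------------------
  loci$ere <- "none"
  for (cond in c("e2_minus", "e2_plus")) {
    i <- which(grp == paste0("common_", cond))
    loci$ere[i] <- draw_ere_label(length(i),
                                  config$ere_half_rate[[cond]],
                                  config$ere_full_rate[[cond]])
  }
  # Shared Fox loci carry one sequence read by both clones, so they are
  # drawn at the WT rate; the K303R-only rate is adjusted so the K303R
  # marginal ERE-free fraction still matches its configured value.
  i <- which(grp == "fox_shared")
  loci$ere[i] <- draw_fox_ere(length(i), config$ere_free[["WT"]],
                              config$ere_full_given_present)
  i <- which(grp == "fox_WT")
  loci$ere[i] <- draw_fox_ere(length(i), config$ere_free[["WT"]],
                              config$ere_full_given_present)
  i <- which(grp == "fox_K303R")
  p_adj <- if (length(i)) {
    min(max((config$ere_free[["K303R"]] * n_fox[["K303R"]] -
             config$ere_free[["WT"]] * n_shared) / length(i), 0), 1)
  } else 0
  loci$ere[i] <- draw_fox_ere(length(i), p_adj,
                              config$ere_full_given_present)
  i <- which(grp == "fox_Y537S")
  loci$ere[i] <- draw_fox_ere(length(i), config$ere_free[["Y537S"]],
                              config$ere_full_given_present)

  # --- opening flags -------------------------------------------------
  for (cl in ERA_CLONES) loci[[paste0("open_", cl)]] <- FALSE
  loci[loci$role %in% c("common", "background"),
       paste0("open_", ERA_CLONES)] <- TRUE
  op <- config$opening
  draw <- function(i, p) stats::runif(length(i)) < p
  i <- which(grp == "fox_shared")
  loci$open_WT[i] <- draw(i, op[["shared_WT"]])
  loci$open_K303R[i] <- draw(i, op[["shared_K303R"]])
  i <- which(grp == "fox_WT")
  loci$open_WT[i] <- draw(i, op[["WT_specific"]])
  i <- which(grp == "fox_K303R")
  loci$open_K303R[i] <- draw(i, op[["K303R_specific"]])
  i <- which(grp == "fox_Y537S")
  loci$open_Y537S[i] <- draw(i, op[["Y537S_fox"]])
  for (cl in ERA_CLONES) {
    i <- which(grp %in% paste0(c("filler_plus_", "filler_minus_"), cl))
    loci[[paste0("open_", cl)]][i] <- draw(i, op[["filler"]])
  }

  # --- plant motif instances and scrub analysed loci -----------------
  fox_rc <- revcomp_chr(FOX_CONSENSUS)
  ere_rc <- revcomp_chr(ERE_HALF_CONSENSUS)
  scrub_strings <- c(FOX_CONSENSUS, fox_rc, ERE_HALF_CONSENSUS, ere_rc)
  Lf <- nchar(FOX_CONSENSUS)
  Le <- nchar(ERE_HALF_CONSENSUS)
  spacer <- 3L
  motif_rows <- vector("list", total)
  analysed <- which(loci$role %in% c("common", "fox", "filler"))
  for (ix in analysed) {
    ci <- chrom_i[ix]
    s0 <- loci$start[ix]
    chars <- genome[[ci]][(s0 + 1L):(s0 + w)]
    mask <- rep(FALSE, w)
    rows <- list()
    if (loci$ere[ix] != "none") {
      if (loci$ere[ix] == "full") {
        o <- sample(10:(90 - (2L * Le + spacer)), 1)
        span <- 2L * Le + spacer
        chars[(o + 1L):(o + Le)] <- strsplit(ERE_HALF_CONSENSUS, "")[[1]]
        chars[(o + Le + spacer + 1L):(o + span)] <- strsplit(ere_rc, "")[[1]]
        mask[(o + 1L):(o + span)] <- TRUE
        rows <- c(rows, list(data.frame(
          locus = loci$id[ix], motif = "ERE_full", chrom = loci$chrom[ix],
          start = s0 + o, strand = "+",
          consensus = paste0(ERE_HALF_CONSENSUS,
                             paste(chars[(o + Le + 1L):(o + Le + spacer)],
                                   collapse = ""), ere_rc),
          stringsAsFactors = FALSE)))
      } else {
        o <- sample(10:(90 - Le), 1)
        st <- sample(c("+", "-"), 1)
        arm <- if (st == "+") ERE_HALF_CONSENSUS else ere_rc
        chars[(o + 1L):(o + Le)] <- strsplit(arm, "")[[1]]
        mask[(o + 1L):(o + Le)] <- TRUE
        rows <- c(rows, list(data.frame(
          locus = loci$id[ix], motif = "ERE_half", chrom = loci$chrom[ix],
          start = s0 + o, strand = st, consensus = arm,
          stringsAsFactors = FALSE)))
      }
    }
    if (loci$fox[ix]) {
      o <- sample(110:(w - 10L - Lf), 1)
      st <- sample(c("+", "-"), 1)
      m <- if (st == "+") FOX_CONSENSUS else fox_rc
      chars[(o + 1L):(o + Lf)] <- strsplit(m, "")[[1]]
      mask[(o + 1L):(o + Lf)] <- TRUE
      rows <- c(rows, list(data.frame(
        locus = loci$id[ix], motif = "FOX", chrom = loci$chrom[ix],
        start = s0 + o, strand = st, consensus = m,
        stringsAsFactors = FALSE)))
    }
    chars <- scrub_region(chars, mask, scrub_strings)
    genome[[ci]][(s0 + 1L):(s0 + w)] <- chars
    if (length(rows)) motif_rows[[ix]] <- do.call(rbind, rows)
  }
  motifs <- do.call(rbind, motif_rows[!vapply(motif_rows, is.null,
                                              logical(1))])

  # --- write files ---------------------------------------------------
  fasta <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome_chars_to_dss(genome), fasta,
                              width = 70L)
  sizes <- data.frame(chrom = paste0("chr", seq_len(config$n_chroms)),
                      size = config$chrom_length)
  utils::write.table(sizes, file.path(out_dir, "chrom.sizes"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  locus_peaks <- function(idx) {
    if (!length(idx)) return(empty_intervals())
    d <- loci[idx, , drop = FALSE]
    data.frame(chrom = d$chrom, start = d$start, end = d$end, name = d$id,
               score = 100, summit = d$start + w %/% 2L,
               stringsAsFactors = FALSE)
  }
  sheet <- list()
  for (cl in c("control", ERA_CLONES)) {
    for (dox in c("plus", "minus")) {
      for (e2 in c("plus", "minus")) {
        for (assay in c("ATAC", "ChIP")) {
          cond <- paste0("e2_", e2)
          idx <- if (assay == "ChIP") {
            if (dox == "minus" || cl == "control") integer(0)
            else which(loci[[paste0("chip_", cl)]] & loci$condition == cond)
          } else {
            bg <- which(loci$role == "background")
            if (dox == "minus" || cl == "control") bg
            else c(bg, which(loci[[paste0("chip_", cl)]] &
                             loci$condition == cond &
                             loci[[paste0("open_", cl)]]))
          }
          fn <- paste(cl, dox, e2, assay, sep = "_")
          fn <- paste0(fn, ".narrowPeak")
          write_narrowpeak(peak_set(locus_peaks(idx),
                                    sample_key(cl, dox, e2, assay)),
                           file.path(out_dir, fn))
          sheet[[length(sheet) + 1L]] <- data.frame(
            file = fn, clone = cl, dox = dox, e2 = e2, assay = assay,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  sheet <- do.call(rbind, sheet)
  utils::write.table(sheet, file.path(out_dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # named vectors -> named lists so JSON keeps the names
  cfg_json <- lapply(unclass(config), function(x)
    if (!is.null(names(x))) as.list(x) else x)
  manifest <- list(config = cfg_json, loci = loci, motifs = motifs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = FALSE)
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir, config = config, loci = loci,
                 motifs = motifs, files = sheet))
}

#' Load a generated scenario directory
#'
#' @param dir Directory written by [plant_scenario()].
#' @return List: `peaks` (named list of PeakSets, `clone.dox.e2.assay`),
#'   `genome` (`DNAStringSet`), `manifest`, `config`, `sheet`.
#' @export
load_scenario <- function(dir) {
  sheet <- utils::read.table(file.path(dir, "sample_sheet.tsv"),
                             sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  peaks <- list()
  for (i in seq_len(nrow(sheet))) {
    key <- sample_key(sheet$clone[i], sheet$dox[i], sheet$e2[i],
                      sheet$assay[i])
    peaks[[format(key)]] <- read_peaks(file.path(dir, sheet$file[i]),
                                       key, format = "narrowPeak")
  }
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  list(peaks = peaks,
       genome = Biostrings::readDNAStringSet(file.path(dir, "genome.fa")),
       manifest = manifest, config = manifest$config, sheet = sheet)
}

#' Verify a scenario's manifest against its emitted files
#'
#' Checks (a) every planted motif record matches the genome sequence at
#' its coordinates, (b) peak files agree with the manifest's membership
#' flags, and (c) empirical Bernoulli rates lie within 4 standard errors
#' of their configured values.
#'
#' @param dir Scenario directory.
#' @return `data.frame` of per-check results: `check`, `value`,
#'   `expected`, `pass`, `detail`.
#' @export
verify_manifest <- function(dir) {
  sc <- load_scenario(dir)
  loci <- sc$manifest$loci
  motifs <- sc$manifest$motifs
  cfg <- sc$config
  out <- list()
  add <- function(check, value, expected, pass, detail = "")
    out[[length(out) + 1L]] <<- data.frame(
      check = check, value = value, expected = expected, pass = pass,
      detail = detail, stringsAsFactors = FALSE)

  seqs <- vapply(seq_len(nrow(motifs)), function(i)
    as.character(Biostrings::subseq(sc$genome[[motifs$chrom[i]]],
                                    motifs$start[i] + 1L,
                                    motifs$start[i] +
                                      nchar(motifs$consensus[i]))), "")
  bad <- which(seqs != motifs$consensus)
  add("motif_sequences_match", length(bad), 0, length(bad) == 0,
      if (length(bad)) paste("first mismatch at locus", motifs$locus[bad[1]])
      else "")

  chip_wt <- sc$peaks[["WT.plus.plus.ChIP"]]$intervals$name
  in_manifest <- loci$id[loci$chip_WT & loci$condition == "e2_plus"]
  add("chip_file_matches_manifest", length(setdiff(chip_wt, in_manifest)) +
        length(setdiff(in_manifest, chip_wt)), 0,
      setequal(chip_wt, in_manifest))

  rate_check <- function(check, x, p) {
    n <- length(x)
    se <- sqrt(p * (1 - p) / max(n, 1))
    v <- mean(x)
    add(check, v, p, abs(v - p) <= 4 * se + 1e-12,
        paste0("n=", n))
  }
  for (cl in c("WT", "K303R")) {
    e2p <- loci[loci[[paste0("chip_", cl)]] & loci$condition == "e2_plus", ]
    rate_check(paste0("fox_fraction_", cl), e2p$fox,
               cfg$fox_fraction[[cl]])
    fx <- e2p[e2p$fox, ]
    rate_check(paste0("ere_free_", cl), fx$ere == "none",
               cfg$ere_free[[cl]])
  }
  wt_fox <- loci[loci$fox & loci$chip_WT, ]
  rate_check("shared_fraction_WT", wt_fox$stratum == "shared", cfg$shared)
  ks <- loci[!is.na(loci$stratum) & loci$stratum == "K303R_specific", ]
  rate_check("opening_K303R_specific", ks$open_K303R,
             cfg$opening[["K303R_specific"]])
  ws <- loci[!is.na(loci$stratum) & loci$stratum == "WT_specific", ]
  rate_check("opening_WT_specific", ws$open_WT,
             cfg$opening[["WT_specific"]])
  for (cond in c("e2_minus", "e2_plus")) {
    cm <- loci[loci$role == "common" & loci$condition == cond, ]
    rate_check(paste0("ere_half_common_", cond), cm$ere == "half",
               cfg$ere_half_rate[[cond]])
    rate_check(paste0("ere_full_common_", cond), cm$ere == "full",
               cfg$ere_full_rate[[cond]])
  }
  do.call(rbind, out)
}

#' Simulate clustered peak landscapes for PCA testing
#'
#' Generates samples around `k` planted landscape centroids: each
#' centroid owns a set of loci; a sample drawn from centroid `c`
#' contains each of that centroid's loci with probability `p_in`, each
#' other centroid's loci with probability `p_out`, plus private noise
#' loci.
#'
#' @param seed Integer seed.
#' @param k Number of centroids.
#' @param n_per_cluster Samples per centroid.
#' @param n_loci Loci per centroid.
#' @param p_in,p_out Inclusion probabilities.
#' @param n_noise Private noise loci per sample.
#' @return List: `samples` (named list of PeakSets), `cluster` (true
#'   assignment, integer per sample).
#' @export
simulate_clustered_samples <- function(seed, k = 3L, n_per_cluster = 4L,
                                       n_loci = 300L, p_in = 0.9,
                                       p_out = 0.05, n_noise = 60L) {
  set.seed(seed)
  w <- 200L
  step <- 300L
  n_slots <- k * n_loci + n_per_cluster * k * n_noise + 1000L
  starts <- (seq_len(n_slots) - 1L) * step
  perm <- sample.int(n_slots)
  centroid_loci <- split(perm[seq_len(k * n_loci)],
                         rep(seq_len(k), each = n_loci))
  pool <- perm[(k * n_loci + 1L):n_slots]
  samples <- list()
  cluster <- integer(0)
  used <- 0L
  for (c in seq_len(k)) {
    for (r in seq_len(n_per_cluster)) {
      keep <- unlist(lapply(seq_len(k), function(cc) {
        p <- if (cc == c) p_in else p_out
        loci <- centroid_loci[[cc]]
        loci[stats::runif(length(loci)) < p]
      }))
      noise <- pool[(used + 1L):(used + n_noise)]
      used <- used + n_noise
      slots <- sort(c(keep, noise))
      nm <- paste0("S", c, "_", r)
      samples[[nm]] <- peak_set(data.frame(
        chrom = "chr1", start = starts[slots], end = starts[slots] + w,
        name = paste0("p", slots), stringsAsFactors = FALSE))
      cluster <- c(cluster, c)
    }
  }
  list(samples = samples, cluster = cluster)
}
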