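DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix (PWM)
#'
#' Count (or probability) matrices are regularised with a per-base
#' pseudocount and normalised so every column sums to 1. Scanning scores
#' are log2-odds against the background distribution.
#'
#' @param motif_id Unique motif identifier.
#' @param counts 4 x L numeric matrix, rows A, C, G, T. Probability
#'   matrices are accepted and rescaled by `nsites` before the pseudocount
#'   is applied.
#' @param background Length-4 background probabilities (A, C, G, T),
#'   default uniform.
#' @param pseudocount Added to every cell before normalisation, default
#'   0.25.
#' @param nsites Effective count total used when `counts` columns sum
#'   to ~1 (probability input), default 100.
#' @return An object of class `PWM`.
#' @export
pwm <- function(motif_id, counts, background = rep(0.25, 4),
                pseudocount = 0.25, nsites = 100) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("pwm: counts must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 4) stop("pwm: motif length must be >= 4")
  if (any(counts < 0)) stop("pwm: negative counts")
  cs <- colSums(counts)
  if (any(cs == 0)) stop("pwm: zero-total column in motif ", motif_id)
  if (all(abs(cs - 1) < 1e-6)) counts <- counts * nsites
  mat <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  background <- background / sum(background)
  rownames(mat) <- DNA_BASES
  structure(list(motif_id = motif_id, matrix = mat,
                 background = stats::setNames(background, DNA_BASES),
                 pseudocount = pseudocount),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("<PWM>", x$motif_id, "- length", ncol(x$matrix),
      "- consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus string (most probable base per position)
#' @param x A [pwm()].
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$matrix, 2, which.max)], collapse = "")
}

# log2-odds score matrix, with an extra row of -Inf for N/ambiguity.
pwm_score_matrix <- function(x) {
  s <- log2(x$matrix / x$background)
  rbind(s, `N` = rep(-Inf, ncol(s)))
}

#' Maximum attainable log2-odds score of a PWM
#' @param x A [pwm()].
#' @return Numeric scalar (bits).
#' @export
pwm_max_score <- function(x) {
  sum(apply(log2(x$matrix / x$background), 2, max))
}

#' Reverse-complement a PWM
#' @param x A [pwm()].
#' @return A `PWM` scanning the opposite strand.
#' @export
pwm_reverse_complement <- function(x) {
  m <- x$matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(x$matrix))),
                drop = FALSE]
  rownames(m) <- DNA_BASES
  y <- x
  y$matrix <- m
  y$background <- stats::setNames(x$background[c("T", "G", "C", "A")],
                                  DNA_BASES)
  y
}

#' Load motifs from JASPAR or MEME text format
#'
#' JASPAR: `>ID name` header followed by four `A [ ... ]` style count
#' rows. MEME minimal text: `MOTIF` blocks with a `letter-probability
#' matrix` section; the file-level `Background letter frequencies` line is
#' honoured when present.
#'
#' @param path Motif file.
#' @param format `"jaspar"` or `"meme"`.
#' @param pseudocount Passed to [pwm()].
#' @return Named list of [pwm()] objects.
#' @export
load_motifs <- function(path, format = c("jaspar", "meme"),
                        pseudocount = 0.25) {
  format <- match.arg(format)
  lines <- readLines(path)
  out <- if (format == "jaspar") parse_jaspar(lines, pseudocount)
         else parse_meme(lines, pseudocount)
  ids <- vapply(out, `[[`, "", "motif_id")
  if (anyDuplicated(ids))
    stop("load_motifs: duplicate motif id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(out, ids)
}

parse_jaspar <- function(lines, pseudocount) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("load_motifs: no JASPAR headers found")
  out <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1] - 1L else length(lines)
    block <- lines[from:to]
    block <- block[nzchar(trimws(block))]
    if (length(block) < 4) stop("load_motifs: truncated JASPAR block")
    id <- strsplit(sub("^>\\s*", "", lines[hdr[i]]), "\\s+")[[1]][1]
    rows <- lapply(block[1:4], function(l) {
      nums <- regmatches(l, gregexpr("[0-9.eE+-]+", l))[[1]]
      as.numeric(nums)
    })
    base <- toupper(substr(trimws(block[1:4]), 1, 1))
    mat <- do.call(rbind, rows)
    if (all(sort(base) == DNA_BASES)) mat <- mat[match(DNA_BASES, base), ]
    if (ncol(mat) == 0) stop("load_motifs: zero-column motif ", id)
    out[[length(out) + 1L]] <- pwm(id, mat, pseudocount = pseudocount)
  }
  out
}

parse_meme <- function(lines, pseudocount) {
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    nums <- as.numeric(regmatches(lines[bgi[1] + 1],
                                  gregexpr("[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?",
                                           lines[bgi[1] + 1]))[[1]])
    if (length(nums) >= 4) bg <- nums[1:4]
  }
  mi <- grep("^MOTIF", lines)
  if (!length(mi)) stop("load_motifs: no MEME MOTIF blocks found")
  out <- list()
  for (i in seq_along(mi)) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[mi[i]])), "\\s+")[[1]][1]
    to <- if (i < length(mi)) mi[i + 1] - 1L else length(lines)
    block <- lines[mi[i]:to]
    li <- grep("letter-probability matrix", block)
    if (!length(li)) stop("load_motifs: MOTIF ", id, " lacks matrix")
    w <- suppressWarnings(as.integer(sub(".*w=\\s*([0-9]+).*", "\\1",
                                         block[li[1]])))
    ns <- suppressWarnings(as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1",
                                          block[li[1]])))
    if (is.na(ns)) ns <- 20
    rows <- block[(li[1] + 1):length(block)]
    rows <- rows[grepl("^\\s*[0-9.]", rows)]
    if (!is.na(w)) rows <- rows[seq_len(w)]
    mat <- vapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])[1:4], numeric(4))
    dimnames(mat) <- NULL
    out[[length(out) + 1L]] <- pwm(id, mat, background = bg,
                                   pseudocount = pseudocount, nsites = ns)
  }
  out
}

encode_dna <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  codes <- match(chars, DNA_BASES)
  codes[is.na(codes)] <- 5L
  codes
}

scan_one_strand <- function(codes, smat) {
  L <- ncol(smat)
  n <- length(codes)
  W <- n - L + 1L
  if (W < 1L) return(numeric(0))
  sc <- numeric(W)
  for (j in seq_len(L)) sc <- sc + smat[codes[j:(j + W - 1L)], j]
  sc
}

#' Scan a DNA sequence with a PWM on both strands
#'
#' A window is a hit when its log2-odds score reaches
#' `threshold_fraction * pwm_max_score(pwm)`. Windows containing `N`
#' score `-Inf` and never hit. Offsets are 0-based window starts relative
#' to the sequence, for both strands.
#'
#' @param pwm A [pwm()].
#' @param sequence DNA string over A, C, G, T, N.
#' @param threshold_fraction Fraction of the maximum attainable score in
#'   (0, 1], default 0.8.
#' @param region_name Optional name stored with each hit.
#' @return `data.frame` with columns `region_name`, `motif_id`, `offset`,
#'   `strand`, `score`, sorted by offset then strand.
#' @export
scan_pwm <- function(pwm, sequence, threshold_fraction = 0.8,
                     region_name = NA_character_) {
  stopifnot(inherits(pwm, "PWM"))
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1)
    stop("scan_pwm: threshold_fraction must be in (0, 1]")
  codes <- encode_dna(sequence)
  smat_f <- pwm_score_matrix(pwm)
  smat_r <- pwm_score_matrix(pwm_reverse_complement(pwm))
  thr <- threshold_fraction * pwm_max_score(pwm)
  sc_f <- scan_one_strand(codes, smat_f)
  sc_r <- scan_one_strand(codes, smat_r)
  hit_f <- which(sc_f >= thr)
  hit_r <- which(sc_r >= thr)
  nh <- length(hit_f) + length(hit_r)
  out <- data.frame(
    region_name = rep(region_name, nh),
    motif_id = rep(pwm$motif_id, nh),
    offset = c(hit_f, hit_r) - 1L,
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(sc_f[hit_f], sc_r[hit_r]),
    stringsAsFactors = FALSE)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Motif presence flag for many sequences
#'
#' @param sequences Character vector of DNA strings.
#' @param pwm A [pwm()].
#' @param threshold_fraction Passed to [scan_pwm()].
#' @return Logical vector: does each sequence contain >= 1 hit?
#' @export
scan_presence <- function(sequences, pwm, threshold_fraction = 0.8) {
  smat_f <- pwm_score_matrix(pwm)
  smat_r <- pwm_score_matrix(pwm_reverse_complement(pwm))
  thr <- threshold_fraction * pwm_max_score(pwm)
  vapply(sequences, function(s) {
    codes <- encode_dna(s)
    any(scan_one_strand(codes, smat_f) >= thr) ||
      any(scan_one_strand(codes, smat_r) >= thr)
  }, logical(1), USE.NAMES = FALSE)
}

#' Classify a sequence for estrogen response element (ERE) content
#'
#' A *full* site is the palindromic arrangement: a forward half-site hit
#' followed, after exactly `spacer` intervening bases, by a
#' reverse-complement half-site hit (consensus `AGGTCAnnnTGACCT` for
#' spacer 3). A *half* site is any half-site hit without such a pair.
#'
#' @param sequence DNA string.
#' @param half_site_pwm [pwm()] of the half site (e.g. AGGTCA).
#' @param spacer Gap between the two arms in bp, default 3.
#' @param threshold_fraction Passed to [scan_pwm()].
#' @return `"none"`, `"half"` or `"full"`.
#' @export
classify_ere <- function(sequence, half_site_pwm, spacer = 3L,
                         threshold_fraction = 0.8) {
  hits <- scan_pwm(half_site_pwm, sequence, threshold_fraction)
  if (!nrow(hits)) return("none")
  L <- ncol(half_site_pwm$matrix)
  fwd <- hits$offset[hits$strand == "+"]
  rev <- hits$offset[hits$strand == "-"]
  if (length(fwd) && length(rev) &&
      any(outer(fwd, rev, function(f, r) r - f == L + spacer)))
    return("full")
  "half"
}

#' Vectorised [classify_ere()]
#' @inheritParams classify_ere
#' @param sequences Character vector of DNA strings.
#' @return Character vector of labels.
#' @export
classify_ere_many <- function(sequences, half_site_pwm, spacer = 3L,
                              threshold_fraction = 0.8) {
  vapply(sequences, classify_ere, "", half_site_pwm = half_site_pwm,
         spacer = spacer, threshold_fraction = threshold_fraction,
         USE.NAMES = FALSE)
}

#' Hypergeometric motif enrichment of a region group against a background
#'
#' Tests whether regions carrying the motif are over-represented in the
#' group relative to the background (upper tail, exact hypergeometric).
#' The group must be a subset of the background.
#'
#' @param group `data.frame` with columns `name`, `has_motif` (logical)
#'   for the group regions.
#' @param background Same layout, for the background regions (which must
#'   contain every group region name).
#' @param motif_id,group_id Labels carried into the result.
#' @return One-row `data.frame`: `motif_id`, `group_id`, `k`, `n`, `K`,
#'   `N`, `p_value`, `score` (= -log10 p).
#' @export
enrichment_test <- function(group, background, motif_id = NA_character_,
                            group_id = NA_character_) {
  if (!all(group$name %in% background$name))
    stop("enrichment_test: group is not a subset of the background")
  k <- sum(group$has_motif)
  n <- nrow(group)
  K <- sum(background$has_motif)
  N <- nrow(background)
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  data.frame(motif_id = motif_id, group_id = group_id,
             k = k, n = n, K = K, N = N,
             p_value = exp(lp), score = -lp / log(10),
             stringsAsFactors = FALSE)
}

#' Enrichment over a motif hit table
#'
#' Convenience wrapper running [enrichment_test()] for every motif in a
#' region x motif presence matrix.
#'
#' @param flags Logical matrix, regions x motifs, rownames = region names.
#' @param group_names Region names forming the group.
#' @param group_id Label for the group.
#' @return `data.frame`, one row per motif, with Benjamini-Hochberg
#'   adjusted p-values alongside the raw score.
#' @export
enrichment_table <- function(flags, group_names, group_id = NA_character_) {
  stopifnot(is.matrix(flags), !is.null(rownames(flags)))
  bg <- data.frame(name = rownames(flags), stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(colnames(flags), function(m) {
    bgm <- transform(bg, has_motif = flags[, m])
    grp <- bgm[bgm$name %in% group_names, , drop = FALSE]
    enrichment_test(grp, bgm, motif_id = m, group_id = group_id)
  }))
  res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Differential motif enrichment: mutant clone vs wild type
#'
#' Scores are the -log10 p enrichment scores; a motif is flagged when
#' `score_mutant - score_wildtype >= delta_min`. Motifs present in only
#' one table get score 0 on the missing side, with a warning.
#'
#' @param mutant,wildtype `data.frame`s with columns `motif_id`, `score`.
#' @param delta_min Flagging threshold on the score difference, default 10.
#' @return `data.frame` sorted by `delta` descending (ties by motif id)
#'   with columns `motif_id`, `score_mutant`, `score_wildtype`, `delta`,
#'   `flagged`.
#' @export
differential_enrichment <- function(mutant, wildtype, delta_min = 10) {
  ids <- sort(union(mutant$motif_id, wildtype$motif_id))
  only <- c(setdiff(mutant$motif_id, wildtype$motif_id),
            setdiff(wildtype$motif_id, mutant$motif_id))
  if (length(only))
    warning("differential_enrichment: motif(s) missing from one side ",
            "treated as score 0: ", paste(only, collapse = ", "))
  sm <- stats::setNames(rep(0, length(ids)), ids)
  sw <- sm
  sm[mutant$motif_id] <- mutant$score
  sw[wildtype$motif_id] <- wildtype$score
  out <- data.frame(motif_id = ids, score_mutant = unname(sm),
                    score_wildtype = unname(sw),
                    delta = unname(sm - sw), stringsAsFactors = FALSE)
  out$flagged <- out$delta >= delta_min
  out[order(-out$delta, out$motif_id), , drop = FALSE]
}

#' Top-k motifs by enrichment score
#'
#' @param results `data.frame` with `motif_id`, `score`.
#' @param k Number of motifs to keep (>= 1); ties broken by motif id.
#' @return The k highest-scoring rows (all rows when k exceeds the table).
#' @export
top_enriched <- function(results, k = 5L) {
  if (k < 1) stop("top_enriched: k must be >= 1")
  o <- order(-results$score, results$motif_id)
  utils::head(results[o, , drop = FALSE], k)
}

#' Extract peak sequences from a genome
#'
#' @param genome A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param peaks A [peak_set()] (or interval data frame).
#' @return Named character vector of region sequences (names = peak names).
#' @export
peak_sequences <- function(genome, peaks) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  df <- if (inherits(peaks, "PeakSet")) peaks$intervals else peaks
  if (!nrow(df)) return(stats::setNames(character(0), character(0)))
  unknown <- setdiff(unique(df$chrom), names(genome))
  if (length(unknown))
    stop("peak_sequences: chromosome(s) absent from genome: ",
         paste(unknown, collapse = ", "))
  seqs <- vapply(seq_len(nrow(df)), function(i)
    as.character(Biostrings::subseq(genome[[df$chrom[i]]],
                                    start = df$start[i] + 1L,
                                    end = df$end[i])), "")
  stats::setNames(seqs, df$name)
}
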