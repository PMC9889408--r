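#' Fraction of ERa ChIP peaks carrying the Fox motif
#'
#' @param chip ChIP [peak_set()] (or interval data frame).
#' @param fox_flags Logical vector aligned to the peaks: Fox motif
#'   presence.
#' @return Fraction in `[0, 1]`.
#' @export
fox_chip_fraction <- function(chip, fox_flags) {
  n <- if (inherits(chip, "PeakSet")) nrow(chip$intervals) else nrow(chip)
  if (!n) stop("fox_chip_fraction: empty ChIP peak set")
  if (length(fox_flags) != n)
    stop("fox_chip_fraction: flags not aligned to peaks")
  mean(as.logical(fox_flags))
}

#' Fraction of Fox-positive peaks without any ERE
#'
#' @param ere_labels Character vector of [classify_ere()] labels
#'   (`none`/`half`/`full`) for the Fox-positive peaks.
#' @return Fraction labelled `none`.
#' @export
ere_free_fraction <- function(ere_labels) {
  if (!length(ere_labels)) stop("ere_free_fraction: empty input")
  bad <- setdiff(unique(ere_labels), c("none", "half", "full"))
  if (length(bad))
    stop("ere_free_fraction: unknown label(s): ", paste(bad, collapse = ", "))
  mean(ere_labels == "none")
}

#' Per-direction sharing of Fox-positive peaks between two clones
#'
#' A peak of one clone is shared when it overlaps any Fox-positive peak
#' of the other clone by >= `min_bp`.
#'
#' @param fox_a,fox_b [peak_set()]s of Fox-positive ChIP peaks of the two
#'   clones.
#' @param min_bp Minimum overlap.
#' @return Named numeric of length 2: fraction of `fox_a` shared,
#'   fraction of `fox_b` shared. `NaN` for an empty set.
#' @export
shared_fraction <- function(fox_a, fox_b, min_bp = 1L) {
  c(a_shared = mean(overlaps_any(fox_a, fox_b, min_bp = min_bp)),
    b_shared = mean(overlaps_any(fox_b, fox_a, min_bp = min_bp)))
}

#' Label Fox-positive peaks as shared or clone-specific between two clones
#'
#' @param fox_a,fox_b Fox-positive [peak_set()]s of the two clones.
#' @param clone_a,clone_b Clone names used in the labels.
#' @param min_bp Minimum overlap.
#' @return List with per-clone label vectors (`shared` or
#'   `<clone>_specific`), aligned to each clone's peaks.
#' @export
fox_partition <- function(fox_a, fox_b, clone_a = "WT", clone_b = "K303R",
                          min_bp = 1L) {
  sa <- overlaps_any(fox_a, fox_b, min_bp = min_bp)
  sb <- overlaps_any(fox_b, fox_a, min_bp = min_bp)
  out <- list(ifelse(sa, "shared", paste0(clone_a, "_specific")),
              ifelse(sb, "shared", paste0(clone_b, "_specific")))
  stats::setNames(out, c(clone_a, clone_b))
}

#' Chromatin-opening rate of Fox-positive peaks per stratum
#'
#' For each stratum (e.g. clone partition x ERE label) reports the
#' fraction of peaks overlapping at least one ATAC peak. Empty strata
#' are reported with `rate = NA` (undefined), never 0.
#'
#' @param fox_peaks [peak_set()] of Fox-positive ChIP peaks.
#' @param strata Character vector (or data frame of label columns)
#'   aligned to the peaks.
#' @param atac ATAC [peak_set()] of the same clone/condition.
#' @param min_bp Minimum overlap for "open".
#' @return `data.frame`: `stratum`, `n`, `n_open`, `rate`.
#' @export
opening_rate <- function(fox_peaks, strata, atac, min_bp = 1L) {
  if (is.data.frame(strata))
    strata <- do.call(paste, c(strata, sep = "."))
  df <- if (inherits(fox_peaks, "PeakSet")) fox_peaks$intervals else fox_peaks
  if (length(strata) != nrow(df))
    stop("opening_rate: strata not aligned to peaks")
  open <- overlaps_any(fox_peaks, atac, min_bp = min_bp)
  out <- do.call(rbind, lapply(sort(unique(strata)), function(s) {
    idx <- strata == s
    data.frame(stratum = s, n = sum(idx), n_open = sum(open[idx]),
               rate = if (sum(idx)) mean(open[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full FoxA1 co-occurrence report for two clones
#'
#' Computes, for a pair of clones (canonically WT and K303R): the
#' fraction of ChIP peaks with a Fox motif, the ERE-free fraction among
#' those, the per-direction sharing between the clones, and the
#' chromatin-opening rate stratified by clone partition and ERE label.
#'
#' @param chip Named list (two clones) of ChIP [peak_set()]s.
#' @param atac Named list (same clones) of matching ATAC [peak_set()]s.
#' @param genome `DNAStringSet` or FASTA path.
#' @param fox_pwm [pwm()] used for Fox motif presence.
#' @param ere_pwm [pwm()] of the ERE half site.
#' @param threshold_fraction PWM hit threshold, default 0.8.
#' @param spacer ERE full-site spacer, default 3.
#' @param min_bp Overlap threshold for sharing and opening.
#' @return List with elements `fractions` (per clone), `sharing`,
#'   `opening` (stratified table) and the per-clone Fox peak tables.
#' @export
fox_report <- function(chip, atac, genome, fox_pwm, ere_pwm,
                       threshold_fraction = 0.8, spacer = 3L, min_bp = 1L) {
  clones <- names(chip)
  stopifnot(length(clones) == 2L, identical(sort(clones), sort(names(atac))))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  fox_sets <- list()
  fractions <- list()
  for (cl in clones) {
    seqs <- peak_sequences(genome, chip[[cl]])
    fox <- scan_presence(seqs, fox_pwm, threshold_fraction)
    fox_set <- peak_set(chip[[cl]]$intervals[fox, , drop = FALSE],
                        chip[[cl]]$sample)
    labels <- classify_ere_many(peak_sequences(genome, fox_set), ere_pwm,
                                spacer, threshold_fraction)
    fox_sets[[cl]] <- list(peaks = fox_set, ere = labels)
    fractions[[cl]] <- data.frame(
      clone = cl,
      n_chip = length(fox), n_fox = sum(fox),
      fox_fraction = fox_chip_fraction(chip[[cl]], fox),
      ere_free_fraction = ere_free_fraction(labels),
      stringsAsFactors = FALSE)
  }
  a <- clones[1]; b <- clones[2]
  sharing <- shared_fraction(fox_sets[[a]]$peaks, fox_sets[[b]]$peaks,
                             min_bp = min_bp)
  names(sharing) <- c(a, b)
  part <- fox_partition(fox_sets[[a]]$peaks, fox_sets[[b]]$peaks,
                        clone_a = a, clone_b = b, min_bp = min_bp)
  opening <- do.call(rbind, lapply(clones, function(cl) {
    strat <- data.frame(partition = part[[cl]], ere = fox_sets[[cl]]$ere)
    tab <- opening_rate(fox_sets[[cl]]$peaks, strat, atac[[cl]],
                        min_bp = min_bp)
    bypart <- opening_rate(fox_sets[[cl]]$peaks, part[[cl]], atac[[cl]],
                           min_bp = min_bp)
    tab$level <- "partition.ere"
    bypart$level <- "partition"
    cbind(clone = cl, rbind(bypart, tab))
  }))
  list(fractions = do.call(rbind, fractions),
       sharing = sharing,
       max_sharing = max(sharing),
       opening = opening,
       fox_sets = fox_sets,
       partition = part)
}
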