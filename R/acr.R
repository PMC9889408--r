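#' Define ERa-bound active chromatin regions (ERa-ACR)
#'
#' An ERa-ACR is a ChIP peak (ERa binding) that overlaps an ATAC peak
#' (open chromatin) of the same clone and condition by at least `min_bp`
#' bases. Coordinates of the result are the ChIP peak's: ChIP defines
#' "ERa-bound", ATAC only gates "active".
#'
#' @param chip ChIP-seq [peak_set()].
#' @param atac ATAC-seq [peak_set()] for the same clone/condition.
#' @param min_bp Minimum overlap, default 1.
#' @return A [peak_set()] holding the qualifying ChIP peaks.
#' @export
define_acr <- function(chip, atac, min_bp = 1L) {
  if (!is.null(chip$sample) && !is.null(atac$sample)) {
    if (chip$sample$assay != "ChIP" || atac$sample$assay != "ATAC")
      stop("define_acr: expected (chip = ChIP peaks, atac = ATAC peaks); got (",
           chip$sample$assay, ", ", atac$sample$assay, ")")
    if (chip$sample$clone != atac$sample$clone ||
        chip$sample$dox != atac$sample$dox ||
        chip$sample$e2 != atac$sample$e2)
      stop("define_acr: ChIP and ATAC samples are from different ",
           "clone/condition cells")
  }
  keep <- overlaps_any(chip, atac, min_bp = min_bp)
  peak_set(chip$intervals[keep, , drop = FALSE], chip$sample)
}

#' Partition ACR regions by clone specificity
#'
#' Across the three ERa-expressing clones, a region is `common` when it
#' overlaps ACR regions of all three clones, `<clone>_specific` when it
#' overlaps no other clone's ACR, and `shared_subset` when it is found in
#' exactly two clones (kept explicit so counts remain auditable).
#'
#' @param acr_by_clone Named list of three [peak_set()]s (names = clone).
#' @param min_bp Minimum overlap for cross-clone region identity.
#' @return Named list of `data.frame`s (one per clone): region columns
#'   plus `n_clones` and `partition`.
#' @export
partition_clone_specificity <- function(acr_by_clone, min_bp = 1L) {
  clones <- names(acr_by_clone)
  if (length(clones) != 3L || is.null(clones))
    stop("partition_clone_specificity: need a named list of exactly ",
         "three clones")
  out <- list()
  for (cl in clones) {
    df <- acr_by_clone[[cl]]$intervals[, c("chrom", "start", "end", "name")]
    inothers <- vapply(setdiff(clones, cl), function(other)
      overlaps_any(acr_by_clone[[cl]], acr_by_clone[[other]],
                   min_bp = min_bp),
      logical(nrow(df)))
    if (nrow(df) == 1L) inothers <- matrix(inothers, nrow = 1L)
    n_clones <- 1L + as.integer(rowSums(inothers))
    df$n_clones <- n_clones
    df$partition <- ifelse(n_clones == 3L, "common",
                    ifelse(n_clones == 1L, paste0(cl, "_specific"),
                           "shared_subset"))
    out[[cl]] <- df
  }
  out
}

#' Fraction of regions carrying a motif
#'
#' @param motif_flags Logical vector: motif presence per region.
#' @return Fraction in `[0, 1]`.
#' @export
motif_rate <- function(motif_flags) {
  if (!length(motif_flags))
    stop("motif_rate: undefined for an empty region set")
  mean(as.logical(motif_flags))
}

#' Select motifs with variable rates across clones/conditions
#'
#' Implements the rate filter "Max/Min >= ratio_min and max rate >=
#' rate_min in any condition". Zero minima are guarded by
#' `eps = 1 / max(group_size)`.
#'
#' @param rates `data.frame` with columns `motif_id`, `rate`, plus any
#'   grouping columns (clone, condition); all cells of one motif are its
#'   rows.
#' @param ratio_min Minimum max/min rate ratio, default 3.
#' @param rate_min Minimum maximal rate, default 0.15 (15%).
#' @param group_size Largest region-group size behind the rates, used for
#'   the zero-minimum guard; default 1000.
#' @return Character vector of selected motif ids (sorted).
#' @export
select_variable_motifs <- function(rates, ratio_min = 3, rate_min = 0.15,
                                   group_size = 1000L) {
  eps <- 1 / max(as.numeric(group_size), 1)
  sel <- vapply(split(rates$rate, rates$motif_id), function(r) {
    mx <- max(r)
    mx / max(min(r), eps) >= ratio_min && mx >= rate_min
  }, logical(1))
  sort(names(sel)[sel])
}

#' Select highly enriched motifs across clone x condition cells
#'
#' A motif is selected when any cell reaches `p_value <= p_max`
#' (default 1e-20).
#'
#' @param results `data.frame` with columns `motif_id`, `p_value` (one
#'   row per clone x condition cell).
#' @param p_max Selection threshold, default `1e-20`.
#' @return Character vector of selected motif ids (sorted).
#' @export
select_high_enrichment_motifs <- function(results, p_max = 1e-20) {
  sel <- vapply(split(results$p_value, results$motif_id),
                function(p) any(p <= p_max), logical(1))
  sort(names(sel)[sel])
}
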