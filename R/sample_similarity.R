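#' Build a consensus presence/score matrix across samples ("DBA-lite")
#'
#' Consensus regions are the [merge_union()] of all samples' peaks. In
#' `binary` mode a cell is 1 when the sample has a peak overlapping the
#' region; in `score` mode it is the maximum score of the overlapping
#' peaks (0 when absent). This is an occupancy stand-in for read-count
#' differential binding affinity analysis, which needs raw reads.
#'
#' @param samples List (>= 2) of [peak_set()]s, each carrying a
#'   SampleKey (or named list).
#' @param mode `"binary"` or `"score"`.
#' @param min_bp Minimum overlap for presence.
#' @param gap Merge gap for the consensus, default 0.
#' @return List: `matrix` (regions x samples), `regions` ([peak_set()]),
#'   `samples` (column key table).
#' @export
build_presence_matrix <- function(samples, mode = c("binary", "score"),
                                  min_bp = 1L, gap = 0L) {
  mode <- match.arg(mode)
  if (length(samples) < 2L)
    stop("build_presence_matrix: need at least 2 samples")
  if (is.null(names(samples)) || !all(nzchar(names(samples))))
    names(samples) <- vapply(samples, function(s)
      if (!is.null(s$sample)) format(s$sample) else "", "")
  if (!all(nzchar(names(samples))) || anyDuplicated(names(samples)))
    stop("build_presence_matrix: samples must be uniquely named or carry ",
         "SampleKeys")
  consensus <- merge_union(samples, gap = gap)
  nr <- nrow(consensus$intervals)
  m <- matrix(0, nrow = nr, ncol = length(samples),
              dimnames = list(consensus$intervals$name, names(samples)))
  cgr <- as_granges(consensus)
  for (j in seq_along(samples)) {
    sdf <- samples[[j]]$intervals
    if (!nrow(sdf)) next
    hits <- GenomicRanges::findOverlaps(
      cgr, as_granges(sdf, unique(consensus$intervals$chrom)),
      minoverlap = as.integer(min_bp))
    qh <- S4Vectors::queryHits(hits)
    if (mode == "binary") {
      m[unique(qh), j] <- 1
    } else {
      sc <- sdf$score[S4Vectors::subjectHits(hits)]
      sc[is.na(sc)] <- 0
      agg <- tapply(sc, qh, max)
      m[as.integer(names(agg)), j] <- as.numeric(agg)
    }
  }
  list(matrix = m, regions = consensus,
       samples = data.frame(sample = names(samples),
                            stringsAsFactors = FALSE))
}

#' PCA projection of samples from a presence matrix
#'
#' Performs principal component analysis of the sample x region matrix
#' (samples as observations, regions centred). Coordinates are
#' deterministic up to per-component sign.
#'
#' @param presence Output of [build_presence_matrix()] (or a plain
#'   regions x samples matrix).
#' @param n_components Number of components, at most the number of
#'   samples.
#' @return List: `coordinates` (samples x components), `sdev`,
#'   `explained_variance` (fractions), `rotation`, `center`.
#' @export
pca_project <- function(presence, n_components = 2L) {
  m <- if (is.list(presence) && !is.null(presence$matrix)) presence$matrix
       else as.matrix(presence)
  x <- t(m) # samples x regions
  if (n_components > nrow(x))
    stop("pca_project: n_components exceeds the number of samples")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(p$sdev^2)
  k <- min(n_components, length(p$sdev))
  list(coordinates = p$x[, seq_len(k), drop = FALSE],
       sdev = p$sdev,
       explained_variance = if (total > 0) p$sdev^2 / total
                            else rep(0, length(p$sdev)),
       rotation = p$rotation,
       center = p$center)
}
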