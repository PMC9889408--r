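#' Dual-luciferase fold changes relative to a reference condition
#'
#' Each well is normalised as firefly / Renilla; condition folds are the
#' mean per-well ratio divided by the mean reference-condition ratio
#' (per-well normalisation, the standard dual-luciferase convention).
#'
#' @param wells `data.frame` with columns `condition`, `replicate`,
#'   `firefly` (>= 0), `renilla` (> 0).
#' @param reference_condition Condition the folds are relative to (e.g.
#'   the no-receptor, no-ligand control); must be present.
#' @return List: `conditions` (`condition`, `n`, `mean_ratio`, `fold`)
#'   and `wells` (input plus per-well `ratio` and `fold`).
#' @export
fold_change <- function(wells, reference_condition) {
  needed <- c("condition", "replicate", "firefly", "renilla")
  miss <- setdiff(needed, names(wells))
  if (length(miss))
    stop("fold_change: missing column(s): ", paste(miss, collapse = ", "))
  if (any(wells$renilla <= 0))
    stop("fold_change: renilla signal must be > 0 in every well")
  if (any(wells$firefly < 0))
    stop("fold_change: negative firefly signal")
  if (!reference_condition %in% wells$condition)
    stop("fold_change: reference condition '", reference_condition,
         "' has no wells")
  wells$ratio <- wells$firefly / wells$renilla
  ref_mean <- mean(wells$ratio[wells$condition == reference_condition])
  wells$fold <- wells$ratio / ref_mean
  agg <- aggregate(ratio ~ condition, wells, mean)
  out <- data.frame(condition = agg$condition,
                    n = as.integer(table(wells$condition)[agg$condition]),
                    mean_ratio = agg$ratio,
                    fold = agg$ratio / ref_mean,
                    stringsAsFactors = FALSE)
  list(conditions = out, wells = wells)
}
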