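CONDITIONS <- c("dox_minus.e2_minus", "dox_minus.e2_plus",
                "dox_plus.e2_minus", "dox_plus.e2_plus")

condition_id <- function(dox, e2) {
  paste0("dox_", dox, ".e2_", e2)
}

#' Presence of consensus regions across the four Dox x E2 conditions
#'
#' For one clone and one assay, evaluates which of the four treatment
#' conditions each consensus region was detected in (binary, overlap
#' based).
#'
#' @param consensus A [peak_set()] of consensus regions (typically
#'   [merge_union()] of the clone's four condition peak sets).
#' @param per_condition Named list of four [peak_set()]s; names must be
#'   the condition ids `dox_minus.e2_minus`, `dox_minus.e2_plus`,
#'   `dox_plus.e2_minus`, `dox_plus.e2_plus` (see [condition_id()]), or
#'   the PeakSets must carry SampleKeys from which the ids are derived.
#' @param min_bp Minimum overlap for presence, default 1.
#' @return `data.frame`: region columns plus one logical presence column
#'   per condition.
#' @export
build_presence <- function(consensus, per_condition, min_bp = 1L) {
  if (is.null(names(per_condition)) || !all(nzchar(names(per_condition)))) {
    names(per_condition) <- vapply(per_condition, function(p) {
      if (is.null(p$sample)) stop("build_presence: unnamed PeakSet without SampleKey")
      condition_id(p$sample$dox, p$sample$e2)
    }, "")
  }
  missing <- setdiff(CONDITIONS, names(per_condition))
  if (length(missing))
    stop("build_presence: missing condition(s): ",
         paste(missing, collapse = ", "))
  df <- consensus$intervals[, c("chrom", "start", "end", "name")]
  for (cond in CONDITIONS)
    df[[cond]] <- overlaps_any(consensus, per_condition[[cond]],
                               min_bp = min_bp)
  df
}

presence_quad <- function(pattern) {
  if (is.data.frame(pattern)) pattern <- pattern[1, CONDITIONS]
  p <- as.logical(unlist(pattern[CONDITIONS]))
  if (length(p) != 4L || anyNA(p))
    stop("presence pattern must provide the four condition flags")
  stats::setNames(p, CONDITIONS)
}

#' Condition-specific group of a presence pattern
#'
#' A region is `<condition>_specific` when it was detected in exactly one
#' of the four conditions: nontreated (Dox-/E2-), E2 only, Dox only, or
#' Dox+E2. Any other pattern is `unclassified` at this level.
#'
#' @param pattern Named logical vector (or one-row data frame) with the
#'   four condition flags of [build_presence()].
#' @return One of `nontreated_specific`, `E2_specific`, `Dox_specific`,
#'   `DoxE2_specific`, `unclassified`.
#' @export
classify_condition_specific <- function(pattern) {
  p <- presence_quad(pattern)
  if (sum(p) != 1L) return("unclassified")
  switch(names(p)[which(p)],
         dox_minus.e2_minus = "nontreated_specific",
         dox_minus.e2_plus = "E2_specific",
         dox_plus.e2_minus = "Dox_specific",
         dox_plus.e2_plus = "DoxE2_specific")
}

#' ERa-dependent group of a presence pattern
#'
#' Classifies regions that require ectopic ERa expression (Dox) into the
#' three ERa-dependent groups: `E2minus_ERa` (detected only under
#' Dox+/E2-), `E2plus_ERa` (only Dox+/E2+), and `E2ind_ERa` (both Dox+
#' conditions, neither Dox- condition). Regions present in any Dox-
#' condition are ERa-independent background and return `unclassified`.
#'
#' @inheritParams classify_condition_specific
#' @return One of `E2minus_ERa`, `E2plus_ERa`, `E2ind_ERa`,
#'   `unclassified`.
#' @export
classify_era_groups <- function(pattern) {
  p <- presence_quad(pattern)
  if (p[["dox_minus.e2_minus"]] || p[["dox_minus.e2_plus"]])
    return("unclassified")
  dm <- p[["dox_plus.e2_minus"]]
  dp <- p[["dox_plus.e2_plus"]]
  if (dm && dp) return("E2ind_ERa")
  if (dm) return("E2minus_ERa")
  if (dp) return("E2plus_ERa")
  "unclassified"
}

#' Classify every region of a presence table
#'
#' @param presence Output of [build_presence()].
#' @return The input with `condition_specific` and `era_group` columns
#'   appended.
#' @export
classify_presence_table <- function(presence) {
  n <- nrow(presence)
  cs <- character(n)
  eg <- character(n)
  for (i in seq_len(n)) {
    p <- presence_quad(presence[i, ])
    cs[i] <- classify_condition_specific(p)
    eg[i] <- classify_era_groups(p)
  }
  presence$condition_specific <- cs
  presence$era_group <- eg
  presence
}
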