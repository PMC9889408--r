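#' Sample coordinate of one peak set
#'
#' A `SampleKey` identifies one peak file in the clone x doxycycline x
#' estradiol x assay grid of an inducible ERa experiment.
#'
#' @param clone One of `"control"`, `"WT"`, `"Y537S"`, `"K303R"`.
#' @param dox Doxycycline status, `"plus"` or `"minus"` (Dox induces
#'   ectopic ERa expression).
#' @param e2 Estradiol status, `"plus"` or `"minus"`.
#' @param assay `"ATAC"` (open chromatin) or `"ChIP"` (ERa binding).
#' @return An object of class `SampleKey`.
#' @export
#' @examples
#' sample_key("WT", "plus", "minus", "ATAC")
sample_key <- function(clone, dox, e2, assay) {
  clone <- match.arg(clone, c("control", "WT", "Y537S", "K303R"))
  dox   <- match.arg(dox, c("plus", "minus"))
  e2    <- match.arg(e2, c("plus", "minus"))
  assay <- match.arg(assay, c("ATAC", "ChIP"))
  structure(list(clone = clone, dox = dox, e2 = e2, assay = assay),
            class = "SampleKey")
}

#' @export
format.SampleKey <- function(x, ...) {
  paste(x$clone, x$dox, x$e2, x$assay, sep = ".")
}

#' @export
print.SampleKey <- function(x, ...) {
  cat("<SampleKey>", format(x), "\n")
  invisible(x)
}

# Canonical empty interval table; coordinates are 0-based half-open.
empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
              name = character(), score = numeric(), summit = integer(),
              stringsAsFactors = FALSE)
}

validate_intervals <- function(df, context = "intervals") {
  needed <- c("chrom", "start", "end", "name")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop(context, ": missing column(s) ", paste(miss, collapse = ", "))
  if (!"score" %in% names(df)) df$score <- rep(NA_real_, nrow(df))
  if (!"summit" %in% names(df)) df$summit <- rep(NA_integer_, nrow(df))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$summit <- as.integer(df$summit)
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad))
    stop(context, ": invalid interval (need 0 <= start < end) at row ",
         bad[1], ": ", df$chrom[bad[1]], ":", df$start[bad[1]], "-",
         df$end[bad[1]])
  has_sum <- !is.na(df$summit)
  badsum <- which(has_sum & !(df$summit >= df$start & df$summit < df$end))
  if (length(badsum))
    stop(context, ": summit outside interval at row ", badsum[1])
  df[, c("chrom", "start", "end", "name", "score", "summit")]
}

#' Construct a PeakSet
#'
#' A `PeakSet` is a sorted collection of 0-based half-open genomic
#' intervals (peaks) with optional signal score and summit position,
#' tagged with the [sample_key()] it came from. Intervals with identical
#' coordinates are deduplicated with a warning; duplicate names are made
#' unique.
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`,
#'   `name` and optionally `score`, `summit` (absolute bp, 0-based).
#' @param sample A [sample_key()] (optional).
#' @return An object of class `PeakSet`: list with `sample` and sorted
#'   `intervals`.
#' @export
peak_set <- function(intervals = empty_intervals(), sample = NULL) {
  df <- validate_intervals(as.data.frame(intervals), "peak_set")
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "start", "end")])
  if (any(dup)) {
    warning("peak_set: dropped ", sum(dup),
            " interval(s) with duplicated coordinates")
    df <- df[!dup, , drop = FALSE]
  }
  if (anyDuplicated(df$name)) {
    warning("peak_set: duplicated names made unique")
    df$name <- make.unique(df$name)
  }
  rownames(df) <- NULL
  structure(list(sample = sample, intervals = df), class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat("<PeakSet>", if (!is.null(x$sample)) format(x$sample) else "(no sample)",
      "-", nrow(x$intervals), "intervals\n")
  invisible(x)
}

#' @export
length.PeakSet <- function(x) nrow(x$intervals)

# Internal: PeakSet/data.frame -> GRanges (1-based closed internally).
# Passing shared seqlevels avoids findOverlaps warnings on disjoint
# chromosome sets.
as_granges <- function(x, seqlevels = NULL) {
  df <- if (inherits(x, "PeakSet")) x$intervals else x
  if (is.null(seqlevels)) seqlevels <- unique(df$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    name = df$name)
}

#' Read a BED6 or narrowPeak file into a PeakSet
#'
#' narrowPeak (ENCODE, 10 columns) summit offsets (column 10) are
#' converted to absolute 0-based summit positions; offset -1 leaves the
#' summit unset. BED input uses the first 3-6 columns; missing names are
#' autogenerated.
#'
#' @param path Path to the peak file (plain text, tab-separated).
#' @param sample A [sample_key()] to attach (optional).
#' @param format `"bed6"` or `"narrowPeak"`.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, sample = NULL, format = c("bed6", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_peaks: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(peak_set(empty_intervals(), sample))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (format == "narrowPeak") 10L else 3L
  bad <- which(if (format == "narrowPeak") nf != 10L else nf < 3L)
  if (length(bad))
    stop("read_peaks: malformed row at line ", bad[1], " of ", path,
         " (", nf[bad[1]], " fields, expected ",
         if (format == "narrowPeak") "exactly 10" else ">= 3", ")")
  m <- matrix("", nrow = length(fields), ncol = max(nf, need))
  for (i in seq_along(fields)) m[i, seq_len(nf[i])] <- fields[[i]]
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  badnum <- which(is.na(start) | is.na(end))
  if (length(badnum))
    stop("read_peaks: non-numeric coordinates at line ", badnum[1],
         " of ", path)
  name <- if (max(nf) >= 4) m[, 4] else rep("", length(start))
  empty <- !nzchar(name) | name == "."
  name[empty] <- paste0("peak_", which(empty))
  score <- if (max(nf) >= 5) suppressWarnings(as.numeric(m[, 5])) else
    rep(NA_real_, length(start))
  summit <- rep(NA_integer_, length(start))
  if (format == "narrowPeak") {
    off <- suppressWarnings(as.integer(m[, 10]))
    badoff <- which(is.na(off))
    if (length(badoff))
      stop("read_peaks: malformed summit offset at line ", badoff[1],
           " of ", path)
    summit[off >= 0L] <- start[off >= 0L] + off[off >= 0L]
  }
  w <- which(start >= end)
  if (length(w))
    stop("read_peaks: start >= end at line ", w[1], " of ", path)
  peak_set(data.frame(chrom = m[, 1], start = start, end = end, name = name,
                      score = score, summit = summit,
                      stringsAsFactors = FALSE), sample)
}

#' Write a PeakSet as BED6
#'
#' Coordinates are written unchanged (0-based half-open); strand is always
#' `"."`; missing scores become 0.
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  df <- peaks$intervals
  sc <- ifelse(is.na(df$score), 0, df$score)
  lines <- if (nrow(df)) {
    paste(df$chrom, df$start, df$end, df$name,
          format(sc, trim = TRUE, scientific = FALSE), ".", sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Write a PeakSet as ENCODE narrowPeak
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  df <- peaks$intervals
  sc <- ifelse(is.na(df$score), 0, df$score)
  off <- ifelse(is.na(df$summit), -1L, df$summit - df$start)
  lines <- if (nrow(df)) {
    paste(df$chrom, df$start, df$end, df$name,
          format(sc, trim = TRUE, scientific = FALSE), ".",
          format(sc, trim = TRUE, scientific = FALSE), "-1", "-1", off,
          sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Flag query peaks overlapping any reference peak
#'
#' @param query,reference [peak_set()] objects (or interval data frames).
#' @param min_bp Minimum shared bases for an overlap to count (>= 1).
#' @return Logical vector, one flag per query interval, in query order.
#' @export
overlaps_any <- function(query, reference, min_bp = 1L) {
  min_bp <- as.integer(min_bp)
  if (is.na(min_bp) || min_bp < 1L) stop("overlaps_any: min_bp must be >= 1")
  qdf <- if (inherits(query, "PeakSet")) query$intervals else query
  rdf <- if (inherits(reference, "PeakSet")) reference$intervals else reference
  if (!nrow(qdf)) return(logical(0))
  if (!nrow(rdf)) return(rep(FALSE, nrow(qdf)))
  lev <- union(unique(qdf$chrom), unique(rdf$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges(qdf, lev),
                                      as_granges(rdf, lev),
                                      minoverlap = min_bp)
  out <- rep(FALSE, nrow(qdf))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Merge a list of PeakSets into their interval union
#'
#' Returns the minimal set of maximal intervals covering the union of all
#' inputs; intervals separated by at most `gap` bases are merged
#' (`gap = 0` merges overlapping and book-ended intervals).
#'
#' @param sets A list of [peak_set()] objects (or a single PeakSet).
#' @param gap Maximum separation (bp) still merged, default 0.
#' @return A [peak_set()] with autogenerated region names `region_i`.
#' @export
merge_union <- function(sets, gap = 0L) {
  if (inherits(sets, "PeakSet")) sets <- list(sets)
  if (!length(sets)) stop("merge_union: need at least one PeakSet")
  dfs <- lapply(sets, function(s)
    (if (inherits(s, "PeakSet")) s$intervals else s)[, c("chrom", "start", "end")])
  df <- do.call(rbind, dfs)
  if (!nrow(df)) return(peak_set(empty_intervals()))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = as.integer(gap) + 1L)
  red <- GenomicRanges::sort(red)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red),
                    stringsAsFactors = FALSE)
  out$name <- paste0("region_", seq_len(nrow(out)))
  peak_set(out)
}

#' Replace peaks by fixed windows around their summits
#'
#' Each interval becomes `[summit - flank, summit + flank)`, clipped to the
#' chromosome. Intervals without a recorded summit fall back to their
#' midpoint when `midpoint_fallback` is `TRUE`.
#'
#' @param peaks A [peak_set()].
#' @param flank Flank size in bp (> 0); e.g. 3000 for +/- 3 kb windows.
#' @param chrom_sizes Named integer vector or two-column data frame
#'   (chrom, size).
#' @param midpoint_fallback Use the interval midpoint when no summit is set.
#' @return A [peak_set()] of summit windows.
#' @export
summit_windows <- function(peaks, flank, chrom_sizes, midpoint_fallback = TRUE) {
  stopifnot(inherits(peaks, "PeakSet"))
  flank <- as.integer(flank)
  if (is.na(flank) || flank <= 0L) stop("summit_windows: flank must be > 0")
  if (is.data.frame(chrom_sizes))
    chrom_sizes <- stats::setNames(as.integer(chrom_sizes[[2]]),
                                   as.character(chrom_sizes[[1]]))
  df <- peaks$intervals
  if (!nrow(df)) return(peak_set(empty_intervals(), peaks$sample))
  unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("summit_windows: chromosome(s) not in chrom_sizes: ",
         paste(unknown, collapse = ", "))
  summit <- df$summit
  if (any(is.na(summit))) {
    if (!midpoint_fallback)
      stop("summit_windows: interval without summit and midpoint_fallback is FALSE")
    mid <- (df$start + df$end) %/% 2L
    summit[is.na(summit)] <- mid[is.na(summit)]
  }
  len <- chrom_sizes[df$chrom]
  start <- pmax(0L, summit - flank)
  end <- pmin(as.integer(len), summit + flank)
  keep <- start < end
  peak_set(data.frame(chrom = df$chrom[keep], start = start[keep],
                      end = end[keep], name = df$name[keep],
                      score = df$score[keep], summit = summit[keep],
                      stringsAsFactors = FALSE), peaks$sample)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Tab-separated file: chromosome name, length in bp.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  stats::setNames(df$size, df$chrom)
}
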