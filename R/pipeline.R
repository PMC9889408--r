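#' Assemble a pipeline run configuration
#'
#' @param sample_sheet TSV with columns `file`, `clone`, `dox`, `e2`,
#'   `assay` (paths relative to the sheet's directory).
#' @param genome Genome FASTA path.
#' @param motifs Motif library path (JASPAR text).
#' @param out_dir Output directory.
#' @param min_bp Overlap threshold for all presence/ACR gating.
#' @param threshold_fraction PWM hit threshold.
#' @param delta_min Differential-enrichment flag threshold (score scale).
#' @param ratio_min,rate_min Variable-motif rate filter (max/min ratio
#'   and minimal maximal rate).
#' @param p_max High-enrichment selection threshold on p-values.
#' @param flank Summit window flank (bp).
#' @param spacer ERE full-site spacer.
#' @param fox_motif,ere_motif Motif ids in the library used for the Fox
#'   co-occurrence analysis.
#' @param fox_clones The clone pair of the Fox analysis.
#' @return List of class `RunConfig`.
#' @export
run_config <- function(sample_sheet, genome, motifs, out_dir,
                       min_bp = 1L, threshold_fraction = 0.8,
                       delta_min = 10, ratio_min = 3, rate_min = 0.15,
                       p_max = 1e-20, flank = 3000L, spacer = 3L,
                       fox_motif = "FOX", ere_motif = "ERE_half",
                       fox_clones = c("WT", "K303R")) {
  for (p in c(sample_sheet, genome, motifs))
    if (!file.exists(p)) stop("run_config: no such file: ", p)
  stopifnot(min_bp >= 1, threshold_fraction > 0, threshold_fraction <= 1,
            ratio_min > 0, rate_min > 0, p_max > 0, flank > 0)
  structure(as.list(environment()), class = "RunConfig")
}

sheet_key <- function(row) {
  format(sample_key(row$clone, row$dox, row$e2, row$assay))
}

read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  base <- dirname(path)
  peaks <- list()
  for (i in seq_len(nrow(sheet))) {
    key <- sample_key(sheet$clone[i], sheet$dox[i], sheet$e2[i],
                      sheet$assay[i])
    fp <- sheet$file[i]
    if (!file.exists(fp)) fp <- file.path(base, sheet$file[i])
    fmt <- if (grepl("narrowPeak$", fp)) "narrowPeak" else "bed6"
    peaks[[format(key)]] <- read_peaks(fp, key, format = fmt)
  }
  peaks
}

need_sample <- function(peaks, clone, dox, e2, assay) {
  key <- format(sample_key(clone, dox, e2, assay))
  if (is.null(peaks[[key]]))
    stop("run_pipeline: required sample missing from sheet: ", key)
  peaks[[key]]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the integration pipeline end to end
#'
#' Stages: `groups` (condition-specific / ERa-dependent classification of
#' each clone's ATAC consensus), `acr` (ERa-ACR definition and tri-clone
#' partition per Dox+ condition), `enrich` (motif enrichment of the
#' ERa-dependent ATAC groups against the clone consensus, with
#' differential tables vs WT), `fox` (Fox co-occurrence report for the
#' configured clone pair), `pca` (presence-matrix PCA over all ATAC
#' samples). All stages are deterministic given the config; every
#' reported fraction is accompanied by its numerator and denominator.
#'
#' @param config A [run_config()].
#' @param stages Character subset of
#'   `c("groups", "acr", "enrich", "fox", "pca")`.
#' @return Invisibly, a list of in-memory stage results; files are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config,
                         stages = c("groups", "acr", "enrich", "fox",
                                    "pca")) {
  stopifnot(inherits(config, "RunConfig"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  peaks <- read_sample_sheet(config$sample_sheet)
  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  motifs <- load_motifs(config$motifs, format = "jaspar")
  clones <- intersect(ERA_CLONES,
                      unique(vapply(peaks, function(p) p$sample$clone, "")))
  res <- list()

  if ("groups" %in% stages) {
    res$groups <- list()
    for (cl in clones) {
      conds <- list()
      for (dox in c("minus", "plus"))
        for (e2 in c("minus", "plus"))
          conds[[condition_id(dox, e2)]] <-
            need_sample(peaks, cl, dox, e2, "ATAC")
      consensus <- merge_union(conds)
      tab <- classify_presence_table(
        build_presence(consensus, conds, min_bp = config$min_bp))
      write_tsv(tab, file.path(config$out_dir,
                               paste0("groups_", cl, "_ATAC.tsv")))
      res$groups[[cl]] <- tab
    }
  }

  if (any(c("acr", "enrich") %in% stages)) {
    res$acr <- list()
    for (e2 in c("minus", "plus")) {
      acr_by_clone <- list()
      for (cl in clones)
        acr_by_clone[[cl]] <- define_acr(
          need_sample(peaks, cl, "plus", e2, "ChIP"),
          need_sample(peaks, cl, "plus", e2, "ATAC"),
          min_bp = config$min_bp)
      part <- partition_clone_specificity(acr_by_clone,
                                          min_bp = config$min_bp)
      for (cl in clones) part[[cl]]$clone <- cl
      tab <- do.call(rbind, part)
      tab$condition <- paste0("e2_", e2)
      write_tsv(tab, file.path(config$out_dir,
                               paste0("acr_e2_", e2, ".tsv")))
      res$acr[[paste0("e2_", e2)]] <- list(sets = acr_by_clone,
                                           partition = part)
    }
  }

  if ("enrich" %in% stages) {
    if (is.null(res$groups))
      stop("run_pipeline: 'enrich' needs the 'groups' stage")
    enr <- list()
    for (cl in clones) {
      tab <- res$groups[[cl]]
      seqs <- peak_sequences(genome, tab)
      flags <- vapply(motifs, function(m)
        scan_presence(seqs, m, config$threshold_fraction),
        logical(length(seqs)))
      rownames(flags) <- tab$name
      rows <- do.call(rbind, lapply(
        c("E2minus_ERa", "E2plus_ERa", "E2ind_ERa"), function(g)
          cbind(clone = cl,
                enrichment_table(flags, tab$name[tab$era_group == g], g))))
      enr[[cl]] <- rows
    }
    enrich <- do.call(rbind, enr)
    write_tsv(enrich, file.path(config$out_dir, "enrichment_ATAC.tsv"))
    diffs <- list()
    if ("WT" %in% clones) {
      for (cl in setdiff(clones, "WT")) {
        for (g in unique(enr[[cl]]$group_id)) {
          d <- differential_enrichment(
            enr[[cl]][enr[[cl]]$group_id == g, c("motif_id", "score")],
            enr[["WT"]][enr[["WT"]]$group_id == g, c("motif_id", "score")],
            delta_min = config$delta_min)
          diffs[[paste(cl, g)]] <- cbind(clone = cl, group_id = g, d)
        }
      }
      write_tsv(do.call(rbind, diffs),
                file.path(config$out_dir, "differential_motifs.tsv"))
    }
    res$enrichment <- enrich
    res$differential <- diffs
  }

  if ("fox" %in% stages) {
    fc <- config$fox_clones
    chip <- stats::setNames(lapply(fc, function(cl)
      need_sample(peaks, cl, "plus", "plus", "ChIP")), fc)
    atac <- stats::setNames(lapply(fc, function(cl)
      need_sample(peaks, cl, "plus", "plus", "ATAC")), fc)
    fr <- fox_report(chip, atac, genome,
                      fox_pwm = motifs[[config$fox_motif]],
                      ere_pwm = motifs[[config$ere_motif]],
                      threshold_fraction = config$threshold_fraction,
                      spacer = config$spacer, min_bp = config$min_bp)
    jsonlite::write_json(
      list(fractions = fr$fractions,
           sharing = as.list(fr$sharing),
           max_sharing = fr$max_sharing,
           opening = fr$opening),
      file.path(config$out_dir, "fox_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$fox <- fr
  }

  if ("pca" %in% stages) {
    atac <- peaks[vapply(peaks, function(p)
      p$sample$assay == "ATAC", logical(1))]
    pm <- build_presence_matrix(atac, mode = "binary",
                                min_bp = config$min_bp)
    pca <- pca_project(pm, n_components = min(5L, length(atac)))
    coords <- data.frame(sample = rownames(pca$coordinates),
                         pca$coordinates, stringsAsFactors = FALSE)
    write_tsv(coords, file.path(config$out_dir, "pca_coordinates.tsv"))
    res$pca <- pca
  }

  cfg_txt <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")])), collapse = "\n")
  tmp <- tempfile()
  writeLines(cfg_txt, tmp)
  prov <- list(package = "eracr",
               version = as.character(utils::packageVersion("eracr")),
               r_version = R.version.string,
               config_md5 = unname(tools::md5sum(tmp)),
               timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tmp)
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
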