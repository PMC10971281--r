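## End-to-end driver: support filter -> caller merge -> gap/centromere and
## germline filters -> cross-technology matching -> translocation
## reclassification -> breakpoint resolution -> fusion triangulation,
## writing audit TSVs and a run manifest.

.required_inputs <- c("lumpy_vcf", "delly_vcf", "ogm_smap", "repeats_bed",
                      "gaps_bed", "centromeres_bed", "sparse_bed",
                      "genes_bed", "control_db", "rna_fusions")

#' Assemble (or load) a run configuration
#'
#' @param config named list of input paths and options, or the path of a
#'   YAML file holding one. Required entries: `lumpy_vcf`, `delly_vcf`,
#'   `ogm_smap`, `repeats_bed`, `gaps_bed`, `centromeres_bed`,
#'   `sparse_bed`, `genes_bed`, `control_db`, `rna_fusions`; optional:
#'   `control_calls`, `known_fusions`, `out_dir`, `sample`, and a
#'   `thresholds` sub-list of overrides.
#' @param ... overrides applied on top.
#' @return Validated config list (class `RunConfig`).
#' @export
runConfig <- function(config, ...) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  over <- list(...)
  config[names(over)] <- over
  miss <- setdiff(.required_inputs, names(config))
  if (length(miss)) {
    stop("run config missing input(s): ", paste(miss, collapse = ", "))
  }
  for (f in c(.required_inputs,
              intersect(c("control_calls", "known_fusions"),
                        names(config)))) {
    if (!file.exists(config[[f]])) {
      stop("input file for '", f, "' not found: ", config[[f]])
    }
  }
  if (is.null(config$out_dir)) config$out_dir <- "svtriangulate_out"
  config$thresholds <- do.call(svThresholds,
                               as.list(config$thresholds %||% list()))
  class(config) <- c("RunConfig", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full integration pipeline
#'
#' Executes every stage on the configured inputs and writes the audit
#' outputs into `out_dir`: `merged_wgs.tsv` (post-filter WGS consensus),
#' `integrated_calls.tsv` (final somatic set: OGM-confirmed calls, WGS-only
#' calls with translocation reclassifications applied, OGM-only calls),
#' `matches.tsv`, `reclassification.tsv`, `resolution_report.tsv`,
#' `breakend_labels.tsv`, `fusion_matrix.tsv`, `concordance.tsv`,
#' `size_report.tsv` and `manifest.yaml`. Outputs are deterministic for
#' fixed inputs.
#'
#' @param config a [runConfig()] list (or anything it accepts).
#' @return Invisibly, a list with the stage objects (`wgs`, `ogm`,
#'   `match`, `reclass`, `resolution`, `fusions`, `concordance`,
#'   `size_report`, `manifest`).
#' @export
runPipeline <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else runConfig(config)
  th <- cfg$thresholds
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_counts <- list()

  ## stage 1: ingest
  lumpy <- readWgsVcf(cfg$lumpy_vcf, "lumpy", sample = cfg$sample)
  delly <- readWgsVcf(cfg$delly_vcf, "delly", sample = cfg$sample)
  ogm <- readOgmSmap(cfg$ogm_smap, sample = sampleName(lumpy))
  tracks <- readResourceTracks(repeats = cfg$repeats_bed,
                               gaps = cfg$gaps_bed,
                               centromeres = cfg$centromeres_bed,
                               sparse = cfg$sparse_bed,
                               genes = cfg$genes_bed)
  db <- readControlDb(cfg$control_db)
  ctrl_calls <- if (!is.null(cfg$control_calls)) {
    readIntegratedTsv(cfg$control_calls)
  } else NULL
  rna <- readFusionTable(cfg$rna_fusions)
  known <- if (!is.null(cfg$known_fusions)) {
    readLines(cfg$known_fusions)
  } else NULL
  stage_counts$ingest <- c(lumpy = length(lumpy), delly = length(delly),
                           ogm = length(ogm))

  ## stage 2: support filter
  lumpy <- filterSupport(lumpy, th)
  delly <- filterSupport(delly, th)
  stage_counts$support_filter <- c(lumpy = length(lumpy),
                                   delly = length(delly))

  ## stage 3: dual-caller merge
  wgs <- mergeCallers(lumpy, delly, th)
  stage_counts$merge <- c(merged = length(wgs))

  ## stage 4: gap/centromere filter
  wgs <- filterGapCentromere(wgs, tracks, th)
  stage_counts$gap_filter <- c(kept = length(wgs))

  ## stage 5: germline filter (both technologies)
  wgs <- filterGermline(wgs, db, th, control_calls = ctrl_calls)
  ogm <- filterGermline(ogm, db, th, control_calls = ctrl_calls)
  stage_counts$germline_filter <- c(wgs = length(wgs), ogm = length(ogm))
  writeIntegratedTsv(wgs, file.path(cfg$out_dir, "merged_wgs.tsv"), th)

  ## stage 6: cross-technology matching
  mt <- matchCrossTech(wgs, ogm, th)
  stage_counts$cross_tech <- c(matches = nrow(mt$matches),
                               wgs_only = length(mt$wgs_only),
                               ogm_only = length(mt$ogm_only))
  utils::write.table(mt$matches, file.path(cfg$out_dir, "matches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 7: translocation -> insertion reclassification
  rc <- reclassifyTraToIns(mt$wgs_only, ogm, th)
  stage_counts$reclassify <- c(reclassified = nrow(rc$reclassified))
  utils::write.table(rc$audit,
                     file.path(cfg$out_dir, "reclassification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  wgs_only_cl <- svCalls(mt$wgs_only)
  wgs_only_final <- rbind(
    wgs_only_cl[!wgs_only_cl$id %in% rc$audit$tra_id, , drop = FALSE],
    rc$reclassified)
  ogm_only_cl <- svCalls(mt$ogm_only)
  integrated <- setCalls(wgs, rbind(svCalls(mt$reported), wgs_only_final,
                                    ogm_only_cl))
  writeIntegratedTsv(integrated,
                     file.path(cfg$out_dir, "integrated_calls.tsv"), th)

  ## stage 8: unsupported-breakpoint resolution
  uns <- wgs_only_cl
  bnds <- data.frame(
    id = c(paste0(uns$id, "_1"), paste0(uns$id, "_2")),
    call_id = c(uns$id, uns$id),
    chrom = c(uns$chrom1, uns$chrom2),
    pos = c(uns$pos1, uns$pos2),
    is_tra = rep(uns$svtype == "TRA", 2L),
    support = rep(uns$support_sr + uns$support_pe, 2L),
    stringsAsFactors = FALSE)
  res <- categorizeBreakpoints(bnds, tracks, ogm, th)
  writeResolutionReport(res$table,
                        file.path(cfg$out_dir, "resolution_report.tsv"),
                        th)
  utils::write.table(res$labels,
                     file.path(cfg$out_dir, "breakend_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_counts$resolution <- c(total = res$table@total,
                               unexplained =
                                 res$table@counts[["UNEXPLAINED"]])

  ## stage 9: fusion triangulation
  wgs_fus <- candidateFusionsFromSv(integrated[
    svCalls(integrated)$source != "OGM", drop = FALSE], tracks$genes)
  ogm_fus <- candidateFusionsFromSv(ogm, tracks$genes)
  ev <- integrateFusionEvidence(wgs_fus, ogm_fus, rna, known, th)
  if (nrow(ev)) {
    put <- markPutative(
      data.frame(ev[, c("gene_a", "gene_b", "chrom_a", "pos_a", "chrom_b",
                        "pos_b", "sample")],
                 sv_id = NA, svtype = NA, technology = "WGS",
                 orientation_compatible = ev$orientation_compatible,
                 flags = ev$flags, stringsAsFactors = FALSE),
      tracks$repeats,
      ogm_support = ev$ogm_support, rna_support = ev$rna_support)
    ev$flags <- put$flags
  }
  writeFusionMatrix(ev, file.path(cfg$out_dir, "fusion_matrix.tsv"), th)
  stage_counts$fusions <- c(candidates = nrow(ev),
                            dual = sum(ev$dual_confirmed),
                            triple = sum(ev$dual_confirmed &
                                         ev$rna_support))

  ## reports
  conc <- concordanceSummary(mt$matches, wgs, ogm)
  utils::write.table(conc$per_type,
                     file.path(cfg$out_dir, "concordance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  szr <- sizeDistributionReport(wgs, ogm)
  utils::write.table(szr$bands, file.path(cfg$out_dir, "size_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "svtriangulate",
    version = as.character(utils::packageVersion("svtriangulate")),
    sample = sampleName(wgs),
    thresholds = thresholdList(th),
    stages = lapply(stage_counts, as.list)
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))

  invisible(list(wgs = wgs, ogm = ogm, match = mt, reclass = rc,
                 integrated = integrated, resolution = res, fusions = ev,
                 concordance = conc, size_report = szr,
                 manifest = manifest))
}

.SIZE_BANDS <- c(0, 500, 1e3, 1e4, 1e5, 1e6, Inf)
.SIZE_BAND_LABELS <- c("<0.5kb", "0.5-1kb", "1-10kb", "10-100kb",
                       "100kb-1Mb", ">=1Mb")

#' Deletion size distributions by technology
#'
#' Reports per-technology deletion size medians, counts per size band, and
#' a Wilcoxon rank-sum test comparing the two size distributions. With
#' fewer than two sizes in either group the test is skipped with a notice.
#'
#' @param wgs,ogm [SVCallSet-class] objects.
#' @return List with `medians` (named numeric), `bands` (data.frame),
#'   `p_value` (`NA` when skipped) and `note`.
#' @export
sizeDistributionReport <- function(wgs, ogm) {
  szs <- function(cs) {
    cl <- svCalls(cs)
    cl$length[cl$svtype == "DEL" & !is.na(cl$length)]
  }
  w <- szs(wgs); o <- szs(ogm)
  bands <- data.frame(
    band = .SIZE_BAND_LABELS,
    wgs = as.integer(table(cut(w, .SIZE_BANDS, labels = .SIZE_BAND_LABELS,
                               right = FALSE))),
    ogm = as.integer(table(cut(o, .SIZE_BANDS, labels = .SIZE_BAND_LABELS,
                               right = FALSE))),
    stringsAsFactors = FALSE)
  medians <- c(wgs = stats::median(w), ogm = stats::median(o))
  if (length(w) < 2 || length(o) < 2) {
    return(list(medians = medians, bands = bands, p_value = NA_real_,
                note = "rank-sum test skipped: fewer than 2 sizes per group"))
  }
  p <- suppressWarnings(stats::wilcox.test(w, o))$p.value
  list(medians = medians, bands = bands, p_value = p, note = "")
}
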