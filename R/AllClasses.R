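#' @import methods
#' @importFrom S4Vectors metadata
NULL

## Column schema shared by every call table. Coordinates are 0-based
## half-open throughout the package; VCF/SMAP 1-based coordinates are
## converted at the I/O boundary.
.CALL_COLUMNS <- c(
  "id", "svtype", "chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
  "length", "support_sr", "support_pe", "support_mol", "source", "sample",
  "flags"
)

.SV_TYPES <- c("DEL", "DUP", "INS", "INV", "TRA")
.INTRA_TYPES <- c("DEL", "DUP", "INS", "INV")
.SOURCES <- c("LUMPY", "DELLY", "WGS_MERGED", "OGM", "RNA")

#' Container for a per-sample, per-technology set of structural variant calls
#'
#' An `SVCallSet` holds one sample's calls from one technology as a
#' data.frame with a fixed column schema, plus free-form metadata (merge and
#' filter audit tables, thresholds in effect, ...). Coordinates are 0-based
#' half-open. Intra-chromosomal calls (DEL, DUP, INS, INV) keep
#' `chrom1 == chrom2` and `pos1 <= pos2`; translocations (TRA) join two
#' breakends on different chromosomes (or carry an `INTRA_REARR` flag).
#' `length` is `NA` when unknown (WGS insertions). `flags` is a
#' comma-separated label string (e.g. `RECLASSIFIED_FROM_TRA`).
#'
#' @slot sample sample identifier (length-1 character).
#' @slot technology one of `"WGS"`, `"OGM"`, `"RNA"`.
#' @slot calls data.frame with columns `id, svtype, chrom1, pos1, strand1,
#'   chrom2, pos2, strand2, length, support_sr, support_pe, support_mol,
#'   source, sample, flags`.
#' @slot metadata named list of auxiliary objects.
#' @exportClass SVCallSet
setClass("SVCallSet",
  representation(
    sample = "character",
    technology = "character",
    calls = "data.frame",
    metadata = "list"
  ),
  prototype(sample = NA_character_, technology = "WGS", metadata = list())
)

setValidity("SVCallSet", function(object) {
  msgs <- character()
  if (length(object@technology) != 1L ||
      !object@technology %in% c("WGS", "OGM", "RNA")) {
    msgs <- c(msgs, "technology must be one of WGS, OGM, RNA")
  }
  cl <- object@calls
  miss <- setdiff(.CALL_COLUMNS, names(cl))
  if (length(miss)) {
    return(paste("calls is missing columns:", paste(miss, collapse = ", ")))
  }
  if (nrow(cl)) {
    if (anyDuplicated(cl$id)) msgs <- c(msgs, "call ids must be unique")
    if (!all(cl$svtype %in% .SV_TYPES)) {
      msgs <- c(msgs, "svtype must be one of DEL, DUP, INS, INV, TRA")
    }
    if (!all(cl$sample == cl$sample[1L])) {
      msgs <- c(msgs, "all calls must share one sample id")
    }
    if (any(cl$pos1 < 0, na.rm = TRUE) || any(cl$pos2 < 0, na.rm = TRUE)) {
      msgs <- c(msgs, "breakend positions must be >= 0")
    }
    if (!all(cl$strand1 %in% c("+", "-")) ||
        !all(cl$strand2 %in% c("+", "-"))) {
      msgs <- c(msgs, "strands must be '+' or '-'")
    }
    intra <- cl$svtype %in% .INTRA_TYPES
    if (any(intra & cl$chrom1 != cl$chrom2)) {
      msgs <- c(msgs, "intra-chromosomal calls must have chrom1 == chrom2")
    }
    if (any(intra & cl$pos1 > cl$pos2)) {
      msgs <- c(msgs, "intra-chromosomal calls must have pos1 <= pos2")
    }
    tra <- cl$svtype == "TRA"
    if (any(tra)) {
      same <- cl$chrom1[tra] == cl$chrom2[tra]
      flagged <- grepl("INTRA_REARR", cl$flags[tra])
      if (any(same & !flagged)) {
        msgs <- c(msgs,
          "TRA on one chromosome must carry the INTRA_REARR flag")
      }
    }
    ## Coordinate-span consistency is a WGS-side guarantee. OGM spans
    ## bracket the junction at flanking labels, so the label-derived
    ## length may legitimately differ from pos2 - pos1.
    spanchk <- intra & cl$svtype != "INS" & !is.na(cl$length) &
      cl$source %in% c("LUMPY", "DELLY", "WGS_MERGED")
    if (any(spanchk & cl$length != cl$pos2 - cl$pos1)) {
      msgs <- c(msgs, "WGS DEL/DUP/INV length must equal pos2 - pos1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Numeric rules of the integration pipeline
#'
#' Every threshold used by the consensus, filtering, matching and
#' triangulation steps, collected in one validated object so a run is fully
#' described by its thresholds. Defaults are the published rules:
#' SVs < 50 bp dropped; >= 3 split reads (SR) or >= 3 paired-end reads (PE)
#' per call and >= 5 total reads per translocation; deletion caller-merge at
#' reciprocal overlap (RO) >= 0.5 and inversion merge at RO >= 0.9;
#' translocation merge within +/- 50 bp with matching strands; cross-technology
#' breakend window +/- 500 kb; translocation-to-insertion window 100 kb; the
#' OGM deletion size must be 80-120% of the WGS size; control-database hits
#' need > 50% overlap, > 70% size similarity and >= 5 individuals; LUMPY
#' translocation false-positive rate 0.14; >= 16 RNA reads support a fusion;
#' gap filter pads gaps by 50 bp and uses RO >= 0.5; OGM resolves >= 500 bp.
#'
#' @slot values named numeric vector of thresholds.
#' @exportClass SVThresholds
setClass("SVThresholds", representation(values = "numeric"))

.THRESHOLD_DEFAULTS <- c(
  min_sv_size = 50, min_sr = 3, min_pe = 3, min_tra_reads = 5,
  del_ro = 0.5, inv_ro = 0.9, tra_bnd_window = 50,
  cross_tech_window = 500000, tra_ins_window = 100000,
  size_ratio_low = 0.8, size_ratio_high = 1.2,
  ctrl_overlap = 0.5, ctrl_size_sim = 0.7, ctrl_min_individuals = 5,
  lumpy_tra_fp_rate = 0.14, rna_min_reads = 16,
  gap_pad = 50, gap_ro = 0.5, ogm_min_size = 500,
  large_intra_min = 50000
)

setValidity("SVThresholds", function(object) {
  v <- object@values
  miss <- setdiff(names(.THRESHOLD_DEFAULTS), names(v))
  if (length(miss)) {
    return(paste("missing thresholds:", paste(miss, collapse = ", ")))
  }
  fracs <- c("del_ro", "inv_ro", "size_ratio_low", "ctrl_overlap",
             "ctrl_size_sim", "lumpy_tra_fp_rate", "gap_ro")
  msgs <- character()
  if (any(v[fracs] < 0 | v[fracs] > 1)) {
    msgs <- c(msgs, "fractional thresholds must lie in [0, 1]")
  }
  sizes <- c("min_sv_size", "tra_bnd_window", "cross_tech_window",
             "tra_ins_window", "gap_pad", "ogm_min_size", "large_intra_min")
  if (any(v[sizes] < 0)) msgs <- c(msgs, "windows and sizes must be >= 0")
  if (v["size_ratio_high"] < v["size_ratio_low"]) {
    msgs <- c(msgs, "size_ratio_high must be >= size_ratio_low")
  }
  if (length(msgs)) msgs else TRUE
})

#' Partition of unsupported WGS breakpoints into explanation categories
#'
#' Produced by [categorizeBreakpoints()] (or [resolutionTableFromCounts()]).
#' The categories are mutually exclusive and sum to `total`:
#' `SPARSE_LABEL` (breakend in a sparsely labeled / label-gap region),
#' `REPEAT` (on a repeat element), `OGM_INS` (within the
#' translocation-insertion window of an OGM insertion), `OGM_DUP`, `OGM_DEL`
#' (overlapping an OGM duplication or deletion), `EST_FP` (share allocated to
#' the caller's translocation false-positive rate) and `UNEXPLAINED`.
#'
#' @slot total number of breakpoints partitioned.
#' @slot counts named integer vector over the seven categories.
#' @exportClass ResolutionTable
setClass("ResolutionTable",
  representation(total = "integer", counts = "integer"))

.RESOLUTION_CATEGORIES <- c("SPARSE_LABEL", "REPEAT", "OGM_INS", "OGM_DUP",
                            "OGM_DEL", "EST_FP", "UNEXPLAINED")

setValidity("ResolutionTable", function(object) {
  if (!identical(names(object@counts), .RESOLUTION_CATEGORIES)) {
    return("counts must be named by the seven resolution categories")
  }
  if (any(object@counts < 0)) return("category counts must be >= 0")
  if (sum(object@counts) != object@total) {
    return("category counts must sum to total")
  }
  TRUE
})
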