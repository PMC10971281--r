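## Resolution of WGS breakpoints unsupported by OGM: a sequential,
## mutually exclusive categorization. Precedence: sparse-label/gap region,
## then repeat overlap, then proximity to an OGM insertion, then overlap
## with an OGM duplication, then an OGM deletion; a floor(rate x remaining)
## share of what is left is attributed to the caller's translocation
## false-positive rate; the rest is unexplained.

.inTrack <- function(chrom, pos, track) {
  if (!nrow(track)) return(rep(FALSE, length(chrom)))
  gr <- intervalsAsGRanges(track)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
  suppressWarnings(IRanges::overlapsAny(q, gr))
}

.newResolutionTable <- function(counts) {
  counts <- as.integer(counts)
  names(counts) <- .RESOLUTION_CATEGORIES
  new("ResolutionTable", total = sum(counts), counts = counts)
}

#' Categorize unsupported WGS breakpoints
#'
#' Assigns each breakend exactly one explanation category under the fixed
#' precedence described in [ResolutionTable-class]. The false-positive
#' allocation is `floor(lumpy_tra_fp_rate x remaining)` breakends taken from
#' the still-unexplained pool; for per-breakend labels those are drawn from
#' translocation breakends with the lowest total read support first (ties in
#' genomic order), since the quoted rate is specific to translocation calls.
#'
#' @param bnds data.frame of breakends with columns `chrom`, `pos` and
#'   optionally `id`, `call_id`, `is_tra` (logical), `support` (total reads).
#' @param tracks a `ResourceTracks` list (needs `sparse` and `repeats`).
#' @param ogm an [SVCallSet-class] of OGM calls (may be empty).
#' @param th an [SVThresholds-class]; uses `tra_ins_window` and
#'   `lumpy_tra_fp_rate`.
#' @return List with `table` (a [ResolutionTable-class]) and `labels`
#'   (the input breakends with a `category` column).
#' @export
categorizeBreakpoints <- function(bnds, tracks, ogm = SVCallSet(),
                                  th = svThresholds()) {
  n <- nrow(bnds)
  if (!n) {
    return(list(table = .newResolutionTable(rep(0L, 7)),
                labels = cbind(bnds, category = character(0))))
  }
  if (is.null(bnds$id)) bnds$id <- paste0("b", seq_len(n))
  if (is.null(bnds$is_tra)) bnds$is_tra <- rep(FALSE, n)
  if (is.null(bnds$support)) bnds$support <- rep(0L, n)
  cat <- rep(NA_character_, n)

  ## one query object for every membership test
  q <- GenomicRanges::GRanges(bnds$chrom,
                              IRanges::IRanges(bnds$pos + 1, bnds$pos + 1))
  hit <- function(track) {
    if (!nrow(track)) return(rep(FALSE, n))
    suppressWarnings(IRanges::overlapsAny(q, intervalsAsGRanges(track)))
  }

  cat[hit(tracks$sparse)] <- "SPARSE_LABEL"
  open <- is.na(cat)
  cat[open & hit(tracks$repeats)] <- "REPEAT"

  ocl <- svCalls(ogm)
  ogm_track <- function(type, pad = 0) {
    sel <- ocl[ocl$svtype == type, , drop = FALSE]
    if (!nrow(sel)) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric()))
    }
    end <- ifelse(sel$svtype == "INS", sel$pos1 + 1, sel$pos2)
    data.frame(chrom = sel$chrom1, start = pmax(sel$pos1 - pad, 0),
               end = end + pad)
  }
  open <- is.na(cat)
  cat[open & hit(ogm_track("INS", pad = th["tra_ins_window"]))] <-
    "OGM_INS"
  open <- is.na(cat)
  cat[open & hit(ogm_track("DUP"))] <- "OGM_DUP"
  open <- is.na(cat)
  cat[open & hit(ogm_track("DEL"))] <- "OGM_DEL"

  remaining <- which(is.na(cat))
  n_fp <- floor(th["lumpy_tra_fp_rate"] * length(remaining))
  if (n_fp > 0) {
    pool <- bnds[remaining, , drop = FALSE]
    ord <- order(!pool$is_tra, pool$support, pool$chrom, pool$pos)
    cat[remaining[ord[seq_len(n_fp)]]] <- "EST_FP"
  }
  cat[is.na(cat)] <- "UNEXPLAINED"

  counts <- table(factor(cat, levels = .RESOLUTION_CATEGORIES))
  list(table = .newResolutionTable(counts),
       labels = cbind(bnds, category = cat))
}

#' Build a ResolutionTable directly from stage counts
#'
#' Desk-calculation entry point: given the total and the counts absorbed by
#' the sparse-label, repeat and OGM-overlap stages, allocates
#' `floor(fp_rate x remaining)` to estimated false positives and the rest to
#' unexplained.
#' @param total total unsupported breakpoints.
#' @param sparse,repeats,ogm_ins,ogm_dup,ogm_del per-stage counts.
#' @param fp_rate translocation false-positive rate applied to the
#'   remainder.
#' @return A [ResolutionTable-class].
#' @examples
#' tab <- resolutionTableFromCounts(1408, 17, 747, 74, 2, 2)
#' explainedFraction(tab)  # 0.654...
#' @export
resolutionTableFromCounts <- function(total, sparse, repeats, ogm_ins,
                                      ogm_dup, ogm_del, fp_rate = 0.14) {
  used <- sparse + repeats + ogm_ins + ogm_dup + ogm_del
  if (used > total) stop("stage counts exceed total")
  remaining <- total - used
  est_fp <- floor(fp_rate * remaining)
  .newResolutionTable(c(sparse, repeats, ogm_ins, ogm_dup, ogm_del,
                        est_fp, remaining - est_fp))
}

#' Fraction of unsupported breakpoints explained by the cascade
#' @param tab a [ResolutionTable-class].
#' @return `(total - UNEXPLAINED) / total`.
#' @export
explainedFraction <- function(tab) {
  if (tab@total == 0) stop("explainedFraction undefined for an empty table")
  (tab@total - tab@counts[["UNEXPLAINED"]]) / tab@total
}

#' @describeIn categorizeBreakpoints category counts accessor.
#' @param tab a `ResolutionTable`.
#' @export
resolutionCounts <- function(tab) tab@counts

#' Coerce a ResolutionTable to a data.frame (category, count, percent)
#' @param x a `ResolutionTable`.
#' @param ... ignored.
#' @export
as.data.frame.ResolutionTable <- function(x, ...) {
  data.frame(category = names(x@counts), count = as.integer(x@counts),
             percent = if (x@total) round(100 * x@counts / x@total, 1)
               else rep(0, length(x@counts)),
             row.names = NULL, stringsAsFactors = FALSE)
}

setMethod("show", "ResolutionTable", function(object) {
  cat(sprintf("ResolutionTable: %d breakpoints, %.1f%% explained\n",
              object@total,
              if (object@total) 100 * explainedFraction(object) else 0))
  print(as.data.frame(object))
})
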