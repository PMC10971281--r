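#' Reciprocal overlap of two genomic intervals
#'
#' RO = min(shared / length(a), shared / length(b)), the symmetric overlap
#' stringency used for caller merging and germline screening. Intervals are
#' 0-based half-open; intervals on different chromosomes have RO 0.
#'
#' @param chrom_a,start_a,end_a first interval (vectors recycle).
#' @param chrom_b,start_b,end_b second interval.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' reciprocalOverlap("chr1", 0, 100, "chr1", 50, 150)  # 0.5
#' @export
reciprocalOverlap <- function(chrom_a, start_a, end_a,
                              chrom_b, start_b, end_b) {
  la <- end_a - start_a
  lb <- end_b - start_b
  if (any(la <= 0) || any(lb <= 0)) {
    stop("reciprocalOverlap: zero-length or inverted interval")
  }
  ov <- pmin(end_a, end_b) - pmax(start_a, start_b)
  ov <- pmax(ov, 0)
  ov[chrom_a != chrom_b] <- 0
  pmin(ov / la, ov / lb)
}

#' Size similarity of two SV lengths
#'
#' min(a, b) / max(a, b); used with the control-database rule
#' "> 70% similar in size".
#' @param len_a,len_b lengths in bp (> 0; vectors recycle).
#' @return Fractions in \[0, 1\].
#' @export
sizeSimilarity <- function(len_a, len_b) {
  if (any(len_a <= 0) || any(len_b <= 0)) {
    stop("sizeSimilarity: lengths must be > 0")
  }
  pmin(len_a, len_b) / pmax(len_a, len_b)
}

#' Is an OGM size within the accepted ratio band of the WGS size?
#'
#' The OGM deletion size must be 80-120% of the WGS size (bounds inclusive)
#' for a cross-technology deletion match.
#' @param ogm_len,wgs_len lengths in bp (> 0).
#' @param th an [SVThresholds-class] object.
#' @return Logical vector.
#' @export
sizeRatioOk <- function(ogm_len, wgs_len, th = svThresholds()) {
  if (any(ogm_len <= 0) || any(wgs_len <= 0)) {
    stop("sizeRatioOk: lengths must be > 0")
  }
  r <- ogm_len / wgs_len
  r >= th["size_ratio_low"] & r <= th["size_ratio_high"]
}

#' Canonical strand-pair assignment per SV type
#'
#' Strand convention: `+` marks a breakpoint at the 3' end of the joined arm
#' (the retained segment lies at lower coordinates), `-` at the 5' end.
#' Deletions are `+-`, inversions `++` or `--`, duplications `-+`,
#' unclassified intra-chromosomal rearrangements `++`/`--`. OGM natively
#' reports deletions (`+-`) and inversions (`++`/`--`). Translocations keep
#' the caller-reported pair, so every pair is admissible.
#'
#' @param svtype one of DEL, DUP, INS, INV, TRA (or `"INTRA"` for an
#'   unclassified intra-chromosomal rearrangement).
#' @param source `"WGS"` or `"OGM"`.
#' @return Character vector of admissible strand pairs.
#' @examples
#' normalizeStrand("DEL", "WGS")  # "+-"
#' normalizeStrand("INV", "OGM")  # "++" "--"
#' @export
normalizeStrand <- function(svtype, source = c("WGS", "OGM")) {
  source <- match.arg(source)
  switch(svtype,
    DEL = "+-",
    DUP = if (source == "WGS") "-+" else c("+-", "-+"),
    INV = c("++", "--"),
    INS = "+-",
    INTRA = c("++", "--"),
    TRA = c("+-", "-+", "++", "--"),
    stop("normalizeStrand: unknown svtype '", svtype, "'")
  )
}

.strandPair <- function(calls) paste0(calls$strand1, calls$strand2)

## Strand-pair equality under a given end pairing. Inversion junctions come
## in ++/-- flavors of one event, so INV-vs-INV comparison accepts either.
.strandsMatch <- function(pa, pb, type_a, type_b, swapped) {
  if (swapped) pb <- paste0(substr(pb, 2, 2), substr(pb, 1, 1))
  if (type_a == "INV" && type_b == "INV") {
    pa %in% c("++", "--") && pb %in% c("++", "--")
  } else {
    pa == pb
  }
}

#' Do two calls describe the same event?
#'
#' True when the two breakend pairs lie within `window` bp of each other on
#' matching chromosomes — under either end pairing, since callers order
#' breakends inconsistently — and the strand pairs agree under the pairing
#' used (reversed pairing reverses the strand pair).
#'
#' @param a,b single-row call records (rows of [svCalls()]).
#' @param window per-end tolerance in bp.
#' @return Logical scalar.
#' @export
sameEvent <- function(a, b, window) {
  near <- function(c1, p1, c2, p2) c1 == c2 && abs(p1 - p2) <= window
  pa <- .strandPair(a); pb <- .strandPair(b)
  direct <- near(a$chrom1, a$pos1, b$chrom1, b$pos1) &&
    near(a$chrom2, a$pos2, b$chrom2, b$pos2) &&
    .strandsMatch(pa, pb, a$svtype, b$svtype, swapped = FALSE)
  if (direct) return(TRUE)
  near(a$chrom1, a$pos1, b$chrom2, b$pos2) &&
    near(a$chrom2, a$pos2, b$chrom1, b$pos1) &&
    .strandsMatch(pa, pb, a$svtype, b$svtype, swapped = TRUE)
}

#' Breakend distance between two calls
#'
#' Minimum over the two end pairings (where chromosomes align) of the
#' larger per-end distance; `Inf` when no pairing aligns.
#' @param a,b single-row call records.
#' @return Non-negative number or `Inf`.
#' @export
breakendDistance <- function(a, b) {
  d <- Inf
  if (a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2) {
    d <- min(d, max(abs(a$pos1 - b$pos1), abs(a$pos2 - b$pos2)))
  }
  if (a$chrom1 == b$chrom2 && a$chrom2 == b$chrom1) {
    d <- min(d, max(abs(a$pos1 - b$pos2), abs(a$pos2 - b$pos1)))
  }
  d
}

#' GRanges view of intra-chromosomal calls
#'
#' Converts DEL/DUP/INV spans (and INS loci as width-1 points) of a call
#' table to a `GRanges` for overlap queries. 0-based half-open
#' \[pos1, pos2) maps to 1-based closed \[pos1+1, pos2\].
#' @param calls call data.frame.
#' @return `GRanges` with an `id` metadata column, one range per
#'   intra-chromosomal call.
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
callsAsGRanges <- function(calls) {
  intra <- calls[calls$svtype %in% .INTRA_TYPES, , drop = FALSE]
  end <- ifelse(intra$svtype == "INS", intra$pos1 + 1, intra$pos2)
  GenomicRanges::GRanges(intra$chrom1,
                         IRanges::IRanges(start = intra$pos1 + 1, end = end),
                         id = intra$id, svtype = intra$svtype)
}

#' GRanges from a 0-based half-open interval table
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `name`, `strand`.
#' @return `GRanges`.
#' @export
intervalsAsGRanges <- function(df) {
  if (!nrow(df)) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(start = df$start + 1,
                                                end = df$end))
  if (!is.null(df$strand)) GenomicRanges::strand(gr) <- df$strand
  if (!is.null(df$name)) gr$name <- df$name
  gr
}
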