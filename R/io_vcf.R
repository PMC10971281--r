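## VCF reading for the two supported short-read caller dialects.
##
## LUMPY-style: INFO SVTYPE/SVLEN/END/STRANDS (e.g. "+-:7") with support in
## SU/PE/SR; translocations as mated BND records (MATEID + bracket ALT).
## DELLY-style: INFO SVTYPE/END/CT ("3to5" etc.) with support in PE/SR;
## translocations as mated BND records. Extra fields are ignored.
##
## VCF POS p (1-based) maps to internal 0-based p-1; END maps to the
## half-open end directly. Chromosome names are normalized to the "chr"
## prefix at read time.

.normChrom <- function(x) ifelse(grepl("^chr", x), x, paste0("chr", x))

## natural chromosome sort key: chr1 < chr2 < ... < chr22 < chrX < chrY
## < chrM, unknown contigs after, alphabetically
.chromKey <- function(chrom) {
  x <- sub("^chr", "", chrom)
  r <- match(x, c(as.character(1:22), "X", "Y", "M", "MT"))
  r[is.na(r)] <- 99L
  sprintf("%03d%s", r, chrom)
}

## TRUE when breakend (c1, p1) sorts after (c2, p2) genomically
.bndAfter <- function(c1, p1, c2, p2) {
  k1 <- .chromKey(c1); k2 <- .chromKey(c2)
  k1 > k2 | (k1 == k2 & p1 > p2)
}

.info1 <- function(info, field, default = NA) {
  if (!field %in% names(info)) return(rep(default, nrow(info)))
  v <- info[[field]]
  if (is(v, "List") || is.list(v)) {
    v <- vapply(v, function(e) {
      if (length(e)) as.character(e[[1L]]) else NA_character_
    }, character(1))
  }
  v
}

## Bracket ALT -> strands of this breakend and its mate.
## "t[..[" => +- ; "t]..]" => ++ ; "]..]t" => -+ ; "[..[t" => -- .
.bndStrands <- function(alt) {
  last <- substring(alt, nchar(alt), nchar(alt))
  this <- ifelse(last == "[" | last == "]", "+", "-")
  mate <- ifelse(grepl("]", alt, fixed = TRUE), "+", "-")
  cbind(this = this, mate = mate)
}

.ctToStrands <- function(ct) {
  map <- c("3to3" = "++", "3to5" = "+-", "5to3" = "-+", "5to5" = "--")
  unname(map[ct])
}

#' Read a short-read SV VCF (LUMPY- or DELLY-style dialect)
#'
#' Emits one call per event: mated BND record pairs are collapsed into a
#' single translocation whose `bnd1` is the genomically smaller breakend.
#' Split-read/paired-end support is taken from the dialect's fields (`SR`,
#' `PE`, with LUMPY's `SU` as total support backstop). Insertion lengths are
#' unknown from short reads and stored as `NA`.
#'
#' @param path VCF file.
#' @param dialect `"lumpy"` or `"delly"`.
#' @param sample sample id; defaults to the file's `##sample=` header line or
#'   the file name.
#' @return An [SVCallSet-class] with `technology = "WGS"`.
#' @importFrom VariantAnnotation readVcf info
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom GenomicRanges seqnames start
#' @export
readWgsVcf <- function(path, dialect = c("lumpy", "delly"), sample = NULL) {
  dialect <- match.arg(dialect)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "ref"))
  if (is.null(sample)) {
    hdr <- readLines(path, n = 200L)
    sm <- grep("^##sample=", hdr, value = TRUE)
    sample <- if (length(sm)) sub("^##sample=", "", sm[1L]) else
      sub("\\.vcf$", "", basename(path))
  }
  inf <- VariantAnnotation::info(vcf)
  if (!"SVTYPE" %in% names(inf) || anyNA(.info1(inf, "SVTYPE"))) {
    stop("malformed VCF: SVTYPE missing for one or more records in ", path)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  rec <- data.frame(
    vid = names(rr),
    chrom = .normChrom(as.character(GenomicRanges::seqnames(rr))),
    pos1 = GenomicRanges::start(rr) - 1,
    svtype = as.character(.info1(inf, "SVTYPE")),
    end = suppressWarnings(as.numeric(.info1(inf, "END"))),
    svlen = suppressWarnings(as.numeric(.info1(inf, "SVLEN"))),
    strands = as.character(.info1(inf, "STRANDS", NA_character_)),
    ct = as.character(.info1(inf, "CT", NA_character_)),
    mateid = as.character(.info1(inf, "MATEID", NA_character_)),
    sr = suppressWarnings(as.integer(.info1(inf, "SR", 0L))),
    pe = suppressWarnings(as.integer(.info1(inf, "PE", 0L))),
    su = suppressWarnings(as.integer(.info1(inf, "SU", 0L))),
    stringsAsFactors = FALSE
  )
  rec$sr[is.na(rec$sr)] <- 0L
  rec$pe[is.na(rec$pe)] <- 0L
  alt <- VariantAnnotation::fixed(vcf)$ALT
  rec$alt <- vapply(seq_len(n), function(i) {
    a <- alt[[i]]
    if (length(a)) as.character(a[[1L]]) else NA_character_
  }, character(1))

  out <- list()
  k <- 0L
  is_bnd <- rec$svtype == "BND"

  ## --- intra-chromosomal records ---------------------------------------
  for (i in which(!is_bnd)) {
    r <- rec[i, ]
    if (!r$svtype %in% .INTRA_TYPES) {
      warning("skipping record ", r$vid, " with unsupported SVTYPE ",
              r$svtype)
      next
    }
    pos2 <- if (r$svtype == "INS") r$pos1 else r$end
    if (is.na(pos2)) pos2 <- r$pos1 + abs(r$svlen)
    len <- if (r$svtype == "INS") NA_real_ else pos2 - r$pos1
    sp <- if (!is.na(r$strands)) sub(":.*$", "", r$strands)
      else if (!is.na(r$ct)) .ctToStrands(r$ct)
      else normalizeStrand(r$svtype, "WGS")[1L]
    if (is.na(sp)) sp <- normalizeStrand(r$svtype, "WGS")[1L]
    k <- k + 1L
    out[[k]] <- data.frame(
      id = r$vid, svtype = r$svtype, chrom1 = r$chrom, pos1 = r$pos1,
      strand1 = substr(sp, 1, 1), chrom2 = r$chrom, pos2 = pos2,
      strand2 = substr(sp, 2, 2), length = len,
      support_sr = r$sr, support_pe = r$pe, support_mol = 0L,
      source = toupper(dialect), sample = sample, flags = "",
      stringsAsFactors = FALSE
    )
  }

  ## --- BND records: pair mates into translocations ----------------------
  bnd <- rec[is_bnd, , drop = FALSE]
  seen <- character()
  for (i in seq_len(nrow(bnd))) {
    r <- bnd[i, ]
    if (r$vid %in% seen) next
    mate <- bnd[match(r$mateid, bnd$vid), ]
    if (is.na(r$mateid) || is.na(mate$vid[1L])) {
      warning("unpaired BND record ", r$vid, " skipped")
      next
    }
    seen <- c(seen, r$vid, mate$vid)
    st <- .bndStrands(r$alt)
    a <- list(chrom = r$chrom, pos = r$pos1, strand = st[, "this"])
    b <- list(chrom = mate$chrom, pos = mate$pos1, strand = st[, "mate"])
    ## order breakends genomically
    if (.bndAfter(a$chrom, a$pos, b$chrom, b$pos)) {
      tmp <- a; a <- b; b <- tmp
    }
    flags <- if (a$chrom == b$chrom) "INTRA_REARR" else ""
    k <- k + 1L
    out[[k]] <- data.frame(
      id = sub("_[12]$", "", r$vid), svtype = "TRA",
      chrom1 = a$chrom, pos1 = a$pos, strand1 = a$strand,
      chrom2 = b$chrom, pos2 = b$pos, strand2 = b$strand,
      length = NA_real_,
      support_sr = max(r$sr, mate$sr), support_pe = max(r$pe, mate$pe),
      support_mol = 0L, source = toupper(dialect), sample = sample,
      flags = flags, stringsAsFactors = FALSE
    )
  }
  calls <- if (k) do.call(rbind, out) else emptyCalls()
  SVCallSet(calls, sample = sample, technology = "WGS")
}
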