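## Tabular readers/writers: OGM SMAP-like TSV, BED3/BED6 tracks, control
## (polymorphism) database TSV, RNA fusion candidate TSV, and the package's
## own integrated-call and resolution-report outputs.
##
## Package-defined TSV schemas use 0-based half-open coordinates and say so
## in their "#" header comments. The SMAP-like dialect is 1-based (as the
## source format is) and converted on read.

.SMAP_TYPES <- c(
  deletion = "DEL", insertion = "INS", duplication = "DUP",
  duplication_split = "DUP", duplication_inverted = "DUP",
  inversion = "INV", inversion_paired = "INV",
  translocation_interchr = "TRA", translocation_intrachr = "TRA",
  trans_interchr_common = "TRA"
)

.smapChrom <- function(id) {
  id <- as.character(id)
  id[id == "23"] <- "X"
  id[id == "24"] <- "Y"
  .normChrom(id)
}

#' Read an OGM SV table (SMAP-like TSV dialect)
#'
#' Minimal documented column subset of the optical-mapping SV format:
#' `SmapId`, `RefcontigID1`, `RefcontigID2` (numeric contig ids, 23 = X,
#' 24 = Y), `RefStartPos`, `RefEndPos` (1-based; an intra-chromosomal event
#' spans `RefEndPos - RefStartPos` bases), `Type`, `Confidence`, and
#' optionally `Size` (label-derived SV size in bp) and `Orientation` (strand
#' pair such as `+/-`, translocations only). Extra columns are ignored.
#' Type strings map to DEL/DUP/INS/INV/TRA; rows with an unknown type are
#' skipped with a warning. Intra-chromosomal strands are assigned the
#' canonical pair for the type.
#'
#' @param path TSV file with header.
#' @param sample sample id (default: file name).
#' @return An [SVCallSet-class] with `technology = "OGM"`; molecule support
#'   is taken from `Confidence` when no `MoleculeCount` column is present.
#' @export
readOgmSmap <- function(path, sample = NULL) {
  if (is.null(sample)) sample <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  if (!grepl("SmapId", first)) stop("missing SMAP header line in ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("SmapId", "RefcontigID1", "RefcontigID2", "RefStartPos",
            "RefEndPos", "Type", "Confidence")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("SMAP file missing column(s): ", paste(miss, collapse = ", "))
  }
  svtype <- unname(.SMAP_TYPES[tolower(tab$Type)])
  if (anyNA(svtype)) {
    bad <- unique(tab$Type[is.na(svtype)])
    warning("skipping rows with unknown SMAP Type: ",
            paste(bad, collapse = ", "))
    tab <- tab[!is.na(svtype), , drop = FALSE]
    svtype <- svtype[!is.na(svtype)]
  }
  if (!nrow(tab)) {
    return(SVCallSet(sample = sample, technology = "OGM"))
  }
  chrom1 <- .smapChrom(tab$RefcontigID1)
  chrom2 <- .smapChrom(tab$RefcontigID2)
  pos1 <- tab$RefStartPos - 1
  pos2 <- ifelse(svtype == "INS", tab$RefStartPos - 1, tab$RefEndPos - 1)
  size <- if ("Size" %in% names(tab)) as.numeric(tab$Size) else NA_real_
  len <- ifelse(svtype == "TRA", NA_real_,
                ifelse(!is.na(size) & size > 0, size, pos2 - pos1))
  len[svtype == "INS" & (is.na(size) | size <= 0)] <- NA_real_
  ori <- if ("Orientation" %in% names(tab)) gsub("/", "", tab$Orientation)
    else rep(NA_character_, nrow(tab))
  canon <- vapply(svtype, function(t) normalizeStrand(t, "OGM")[1L],
                  character(1))
  sp <- ifelse(!is.na(ori) & nchar(ori) == 2, ori, canon)
  mol <- if ("MoleculeCount" %in% names(tab)) as.integer(tab$MoleculeCount)
    else as.integer(round(tab$Confidence))
  flags <- ifelse(svtype == "TRA" & chrom1 == chrom2, "INTRA_REARR", "")
  ## order TRA breakends genomically
  swap <- svtype == "TRA" & .bndAfter(chrom1, pos1, chrom2, pos2)
  calls <- data.frame(
    id = paste0("O", tab$SmapId), svtype = svtype,
    chrom1 = ifelse(swap, chrom2, chrom1),
    pos1 = ifelse(swap, pos2, pos1),
    strand1 = ifelse(swap, substr(sp, 2, 2), substr(sp, 1, 1)),
    chrom2 = ifelse(swap, chrom1, chrom2),
    pos2 = ifelse(swap, pos1, pos2),
    strand2 = ifelse(swap, substr(sp, 1, 1), substr(sp, 2, 2)),
    length = len, support_sr = 0L, support_pe = 0L, support_mol = mol,
    source = "OGM", sample = sample, flags = flags,
    stringsAsFactors = FALSE
  )
  SVCallSet(calls, sample = sample, technology = "OGM",
            metadata = list(confidence = stats::setNames(tab$Confidence,
                                                         calls$id)))
}

#' Read a BED3 interval track
#'
#' @param path BED file (0-based half-open, no header). An empty file is a
#'   valid empty track.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
readBedTrack <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 3) stop("BED file needs >= 3 columns: ", path)
  out <- data.frame(chrom = .normChrom(tab[[1L]]), start = tab[[2L]],
                    end = tab[[3L]], stringsAsFactors = FALSE)
  bad <- which(out$start >= out$end)
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], " in ", path, ": start >= end")
  }
  out
}

#' Read a BED6 gene track
#'
#' Requires name (gene symbol) and strand columns on top of BED3.
#' @param path BED6 file.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
readGeneBed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 6) stop("gene BED needs 6 columns (BED6): ", path)
  if (any(!nzchar(tab[[4L]]))) stop("gene BED has empty symbols: ", path)
  bad <- which(tab[[2L]] >= tab[[3L]])
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], " in ", path, ": start >= end")
  }
  data.frame(chrom = .normChrom(tab[[1L]]), start = tab[[2L]],
             end = tab[[3L]], name = tab[[4L]], strand = tab[[6L]],
             stringsAsFactors = FALSE)
}

#' Load the resource tracks used for filtering and annotation
#'
#' @param repeats,gaps,centromeres,sparse paths to BED3 files (any may be
#'   `NULL` for an empty track).
#' @param genes path to a BED6 gene file, or `NULL`.
#' @return Named list of interval data.frames (class `ResourceTracks`).
#' @export
readResourceTracks <- function(repeats = NULL, gaps = NULL,
                               centromeres = NULL, sparse = NULL,
                               genes = NULL) {
  rd <- function(p) if (is.null(p)) {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               stringsAsFactors = FALSE)
  } else readBedTrack(p)
  structure(list(
    repeats = rd(repeats), gaps = rd(gaps), centromeres = rd(centromeres),
    sparse = rd(sparse),
    genes = if (is.null(genes)) {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 name = character(), strand = character(),
                 stringsAsFactors = FALSE)
    } else readGeneBed(genes)
  ), class = "ResourceTracks")
}

#' Read a control/polymorphism database (DGV-like TSV)
#'
#' Schema: `chrom`, `start`, `end` (0-based half-open), `svtype`,
#' `n_individuals` (optionally `id`, `length`). Used for tumor-only
#' germline filtering.
#' @param path TSV file with header.
#' @return data.frame of control records.
#' @export
readControlDb <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("chrom", "start", "end", "svtype", "n_individuals")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("control DB missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(tab$n_individuals < 1)) {
    stop("control DB n_individuals must be >= 1")
  }
  tab$chrom <- .normChrom(tab$chrom)
  if (is.null(tab$id)) tab$id <- paste0("ctrl", seq_len(nrow(tab)))
  if (is.null(tab$length)) tab$length <- tab$end - tab$start
  tab
}

#' Read an RNA-Seq fusion candidate table
#'
#' Schema: `gene_a`, `gene_b`, `bnd_a`, `bnd_b` (breakends as
#' `"chr:pos"`, 0-based; may be empty), `reads` (supporting hybrid read
#' count).
#' @param path TSV file with header.
#' @return data.frame with parsed breakend columns `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`.
#' @export
readFusionTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("gene_a", "gene_b", "reads")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("fusion table missing column(s): ", paste(miss, collapse = ", "))
  }
  parse_bnd <- function(x) {
    if (is.null(x)) x <- rep("", nrow(tab))
    parts <- strsplit(as.character(x), ":", fixed = TRUE)
    list(chrom = vapply(parts, function(p)
           if (length(p) == 2) .normChrom(p[1L]) else NA_character_,
           character(1)),
         pos = vapply(parts, function(p)
           if (length(p) == 2) as.numeric(p[2L]) else NA_real_, numeric(1)))
  }
  a <- parse_bnd(tab$bnd_a); b <- parse_bnd(tab$bnd_b)
  data.frame(gene_a = tab$gene_a, gene_b = tab$gene_b,
             chrom_a = a$chrom, pos_a = a$pos,
             chrom_b = b$chrom, pos_b = b$pos,
             reads = as.integer(tab$reads), stringsAsFactors = FALSE)
}

.thresholdHeader <- function(th) {
  v <- thresholdList(th)
  c("# coordinates: 0-based half-open",
    sprintf("# threshold: %s=%g", names(v), unlist(v)))
}

#' Write an integrated call set as TSV (with threshold header comments)
#'
#' Output is deterministic: calls are sorted by chromosome, position and id.
#' [readIntegratedTsv()] reads it back field-for-field.
#' @param cs an [SVCallSet-class].
#' @param path output file.
#' @param th thresholds recorded in the header.
#' @return `path`, invisibly.
#' @export
writeIntegratedTsv <- function(cs, path, th = svThresholds()) {
  cl <- svCalls(cs)
  cl <- cl[order(cl$chrom1, cl$pos1, cl$id), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.thresholdHeader(th),
               sprintf("# sample=%s technology=%s", sampleName(cs),
                       technology(cs))), con)
  utils::write.table(cl, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIntegratedTsv
#' @export
readIntegratedTsv <- function(path) {
  hdr <- grep("^# sample=", readLines(path, n = 50L), value = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  tab$flags[is.na(tab$flags)] <- ""
  tech <- if (length(hdr)) sub(".*technology=", "", hdr[1L]) else "WGS"
  SVCallSet(tab, technology = tech)
}

#' Write the unsupported-breakpoint resolution report
#'
#' One row per category with count and percent of total, mirroring the
#' cascade accounting.
#' @param tab a [ResolutionTable-class].
#' @param path output TSV.
#' @param th thresholds recorded in the header.
#' @return `path`, invisibly.
#' @export
writeResolutionReport <- function(tab, path, th = svThresholds()) {
  df <- as.data.frame(tab)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.thresholdHeader(th), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
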