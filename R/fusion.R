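## Gene-fusion triangulation: derive candidates from DNA SV breakends,
## flag repeat-mediated WGS-only candidates as putative, and integrate
## WGS, OGM and RNA-Seq evidence into one matrix.

.geneAt <- function(chrom, pos, genes) {
  if (!nrow(genes)) return(rep(NA_integer_, length(chrom)))
  gr <- intervalsAsGRanges(genes)
  GenomicRanges::strand(gr) <- "*"
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, gr, select = "first"))
  as.integer(hits)
}

## A breakend arm retains the gene's 5' portion iff the gene strand equals
## the breakend strand ('+' arm keeps lower coordinates, which is the 5'
## side of a '+' gene; symmetric for '-').
.fivePrime <- function(gene_strand, bnd_strand) gene_strand == bnd_strand

.emptyFusions <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             chrom_a = character(), pos_a = numeric(),
             chrom_b = character(), pos_b = numeric(),
             sv_id = character(), svtype = character(),
             sample = character(), technology = character(),
             orientation_compatible = logical(), flags = character(),
             stringsAsFactors = FALSE)
}

#' Derive gene-fusion candidates from SV calls
#'
#' A translocation (or a deletion/duplication/inversion spanning two genes)
#' whose breakends fall inside two distinct genes yields one candidate.
#' `orientation_compatible` is `TRUE` when the joined arms place the genes
#' head-to-tail: exactly one arm retains its gene's 5' portion, so
#' transcription can run from one gene into the other. Incompatible
#' junctions (both 5' or both 3' arms) are still reported — they juxtapose
#' the genes without creating a fusion transcript.
#'
#' @param cs an [SVCallSet-class].
#' @param genes gene track data.frame (`chrom`, `start`, `end`, `name`,
#'   `strand`), e.g. from [readGeneBed()].
#' @return data.frame of candidates (`gene_a` is the 5'-donor gene when the
#'   orientation is compatible).
#' @export
candidateFusionsFromSv <- function(cs, genes) {
  cl <- svCalls(cs)
  cl <- cl[cl$svtype %in% c("TRA", "DEL", "DUP", "INV"), , drop = FALSE]
  if (!nrow(cl) || !nrow(genes)) return(.emptyFusions())
  g1 <- .geneAt(cl$chrom1, cl$pos1, genes)
  g2 <- .geneAt(cl$chrom2, cl$pos2, genes)
  sel <- which(!is.na(g1) & !is.na(g2) & genes$name[g1] != genes$name[g2])
  if (!length(sel)) return(.emptyFusions())
  out <- lapply(sel, function(i) {
    fa <- .fivePrime(genes$strand[g1[i]], cl$strand1[i])
    fb <- .fivePrime(genes$strand[g2[i]], cl$strand2[i])
    compat <- xor(fa, fb)
    ## put the donor (5'-contributing) gene first when defined
    swap <- compat && fb
    a <- if (swap) g2[i] else g1[i]
    b <- if (swap) g1[i] else g2[i]
    data.frame(
      gene_a = genes$name[a], gene_b = genes$name[b],
      chrom_a = if (swap) cl$chrom2[i] else cl$chrom1[i],
      pos_a = if (swap) cl$pos2[i] else cl$pos1[i],
      chrom_b = if (swap) cl$chrom1[i] else cl$chrom2[i],
      pos_b = if (swap) cl$pos1[i] else cl$pos2[i],
      sv_id = cl$id[i], svtype = cl$svtype[i], sample = cl$sample[i],
      technology = technology(cs), orientation_compatible = compat,
      flags = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Flag repeat-overlapping single-method fusions as putative
#'
#' A WGS fusion candidate is marked `PUTATIVE` when either breakend
#' overlaps a repeat interval and no second method (OGM match or RNA
#' support) backs it.
#'
#' @param fusions candidate data.frame from [candidateFusionsFromSv()].
#' @param repeats repeat track data.frame (`chrom`, `start`, `end`).
#' @param ogm_support,rna_support logical vectors (recycled) saying whether
#'   each candidate is supported by OGM / RNA; default none.
#' @return `fusions` with updated `flags`.
#' @export
markPutative <- function(fusions, repeats, ogm_support = FALSE,
                         rna_support = FALSE) {
  if (!nrow(fusions)) return(fusions)
  on_rep <- .inTrack(fusions$chrom_a, fusions$pos_a, repeats) |
    .inTrack(fusions$chrom_b, fusions$pos_b, repeats)
  second <- rep_len(ogm_support, nrow(fusions)) |
    rep_len(rna_support, nrow(fusions))
  put <- on_rep & !second
  fusions$flags <- ifelse(put & !grepl("PUTATIVE", fusions$flags),
                          ifelse(nzchar(fusions$flags),
                                 paste0(fusions$flags, ",PUTATIVE"),
                                 "PUTATIVE"),
                          fusions$flags)
  fusions
}

.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "::")
}

#' Integrate fusion evidence across WGS, OGM and RNA-Seq
#'
#' Candidates from the two DNA technologies are matched by unordered gene
#' pair within a sample, confirmed when their breakends agree within the
#' cross-technology window. RNA support requires a fusion-table row for the
#' gene pair with at least `rna_min_reads` (16) supporting hybrid reads.
#' A pair absent from the known-fusion list is flagged `NOVEL`.
#'
#' @param wgs_f,ogm_f candidate data.frames from
#'   [candidateFusionsFromSv()] (either may be empty).
#' @param rna_table data.frame from [readFusionTable()] (or with columns
#'   `gene_a`, `gene_b`, `reads`); may be `NULL`.
#' @param known_fusions character vector of known pairs (`"A::B"`) or a
#'   data.frame with `gene_a`/`gene_b`; `NULL` means no list (everything
#'   novel).
#' @param th an [SVThresholds-class].
#' @return Evidence matrix data.frame: one row per (sample, gene pair) with
#'   `wgs_support`, `ogm_support`, `rna_support`, `rna_reads`,
#'   `orientation_compatible`, coordinates (WGS preferred) and `flags`.
#' @export
integrateFusionEvidence <- function(wgs_f, ogm_f, rna_table = NULL,
                                    known_fusions = NULL,
                                    th = svThresholds()) {
  if (is.null(wgs_f) || !NROW(wgs_f)) wgs_f <- .emptyFusions()
  if (is.null(ogm_f) || !NROW(ogm_f)) ogm_f <- .emptyFusions()
  wgs_f$key <- .pairKey(wgs_f$gene_a, wgs_f$gene_b)
  ogm_f$key <- .pairKey(ogm_f$gene_a, ogm_f$gene_b)
  known <- if (is.null(known_fusions)) character()
    else if (is.data.frame(known_fusions))
      .pairKey(known_fusions$gene_a, known_fusions$gene_b)
    else vapply(strsplit(known_fusions, "::", fixed = TRUE),
                function(p) .pairKey(p[1L], p[2L]), character(1))
  rna <- if (is.null(rna_table) || !NROW(rna_table)) NULL else {
    rk <- .pairKey(rna_table$gene_a, rna_table$gene_b)
    stats::aggregate(list(reads = rna_table$reads), list(key = rk), max)
  }
  win <- th["cross_tech_window"]

  keys <- unique(rbind(wgs_f[c("sample", "key")], ogm_f[c("sample", "key")]))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sm <- keys$sample[i]; ky <- keys$key[i]
    w <- wgs_f[wgs_f$sample == sm & wgs_f$key == ky, , drop = FALSE]
    o <- ogm_f[ogm_f$sample == sm & ogm_f$key == ky, , drop = FALSE]
    dual <- FALSE
    if (nrow(w) && nrow(o)) {
      for (iw in seq_len(nrow(w))) {
        for (io in seq_len(nrow(o))) {
          near <- function(c1, p1, c2, p2) c1 == c2 && abs(p1 - p2) <= win
          ok <- (near(w$chrom_a[iw], w$pos_a[iw], o$chrom_a[io],
                      o$pos_a[io]) &&
                 near(w$chrom_b[iw], w$pos_b[iw], o$chrom_b[io],
                      o$pos_b[io])) ||
                (near(w$chrom_a[iw], w$pos_a[iw], o$chrom_b[io],
                      o$pos_b[io]) &&
                 near(w$chrom_b[iw], w$pos_b[iw], o$chrom_a[io],
                      o$pos_a[io]))
          if (ok) dual <- TRUE
        }
      }
    }
    base <- if (nrow(w)) w[1L, ] else o[1L, ]
    reads <- if (!is.null(rna)) rna$reads[match(ky, rna$key)] else NA_integer_
    if (is.na(reads)) reads <- 0L
    flags <- setdiff(strsplit(base$flags, ",")[[1]], "")
    if (!ky %in% known) flags <- c(flags, "NOVEL")
    data.frame(
      gene_a = base$gene_a, gene_b = base$gene_b, sample = sm,
      chrom_a = base$chrom_a, pos_a = base$pos_a,
      chrom_b = base$chrom_b, pos_b = base$pos_b,
      wgs_support = nrow(w) > 0, ogm_support = nrow(o) > 0,
      dual_confirmed = dual,
      rna_reads = reads, rna_support = reads >= th["rna_min_reads"],
      orientation_compatible = base$orientation_compatible,
      flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      sample = character(), chrom_a = character(),
                      pos_a = numeric(), chrom_b = character(),
                      pos_b = numeric(), wgs_support = logical(),
                      ogm_support = logical(), dual_confirmed = logical(),
                      rna_reads = integer(), rna_support = logical(),
                      orientation_compatible = logical(),
                      flags = character(), stringsAsFactors = FALSE)
  }
  out[order(out$sample, out$gene_a, out$gene_b), , drop = FALSE]
}

#' Write the fusion evidence matrix as TSV
#' @param ev evidence matrix from [integrateFusionEvidence()].
#' @param path output file.
#' @param th thresholds recorded in the header.
#' @return `path`, invisibly.
#' @export
writeFusionMatrix <- function(ev, path, th = svThresholds()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.thresholdHeader(th), con)
  utils::write.table(ev, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
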