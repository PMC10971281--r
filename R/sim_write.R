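## Writers that render simulator output in the same external formats the
## readers consume, so simulated data is a drop-in pipeline input.

.bracketAlt <- function(s1, s2, chrom, pos1) {
  ## breakend ALT for this-end strand s1 and mate strand s2 (mate at
  ## chrom:pos1, 1-based)
  m <- paste0(chrom, ":", pos1)
  ifelse(s1 == "+" & s2 == "-", paste0("N[", m, "["),
  ifelse(s1 == "+" & s2 == "+", paste0("N]", m, "]"),
  ifelse(s1 == "-" & s2 == "+", paste0("]", m, "]N"),
                                paste0("[", m, "[N"))))
}

#' Write a call set as a caller-dialect VCF
#'
#' Renders intra-chromosomal calls as symbolic-ALT records and
#' translocations as mated BND pairs, using the LUMPY-style
#' (`STRANDS`/`SU`/`PE`/`SR`) or DELLY-style (`CT`/`PE`/`SR`) INFO fields
#' that [readWgsVcf()] parses. Internal 0-based `pos1` becomes VCF
#' `POS = pos1 + 1`; `END` is the half-open end.
#'
#' @param cs an [SVCallSet-class].
#' @param path output VCF.
#' @param dialect `"lumpy"` or `"delly"`.
#' @param chrom_lengths named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
writeCallerVcf <- function(cs, path, dialect = c("lumpy", "delly"),
                           chrom_lengths = NULL) {
  dialect <- match.arg(dialect)
  cl <- svCalls(cs)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##sample=", sampleName(cs)),
    paste0("##source=", dialect),
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths))
    },
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Half-open end\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    if (dialect == "lumpy") c(
      "##INFO=<ID=STRANDS,Number=1,Type=String,Description=\"Strand pair with support\">",
      "##INFO=<ID=SU,Number=1,Type=Integer,Description=\"Total support\">"
    ) else
      "##INFO=<ID=CT,Number=1,Type=String,Description=\"Junction orientation\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Paired-end support\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Split-read support\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- character()
  ct_of <- function(sp) {
    c("++" = "3to3", "+-" = "3to5", "-+" = "5to3", "--" = "5to5")[sp]
  }
  for (i in seq_len(nrow(cl))) {
    r <- cl[i, ]
    sup <- if (dialect == "lumpy") {
      sprintf("STRANDS=%s%s:%d;SU=%d;PE=%d;SR=%d", r$strand1, r$strand2,
              r$support_sr + r$support_pe, r$support_sr + r$support_pe,
              r$support_pe, r$support_sr)
    } else {
      sprintf("CT=%s;PE=%d;SR=%d", ct_of(paste0(r$strand1, r$strand2)),
              r$support_pe, r$support_sr)
    }
    if (r$svtype == "TRA") {
      a1 <- .bracketAlt(r$strand1, r$strand2, r$chrom2, r$pos2 + 1)
      a2 <- .bracketAlt(r$strand2, r$strand1, r$chrom1, r$pos1 + 1)
      lines <- c(lines,
        sprintf("%s\t%d\t%s_1\tN\t%s\t.\tPASS\tSVTYPE=BND;MATEID=%s_2;%s",
                r$chrom1, r$pos1 + 1, r$id, a1, r$id, sup),
        sprintf("%s\t%d\t%s_2\tN\t%s\t.\tPASS\tSVTYPE=BND;MATEID=%s_1;%s",
                r$chrom2, r$pos2 + 1, r$id, a2, r$id, sup))
    } else {
      svlen <- if (is.na(r$length)) "" else
        sprintf(";SVLEN=%d", as.integer(
          if (r$svtype == "DEL") -r$length else r$length))
      lines <- c(lines,
        sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d%s;%s",
                r$chrom1, r$pos1 + 1, r$id, r$svtype, r$svtype,
                as.integer(if (r$svtype == "INS") r$pos1 else r$pos2),
                svlen, sup))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

.smapContig <- function(chrom) {
  x <- sub("^chr", "", chrom)
  x[x == "X"] <- "23"
  x[x == "Y"] <- "24"
  as.integer(x)
}

#' Write a call set as an OGM SMAP-like TSV
#'
#' Inverse of [readOgmSmap()] for the documented column subset.
#' @param cs an [SVCallSet-class] (typically from [observeOgm()]).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeOgmSmap <- function(cs, path) {
  cl <- svCalls(cs)
  type_of <- c(DEL = "deletion", INS = "insertion", DUP = "duplication",
               INV = "inversion")
  tab <- data.frame(
    SmapId = seq_len(nrow(cl)),
    RefcontigID1 = .smapContig(cl$chrom1),
    RefcontigID2 = .smapContig(cl$chrom2),
    RefStartPos = cl$pos1 + 1,
    RefEndPos = ifelse(cl$svtype == "INS", cl$pos1 + 1, cl$pos2 + 1),
    Type = ifelse(cl$svtype == "TRA",
                  ifelse(cl$chrom1 == cl$chrom2, "translocation_intrachr",
                         "translocation_interchr"),
                  type_of[cl$svtype]),
    Confidence = cl$support_mol,
    Size = ifelse(is.na(cl$length), -1, cl$length),
    Orientation = ifelse(cl$svtype == "TRA",
                         paste0(cl$strand1, "/", cl$strand2), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.writeBed3 <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.writeBed6 <- function(df, path) {
  out <- data.frame(df$chrom, df$start, df$end, df$name, 0L, df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset as pipeline input files
#'
#' Produces the full set of external-format inputs ([runPipeline()]'s
#' expected layout): two caller VCFs, the OGM SMAP-like TSV, resource-track
#' BEDs, the control database and control-call TSVs, and the RNA fusion
#' table.
#'
#' @param sim a [simulateDataset()] result.
#' @param dir output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
writeSimulatedInputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$truth$config
  tr <- sim$truth$tracks
  p <- list(
    lumpy_vcf = file.path(dir, "lumpy.vcf"),
    delly_vcf = file.path(dir, "delly.vcf"),
    ogm_smap = file.path(dir, "ogm_smap.tsv"),
    repeats_bed = file.path(dir, "repeats.bed"),
    gaps_bed = file.path(dir, "gaps.bed"),
    centromeres_bed = file.path(dir, "centromeres.bed"),
    sparse_bed = file.path(dir, "sparse.bed"),
    genes_bed = file.path(dir, "genes.bed"),
    control_db = file.path(dir, "control_db.tsv"),
    control_calls = file.path(dir, "control_calls.tsv"),
    rna_fusions = file.path(dir, "rna_fusions.tsv")
  )
  writeCallerVcf(sim$lumpy, p$lumpy_vcf, "lumpy", cfg$chrom_lengths)
  writeCallerVcf(sim$delly, p$delly_vcf, "delly", cfg$chrom_lengths)
  writeOgmSmap(sim$ogm, p$ogm_smap)
  .writeBed3(tr$repeats, p$repeats_bed)
  .writeBed3(tr$gaps, p$gaps_bed)
  .writeBed3(tr$centromeres, p$centromeres_bed)
  .writeBed3(tr$sparse, p$sparse_bed)
  .writeBed6(tr$genes, p$genes_bed)
  utils::write.table(sim$truth$control_db, p$control_db, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeIntegratedTsv(sim$truth$control_calls, p$control_calls)
  rna <- sim$rna
  rna_out <- data.frame(
    gene_a = rna$gene_a, gene_b = rna$gene_b,
    bnd_a = ifelse(is.na(rna$chrom_a), "",
                   paste0(rna$chrom_a, ":", rna$pos_a)),
    bnd_b = ifelse(is.na(rna$chrom_b), "",
                   paste0(rna$chrom_b, ":", rna$pos_b)),
    reads = rna$reads, stringsAsFactors = FALSE)
  utils::write.table(rna_out, p$rna_fusions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(p)
}
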