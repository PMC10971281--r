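## Cross-technology integration: match the WGS consensus set against the
## OGM set, resolve translocation/insertion discordance, and summarize
## concordance. Reported coordinates always come from the higher-resolution
## technology, WGS.

.matchRules <- c("TRA_WINDOW", "DEL_OVERLAP", "DUP_AS_INS", "LARGE_INTRA")

## candidate (wgs, ogm) pairs for one rule; score: larger = better
.crossCandidates <- function(wcl, ocl, th) {
  out <- list(); k <- 0L
  add <- function(id_w, id_o, rule, score) {
    k <<- k + 1L
    out[[k]] <<- data.frame(id_w = id_w, id_o = id_o, rule = rule,
                            score = score, stringsAsFactors = FALSE)
  }
  win <- th["cross_tech_window"]

  ## deletions: WGS-anchored coverage >= 0.5 plus the 80-120% size rule.
  ## The same rule screens small same-type DUP/INV pairs; the asymmetric
  ## coverage reading follows the published wording for deletions.
  for (ty in c("DEL", "DUP", "INV")) {
    w <- wcl[wcl$svtype == ty & wcl$pos2 > wcl$pos1, , drop = FALSE]
    o <- ocl[ocl$svtype == ty & ocl$pos2 > ocl$pos1, , drop = FALSE]
    if (nrow(w) && nrow(o)) {
      grw <- intervalsAsGRanges(data.frame(chrom = w$chrom1, start = w$pos1,
                                           end = w$pos2))
      gro <- intervalsAsGRanges(data.frame(chrom = o$chrom1, start = o$pos1,
                                           end = o$pos2))
      hits <- suppressWarnings(GenomicRanges::findOverlaps(grw, gro))
      for (h in seq_along(hits)) {
        iw <- S4Vectors::queryHits(hits)[h]
        io <- S4Vectors::subjectHits(hits)[h]
        ov <- min(w$pos2[iw], o$pos2[io]) - max(w$pos1[iw], o$pos1[io])
        cover <- ov / (w$pos2[iw] - w$pos1[iw])
        olen <- if (!is.na(o$length[io]) && o$length[io] > 0) o$length[io]
          else o$pos2[io] - o$pos1[io]
        if (cover >= th["del_ro"] &&
            sizeRatioOk(olen, w$pos2[iw] - w$pos1[iw], th)) {
          add(w$id[iw], o$id[io], "DEL_OVERLAP", cover)
        }
      }
    }
  }

  ## translocations and large intra-chromosomal SVs: same event within the
  ## cross-technology window (both ends, matching strands).
  big <- function(cl) cl$svtype == "TRA" |
    (cl$svtype %in% c("DUP", "INV") & !is.na(cl$length) &
     cl$length >= th["large_intra_min"])
  w <- wcl[big(wcl), , drop = FALSE]
  o <- ocl[big(ocl), , drop = FALSE]
  for (iw in seq_len(nrow(w))) {
    for (io in seq_len(nrow(o))) {
      if (w$svtype[iw] != o$svtype[io]) next
      if (sameEvent(w[iw, ], o[io, ], win)) {
        rule <- if (w$svtype[iw] == "TRA") "TRA_WINDOW" else "LARGE_INTRA"
        add(w$id[iw], o$id[io], rule, -breakendDistance(w[iw, ], o[io, ]))
      }
    }
  }

  ## insertions: WGS insertion lengths are unknown, so proximity only
  w <- wcl[wcl$svtype == "INS", , drop = FALSE]
  o <- ocl[ocl$svtype == "INS", , drop = FALSE]
  for (iw in seq_len(nrow(w))) {
    for (io in seq_len(nrow(o))) {
      d <- abs(w$pos1[iw] - o$pos1[io])
      if (w$chrom1[iw] == o$chrom1[io] && d <= win) {
        add(w$id[iw], o$id[io], "LARGE_INTRA", -d)
      }
    }
  }

  ## WGS duplication at the locus of an OGM insertion: the insertion is
  ## resolved as a duplication by short reads; annotate as DUP.
  w <- wcl[wcl$svtype == "DUP", , drop = FALSE]
  o <- ocl[ocl$svtype == "INS", , drop = FALSE]
  for (iw in seq_len(nrow(w))) {
    for (io in seq_len(nrow(o))) {
      if (w$chrom1[iw] != o$chrom1[io]) next
      d <- min(abs(w$pos1[iw] - o$pos1[io]), abs(w$pos2[iw] - o$pos1[io]))
      if (d <= win) add(w$id[iw], o$id[io], "DUP_AS_INS", -d)
    }
  }

  if (k) do.call(rbind, out) else
    data.frame(id_w = character(), id_o = character(), rule = character(),
               score = numeric(), stringsAsFactors = FALSE)
}

#' Match the WGS consensus set against the OGM set
#'
#' Rules: translocations and large (>= `large_intra_min`) intra-chromosomal
#' SVs match as the same event within the +/- `cross_tech_window` breakend
#' window; deletions match when at least `del_ro` of the WGS deletion is
#' covered by the OGM deletion and the OGM size is within the 80-120% band;
#' small duplications/inversions use the deletion rule; WGS insertions match
#' OGM insertions by locus proximity; a WGS duplication may match an OGM
#' insertion at the same locus (rule `DUP_AS_INS`, annotated as
#' duplication). Assignment is greedy 1-to-1 with same-type overlap rules
#' taking priority over the `DUP_AS_INS` fallback. The output partitions
#' both inputs: every call lands in exactly one of matches, `wgs_only`,
#' `ogm_only`.
#'
#' @param wgs,ogm filtered [SVCallSet-class] objects.
#' @param th an [SVThresholds-class].
#' @return List with `matches` (data.frame `wgs_id, ogm_id, rule`),
#'   `wgs_only` and `ogm_only` (`SVCallSet`s), and `reported` (matched calls
#'   at WGS coordinates, flagged `OGM_CONFIRMED`).
#' @export
matchCrossTech <- function(wgs, ogm, th = svThresholds()) {
  wcl <- svCalls(wgs); ocl <- svCalls(ogm)
  cand <- .crossCandidates(wcl, ocl, th)
  ## same-type rules first, DUP_AS_INS only for what remains
  primary <- cand[cand$rule != "DUP_AS_INS", , drop = FALSE]
  fallback <- cand[cand$rule == "DUP_AS_INS", , drop = FALSE]
  pick <- function(p, used_w, used_o) {
    p <- p[!(p$id_w %in% used_w) & !(p$id_o %in% used_o), , drop = FALSE]
    names(p)[1:2] <- c("id_a", "id_b")
    p[.greedy1to1(p, p$score), , drop = FALSE]
  }
  m1 <- pick(primary, character(), character())
  m2 <- pick(fallback, m1$id_a, m1$id_b)
  matches <- rbind(m1, m2)
  matches <- data.frame(wgs_id = matches$id_a, ogm_id = matches$id_b,
                        rule = matches$rule, stringsAsFactors = FALSE)

  rep_idx <- match(matches$wgs_id, wcl$id)
  reported <- wcl[rep_idx, , drop = FALSE]
  if (nrow(reported)) {
    reported$flags <- ifelse(nzchar(reported$flags),
                             paste0(reported$flags, ",OGM_CONFIRMED"),
                             "OGM_CONFIRMED")
  }
  list(
    matches = matches,
    reported = setCalls(wgs, reported),
    wgs_only = setCalls(wgs, wcl[!wcl$id %in% matches$wgs_id, ,
                                 drop = FALSE]),
    ogm_only = setCalls(ogm, ocl[!ocl$id %in% matches$ogm_id, ,
                                 drop = FALSE])
  )
}

#' Reclassify unmatched WGS translocations near OGM insertions
#'
#' A WGS translocation unsupported by OGM whose breakend lies within
#' `tra_ins_window` (100 kb) of an OGM insertion is reinterpreted as an
#' insertion: short reads from the inserted (often repeated) sequence
#' mis-map to another copy elsewhere in the genome and masquerade as a
#' translocation. The reclassified call takes the OGM insertion locus and
#' length and is flagged `RECLASSIFIED_FROM_TRA`. Each OGM insertion
#' consumes at most one translocation, nearest first.
#'
#' @param wgs_only_tra [SVCallSet-class] (or call data.frame) of unmatched
#'   WGS translocations; non-TRA rows pass through untouched.
#' @param ogm_ins [SVCallSet-class] of OGM calls; only insertions are used.
#' @param th an [SVThresholds-class].
#' @return List with `reclassified` and `remaining_tra` call data.frames,
#'   plus `audit` (`tra_id`, `ogm_id`, `distance`).
#' @export
reclassifyTraToIns <- function(wgs_only_tra, ogm_ins, th = svThresholds()) {
  tcl <- if (is(wgs_only_tra, "SVCallSet")) svCalls(wgs_only_tra)
    else wgs_only_tra
  ocl <- if (is(ogm_ins, "SVCallSet")) svCalls(ogm_ins) else ogm_ins
  tra <- tcl[tcl$svtype == "TRA", , drop = FALSE]
  ins <- ocl[ocl$svtype == "INS", , drop = FALSE]
  win <- th["tra_ins_window"]

  pairs <- list()
  for (j in seq_len(nrow(ins))) {
    d1 <- ifelse(tra$chrom1 == ins$chrom1[j],
                 abs(tra$pos1 - ins$pos1[j]), Inf)
    d2 <- ifelse(tra$chrom2 == ins$chrom1[j],
                 abs(tra$pos2 - ins$pos1[j]), Inf)
    d <- pmin(d1, d2)
    sel <- which(d <= win)
    if (length(sel)) {
      pairs[[j]] <- data.frame(id_a = tra$id[sel], id_b = ins$id[j],
                               d = d[sel], stringsAsFactors = FALSE)
    }
  }
  reclass <- emptyCalls(); audit <- data.frame(
    tra_id = character(), ogm_id = character(), distance = numeric(),
    stringsAsFactors = FALSE)
  if (length(pairs)) {
    pairs <- do.call(rbind, pairs)
    kept <- pairs[.greedy1to1(pairs, -pairs$d), , drop = FALSE]
    if (nrow(kept)) {
      tr <- tra[match(kept$id_a, tra$id), , drop = FALSE]
      oi <- ins[match(kept$id_b, ins$id), , drop = FALSE]
      tr$svtype <- "INS"
      tr$chrom1 <- tr$chrom2 <- oi$chrom1
      tr$pos1 <- tr$pos2 <- oi$pos1
      tr$strand1 <- "+"; tr$strand2 <- "-"
      tr$length <- oi$length
      tr$flags <- ifelse(nzchar(tr$flags),
                         paste0(tr$flags, ",RECLASSIFIED_FROM_TRA"),
                         "RECLASSIFIED_FROM_TRA")
      tr$flags <- gsub("INTRA_REARR,?", "", tr$flags)
      rownames(tr) <- NULL
      reclass <- tr
      audit <- data.frame(tra_id = kept$id_a, ogm_id = kept$id_b,
                          distance = kept$d, stringsAsFactors = FALSE)
    }
  }
  remaining <- tra[!tra$id %in% audit$tra_id, , drop = FALSE]
  rownames(remaining) <- NULL
  list(reclassified = reclass, remaining_tra = remaining, audit = audit)
}

#' Per-type concordance between WGS and OGM
#'
#' For each SV type: the number of WGS calls, OGM calls and calls confirmed
#' by both, with `pct_both = 100 * n_both / (n_wgs + n_ogm - n_both)`
#' (union denominator), plus the per-type count of OGM-only calls. An OGM
#' insertion matched to a WGS duplication is counted as a duplication.
#'
#' @param matches match table from [matchCrossTech()].
#' @param wgs,ogm the [SVCallSet-class] inputs that were matched.
#' @return List with `per_type` data.frame (`svtype, n_wgs, n_ogm, n_both,
#'   pct_both, ogm_only`) and `overall` percent.
#' @export
concordanceSummary <- function(matches, wgs, ogm) {
  wcl <- svCalls(wgs); ocl <- svCalls(ogm)
  ## re-annotate OGM INS matched as DUP
  dup_ins <- matches$ogm_id[matches$rule == "DUP_AS_INS"]
  otype <- ifelse(ocl$id %in% dup_ins, "DUP", ocl$svtype)
  mtype <- wcl$svtype[match(matches$wgs_id, wcl$id)]
  per <- do.call(rbind, lapply(.SV_TYPES, function(ty) {
    n_w <- sum(wcl$svtype == ty)
    n_o <- sum(otype == ty)
    n_b <- sum(mtype == ty)
    denom <- n_w + n_o - n_b
    data.frame(svtype = ty, n_wgs = n_w, n_ogm = n_o, n_both = n_b,
               pct_both = if (denom > 0) 100 * n_b / denom else NA_real_,
               ogm_only = n_o - n_b, stringsAsFactors = FALSE)
  }))
  tot_b <- nrow(matches)
  denom <- nrow(wcl) + nrow(ocl) - tot_b
  list(per_type = per,
       overall = if (denom > 0) 100 * tot_b / denom else NA_real_)
}
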