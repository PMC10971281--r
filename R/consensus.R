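## WGS consensus: support filtering, dual-caller merging, gap/centromere
## deletion filtering, and tumor-only germline filtering.

#' Filter WGS calls on read support, size and chromosome
#'
#' Keeps non-translocation calls with at least `min_sr` split reads or
#' `min_pe` paired-end reads; translocations need `min_tra_reads` total
#' supporting reads (split + paired-end). Calls with a known length below
#' `min_sv_size` are dropped, as are calls touching chrY or chrM. The filter
#' is total and idempotent.
#'
#' @param cs a WGS [SVCallSet-class].
#' @param th an [SVThresholds-class].
#' @return Filtered `SVCallSet`; removal counts land in
#'   `metadata(x)$support_filter`.
#' @export
filterSupport <- function(cs, th = svThresholds()) {
  cl <- svCalls(cs)
  if (!nrow(cl)) return(cs)
  is_tra <- cl$svtype == "TRA"
  keep_support <- ifelse(is_tra,
    cl$support_sr + cl$support_pe >= th["min_tra_reads"],
    cl$support_sr >= th["min_sr"] | cl$support_pe >= th["min_pe"])
  keep_size <- is.na(cl$length) | cl$length >= th["min_sv_size"]
  bad_chrom <- c("chrY", "chrM", "chrMT")
  keep_chrom <- !(cl$chrom1 %in% bad_chrom | cl$chrom2 %in% bad_chrom)
  keep <- keep_support & keep_size & keep_chrom
  setCalls(cs, cl[keep, , drop = FALSE],
           metadata = list(support_filter = c(
             input = nrow(cl), low_support = sum(!keep_support),
             too_small = sum(!keep_size), bad_chrom = sum(!keep_chrom),
             kept = sum(keep))))
}

## Greedy 1-to-1 assignment on a candidate-pair table scored descending,
## ties broken by the first caller's id. Returns kept row indices.
.greedy1to1 <- function(pairs, score) {
  if (!nrow(pairs)) return(integer())
  ord <- order(-score, pairs$id_a, pairs$id_b)
  used_a <- used_b <- character()
  keep <- integer()
  for (i in ord) {
    if (pairs$id_a[i] %in% used_a || pairs$id_b[i] %in% used_b) next
    keep <- c(keep, i)
    used_a <- c(used_a, pairs$id_a[i])
    used_b <- c(used_b, pairs$id_b[i])
  }
  keep
}

.roPairs <- function(a, b) {
  ## candidate same-type span pairs with their reciprocal overlap
  if (!nrow(a) || !nrow(b)) {
    return(data.frame(id_a = character(), id_b = character(),
                      ro = numeric()))
  }
  gra <- intervalsAsGRanges(data.frame(chrom = a$chrom1, start = a$pos1,
                                       end = a$pos2))
  grb <- intervalsAsGRanges(data.frame(chrom = b$chrom1, start = b$pos1,
                                       end = b$pos2))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gra, grb))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) {
    return(data.frame(id_a = character(), id_b = character(),
                      ro = numeric()))
  }
  ro <- reciprocalOverlap(a$chrom1[qi], a$pos1[qi], a$pos2[qi],
                          b$chrom1[si], b$pos1[si], b$pos2[si])
  data.frame(id_a = a$id[qi], id_b = b$id[si], ro = ro,
             stringsAsFactors = FALSE)
}

#' Merge LUMPY- and DELLY-style call sets into a WGS consensus
#'
#' Retains events identified by both callers: deletions (and duplications,
#' by the same rule) at reciprocal overlap >= `del_ro`, inversions at
#' >= `inv_ro`, translocations when both breakends lie within
#' `tra_bnd_window` bp under matching strands. Insertions are taken from the
#' DELLY-style set alone (the LUMPY-style caller does not detect
#' insertions). Merged coordinates come from the LUMPY-style call
#' (insertions from DELLY). Matching is greedy 1-to-1 by descending overlap
#' (nearest breakends for translocations), ties broken by the smaller LUMPY
#' id.
#'
#' @param lumpy,delly support-filtered WGS [SVCallSet-class] objects.
#' @param th an [SVThresholds-class].
#' @return An `SVCallSet` with `source = "WGS_MERGED"`;
#'   `metadata(x)$merge_audit` records `(merged_id, lumpy_id, delly_id,
#'   criterion)` per merge (criteria `DEL_RO`, `DUP_RO`, `INV_RO`,
#'   `TRA_BND`, `INS_DELLY`).
#' @export
mergeCallers <- function(lumpy, delly, th = svThresholds()) {
  lcl <- svCalls(lumpy); dcl <- svCalls(delly)
  audit <- list(); merged <- list(); k <- 0L
  add <- function(base, lumpy_id, delly_id, criterion) {
    k <<- k + 1L
    base$id <- sprintf("M%04d", k)
    base$source <- "WGS_MERGED"
    merged[[k]] <<- base
    audit[[k]] <<- data.frame(merged_id = base$id, lumpy_id = lumpy_id,
                              delly_id = delly_id, criterion = criterion,
                              stringsAsFactors = FALSE)
  }

  for (ty in c("DEL", "DUP", "INV")) {
    a <- lcl[lcl$svtype == ty, , drop = FALSE]
    b <- dcl[dcl$svtype == ty, , drop = FALSE]
    pairs <- .roPairs(a, b)
    cut <- if (ty == "INV") th["inv_ro"] else th["del_ro"]
    pairs <- pairs[pairs$ro >= cut, , drop = FALSE]
    for (i in .greedy1to1(pairs, pairs$ro)) {
      add(a[a$id == pairs$id_a[i], , drop = FALSE],
          pairs$id_a[i], pairs$id_b[i], paste0(ty, "_RO"))
    }
  }

  at <- lcl[lcl$svtype == "TRA", , drop = FALSE]
  bt <- dcl[dcl$svtype == "TRA", , drop = FALSE]
  if (nrow(at) && nrow(bt)) {
    cand <- expand.grid(ia = seq_len(nrow(at)), ib = seq_len(nrow(bt)))
    dist <- mapply(function(ia, ib) {
      a <- at[ia, ]; b <- bt[ib, ]
      if (!sameEvent(a, b, th["tra_bnd_window"])) return(NA_real_)
      breakendDistance(a, b)
    }, cand$ia, cand$ib)
    ok <- which(!is.na(dist))
    pairs <- data.frame(id_a = at$id[cand$ia[ok]], id_b = bt$id[cand$ib[ok]],
                        stringsAsFactors = FALSE)
    for (i in .greedy1to1(pairs, -dist[ok])) {
      add(at[at$id == pairs$id_a[i], , drop = FALSE],
          pairs$id_a[i], pairs$id_b[i], "TRA_BND")
    }
  }

  ins <- dcl[dcl$svtype == "INS", , drop = FALSE]
  for (i in seq_len(nrow(ins))) {
    add(ins[i, , drop = FALSE], NA_character_, ins$id[i], "INS_DELLY")
  }

  calls <- if (k) do.call(rbind, merged) else emptyCalls()
  SVCallSet(calls, sample = sampleName(lumpy), technology = "WGS",
            metadata = list(merge_audit = if (k) do.call(rbind, audit)
              else data.frame(merged_id = character(),
                              lumpy_id = character(),
                              delly_id = character(),
                              criterion = character())))
}

#' Remove deletions over assembly gaps and centromeres
#'
#' A deletion is dropped if it has reciprocal overlap >= `gap_ro` with any
#' gap interval padded by `gap_pad` bp, or if it overlaps a centromere
#' interval by at least one base.
#' @param cs merged WGS [SVCallSet-class].
#' @param tracks `ResourceTracks` (uses `gaps` and `centromeres`).
#' @param th an [SVThresholds-class].
#' @return Filtered `SVCallSet` (`metadata(x)$gap_filter` has counts).
#' @export
filterGapCentromere <- function(cs, tracks, th = svThresholds()) {
  cl <- svCalls(cs)
  del <- which(cl$svtype == "DEL")
  if (!length(del)) return(cs)
  drop <- rep(FALSE, length(del))
  gaps <- tracks$gaps
  if (nrow(gaps)) {
    padded <- data.frame(chrom = gaps$chrom,
                         start = pmax(gaps$start - th["gap_pad"], 0),
                         end = gaps$end + th["gap_pad"])
    pairs <- .roPairs(cl[del, , drop = FALSE],
                      data.frame(id = paste0("g", seq_len(nrow(padded))),
                                 svtype = "DEL", chrom1 = padded$chrom,
                                 pos1 = padded$start, pos2 = padded$end,
                                 stringsAsFactors = FALSE))
    hit <- unique(pairs$id_a[pairs$ro >= th["gap_ro"]])
    drop <- drop | cl$id[del] %in% hit
  }
  if (nrow(tracks$centromeres)) {
    gr <- intervalsAsGRanges(tracks$centromeres)
    q <- intervalsAsGRanges(data.frame(chrom = cl$chrom1[del],
                                       start = cl$pos1[del],
                                       end = cl$pos2[del]))
    drop <- drop | suppressWarnings(IRanges::overlapsAny(q, gr))
  }
  keep <- setdiff(seq_len(nrow(cl)), del[drop])
  setCalls(cs, cl[keep, , drop = FALSE],
           metadata = list(gap_filter = c(input = nrow(cl),
                                          removed = sum(drop))))
}

#' Remove likely germline polymorphisms (tumor-only filtering)
#'
#' An intra-chromosomal SV with known length is removed when the control
#' database holds a record of the same type with reciprocal overlap
#' strictly > `ctrl_overlap`, size similarity strictly > `ctrl_size_sim`,
#' and `n_individuals >= ctrl_min_individuals`. Translocations (which
#' population databases do not carry) are screened against an optional
#' control call set via [sameEvent()] with the `tra_bnd_window`.
#' Insertions with unknown length are not size-comparable and are kept.
#'
#' @param cs an [SVCallSet-class] (WGS consensus or OGM).
#' @param db control database data.frame from [readControlDb()].
#' @param th an [SVThresholds-class].
#' @param control_calls optional [SVCallSet-class] of control SVs for
#'   translocation screening.
#' @return Filtered `SVCallSet`; `metadata(x)$germline_removed` logs
#'   `(id, matched)` for each removal.
#' @export
filterGermline <- function(cs, db, th = svThresholds(),
                           control_calls = NULL) {
  cl <- svCalls(cs)
  if (!nrow(cl)) return(cs)
  removed <- data.frame(id = character(), matched = character(),
                        stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(cl))

  cand <- which(cl$svtype %in% c("DEL", "DUP", "INV") & !is.na(cl$length) &
                cl$length > 0)
  if (length(cand) && nrow(db)) {
    dbv <- db[db$end > db$start, , drop = FALSE]
    for (i in cand) {
      same <- dbv[dbv$svtype == cl$svtype[i] &
                  dbv$n_individuals >= th["ctrl_min_individuals"], ,
                  drop = FALSE]
      if (!nrow(same)) next
      ro <- reciprocalOverlap(cl$chrom1[i], cl$pos1[i], cl$pos2[i],
                              same$chrom, same$start, same$end)
      sim <- sizeSimilarity(cl$length[i], same$length)
      hit <- which(ro > th["ctrl_overlap"] & sim > th["ctrl_size_sim"])
      if (length(hit)) {
        drop[i] <- TRUE
        removed <- rbind(removed,
                         data.frame(id = cl$id[i], matched = same$id[hit[1L]],
                                    stringsAsFactors = FALSE))
      }
    }
  }

  if (!is.null(control_calls)) {
    ctl <- svCalls(control_calls)
    tra <- which(cl$svtype == "TRA")
    ctl_tra <- ctl[ctl$svtype == "TRA", , drop = FALSE]
    for (i in tra) {
      for (j in seq_len(nrow(ctl_tra))) {
        if (sameEvent(cl[i, ], ctl_tra[j, ], th["tra_bnd_window"])) {
          drop[i] <- TRUE
          removed <- rbind(removed,
                           data.frame(id = cl$id[i],
                                      matched = ctl_tra$id[j],
                                      stringsAsFactors = FALSE))
          break
        }
      }
    }
  }

  setCalls(cs, cl[!drop, , drop = FALSE],
           metadata = list(germline_removed = removed))
}
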