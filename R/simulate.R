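## Seeded call-set simulator. Produces a truth SV set with resource tracks,
## technology-specific observed call sets (two short-read caller dialects
## and an optical-mapping set), and an RNA fusion table, so every pipeline
## stage can be exercised without external data.
##
## Error-model defaults the underlying study does not quantify (detection
## rates, jitter, support means) are plumbing choices documented in the
## package vignette; physically grounded defaults are the label spacing
## (6,600 bp, i.e. ~15.2 labels/100 kb), the 500 bp optical-mapping
## resolution floor, and the ~50 kb segment limit below which a
## translocated insertion loses its source chromosome.

#' Simulator configuration
#'
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_sv number of background truth SVs (fusion-generating
#'   translocations are added on top).
#' @param type_weights sampling weights over DEL/DUP/INS/INV/TRA.
#' @param size_range intra-chromosomal SV size range (bp), log-uniform.
#' @param repeat_fraction,sparse_fraction genome fraction covered by the
#'   repeat and sparse-label tracks.
#' @param wgs_jitter short-read breakpoint jitter (+/- bp).
#' @param ogm_label_spacing mean distance between optical labels (bp).
#' @param ogm_min_size optical-mapping resolution floor (bp).
#' @param ogm_tra_ins_max segment size below which a translocated insertion
#'   is reported by OGM as an insertion at the acceptor locus (bp).
#' @param wgs_fn,ogm_fn per-call false-negative rates.
#' @param spurious_tra_rate probability that a truth insertion inside a
#'   repeat spawns a false WGS translocation to another repeat copy.
#' @param germline_fraction fraction of background SVs that are germline
#'   polymorphisms (placed in the control database).
#' @param n_genes,gene_size gene track size and per-gene length range.
#' @param n_fusions,fusion_expressed_rate fusion-generating translocations
#'   and the fraction with an expressed transcript.
#' @param tra_segment_range translocated segment size range (bp),
#'   log-uniform.
#' @param support_mean_sr,support_mean_pe,support_mean_mol Poisson means of
#'   read/molecule support.
#' @param rna_mean,rna_size negative-binomial read-count model for
#'   expressed fusions.
#' @return A `SimConfig` list.
#' @export
simConfig <- function(seed = 1L,
                      chrom_lengths = c(chr1 = 4e7, chr2 = 4e7,
                                        chr3 = 4e7, chr4 = 4e7),
                      n_sv = 60L,
                      type_weights = c(DEL = 0.30, DUP = 0.15, INS = 0.25,
                                       INV = 0.10, TRA = 0.20),
                      size_range = c(50, 5e6),
                      repeat_fraction = 0.10, sparse_fraction = 0.02,
                      wgs_jitter = 10, ogm_label_spacing = 6600,
                      ogm_min_size = 500, ogm_tra_ins_max = 5e4,
                      wgs_fn = 0.08, ogm_fn = 0.08,
                      spurious_tra_rate = 0.3, germline_fraction = 0.3,
                      n_genes = 120L, gene_size = c(2e4, 2e5),
                      n_fusions = 6L, fusion_expressed_rate = 0.7,
                      tra_segment_range = c(1e3, 2e5),
                      support_mean_sr = 8, support_mean_pe = 8,
                      support_mean_mol = 20,
                      rna_mean = 50, rna_size = 10) {
  stopifnot(abs(sum(type_weights) - 1) < 1e-8,
            all(names(type_weights) == .SV_TYPES))
  cfg <- as.list(environment())
  class(cfg) <- c("SimConfig", "list")
  cfg
}

.logUnif <- function(n, range) {
  exp(stats::runif(n, log(range[1L]), log(range[2L])))
}

.pickPos <- function(cfg) {
  p <- cfg$chrom_lengths / sum(cfg$chrom_lengths)
  chrom <- sample(names(cfg$chrom_lengths), 1L, prob = p)
  list(chrom = chrom, len = cfg$chrom_lengths[[chrom]])
}

## interval track with exact per-chromosome coverage: draw interval
## lengths until the target is met (last one truncated), then distribute
## the leftover space as exponential gaps rescaled to fit the chromosome
.coverTrack <- function(cfg, fraction, size_range) {
  out <- list()
  for (chrom in names(cfg$chrom_lengths)) {
    L <- cfg$chrom_lengths[[chrom]]
    target <- round(L * fraction)
    if (target <= 0) next
    lens <- numeric()
    while (sum(lens) < target) {
      lens <- c(lens, round(.logUnif(min(64L, max(1L,
        ceiling((target - sum(lens)) / mean(size_range)))), size_range)))
    }
    over <- sum(lens) - target
    lens[length(lens)] <- lens[length(lens)] - over
    lens <- lens[lens >= 1]
    n <- length(lens)
    gaps <- stats::rexp(n + 1L)
    gaps <- gaps / sum(gaps) * (L - sum(lens))
    start <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(lens))[seq_len(n)]
    start <- round(start)
    out[[chrom]] <- data.frame(chrom = chrom, start = start,
                               end = start + lens,
                               stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  df
}

.overlapsOccupied <- function(chrom, start, end, occ) {
  if (!nrow(occ)) return(FALSE)
  any(occ$chrom == chrom & occ$start < end & occ$end > start)
}

#' Simulate a truth set
#'
#' Generates non-overlapping truth SVs (with germline polymorphisms and
#' fusion-generating translocations), resource tracks (repeats,
#' sparse-label regions, assembly gaps, centromeres, genes), a control
#' database holding the germline intra-chromosomal SVs, a control
#' translocation call set, and truth fusions. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [simConfig()] list.
#' @return A `TruthSet` list: `svs`, `fusions`, `tracks`, `control_db`,
#'   `control_calls`, `config`.
#' @export
simulateTruth <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  tracks <- list()
  tracks$centromeres <- do.call(rbind, lapply(names(cfg$chrom_lengths),
    function(ch) {
      mid <- cfg$chrom_lengths[[ch]] / 2
      data.frame(chrom = ch, start = round(mid - 250e3),
                 end = round(mid + 250e3), stringsAsFactors = FALSE)
    }))
  tracks$gaps <- do.call(rbind, lapply(names(cfg$chrom_lengths),
    function(ch) {
      L <- cfg$chrom_lengths[[ch]]
      w <- round(.logUnif(2L, c(2e4, 8e4)))
      s <- round(stats::runif(2L, 0, L - max(w)))
      data.frame(chrom = ch, start = s, end = s + w,
                 stringsAsFactors = FALSE)
    }))
  tracks$repeats <- .coverTrack(cfg, cfg$repeat_fraction, c(200, 5000))
  tracks$sparse <- .coverTrack(cfg, cfg$sparse_fraction, c(5e4, 5e5))

  occupied <- rbind(tracks$centromeres, tracks$gaps)

  ## gene track
  genes <- list(); gocc <- occupied
  for (i in seq_len(cfg$n_genes)) {
    for (try in 1:200) {
      w <- round(.logUnif(1L, cfg$gene_size))
      at <- .pickPos(cfg)
      s <- round(stats::runif(1L, 0, at$len - w))
      if (!.overlapsOccupied(at$chrom, s, s + w, gocc)) {
        g <- data.frame(chrom = at$chrom, start = s, end = s + w,
                        name = sprintf("GENE%03d", i),
                        strand = sample(c("+", "-"), 1L),
                        stringsAsFactors = FALSE)
        genes[[i]] <- g
        gocc <- rbind(gocc, g[, c("chrom", "start", "end")])
        break
      }
      if (try == 200) stop("infeasible packing: gene track")
    }
  }
  tracks$genes <- do.call(rbind, genes)

  svs <- list(); k <- 0L
  addsv <- function(row) {
    k <<- k + 1L
    row$id <- sprintf("T%04d", k)
    svs[[k]] <<- row
    occupied <<- rbind(occupied,
      data.frame(chrom = c(row$chrom1, row$chrom2),
                 start = pmax(c(row$pos1, row$pos2) - 1000, 0),
                 end = c(ifelse(row$svtype %in% c("DEL", "DUP", "INV"),
                                row$pos2, row$pos1),
                         row$pos2) + 1000, stringsAsFactors = FALSE))
  }

  ## fusion-generating translocations: breakends inside two genes on
  ## different chromosomes; most orientation-compatible, some inverted
  fus <- list()
  gtab <- tracks$genes
  for (f in seq_len(cfg$n_fusions)) {
    for (try in 1:200) {
      pair <- gtab[sample(nrow(gtab), 2L), ]
      if (pair$chrom[1L] == pair$chrom[2L]) next
      p1 <- round(stats::runif(1L, pair$start[1L] + 1, pair$end[1L] - 1))
      p2 <- round(stats::runif(1L, pair$start[2L] + 1, pair$end[2L] - 1))
      if (.overlapsOccupied(pair$chrom[1L], p1, p1 + 1, occupied) ||
          .overlapsOccupied(pair$chrom[2L], p2, p2 + 1, occupied)) next
      compatible <- stats::runif(1L) < 0.8
      s1 <- pair$strand[1L]
      s2 <- if (compatible) chartr("+-", "-+", pair$strand[2L])
        else pair$strand[2L]
      ## fusion junctions move gene-scale segments, large enough for OGM
      ## to trace the source chromosome
      seg <- round(.logUnif(1L, c(max(cfg$ogm_tra_ins_max * 2,
                                      cfg$tra_segment_range[1L]), 1e6)))
      ord <- order(c(pair$chrom[1L], pair$chrom[2L]),
                   c(p1, p2))
      row <- data.frame(
        svtype = "TRA",
        chrom1 = pair$chrom[ord[1L]], pos1 = c(p1, p2)[ord[1L]],
        strand1 = c(s1, s2)[ord[1L]],
        chrom2 = pair$chrom[ord[2L]], pos2 = c(p1, p2)[ord[2L]],
        strand2 = c(s1, s2)[ord[2L]],
        length = NA_real_, tra_segment = seg, germline = FALSE,
        fusion = TRUE, stringsAsFactors = FALSE)
      addsv(row)
      fus[[f]] <- data.frame(
        fusion_id = sprintf("F%02d", f), sv_id = sprintf("T%04d", k),
        gene_a = pair$name[1L], gene_b = pair$name[2L],
        chrom_a = pair$chrom[1L], pos_a = p1,
        chrom_b = pair$chrom[2L], pos_b = p2,
        compatible = compatible,
        expressed = compatible &&
          stats::runif(1L) < cfg$fusion_expressed_rate,
        stringsAsFactors = FALSE)
      break
    }
  }
  fusions <- if (length(fus)) do.call(rbind, fus) else NULL

  ## background SVs
  for (i in seq_len(cfg$n_sv)) {
    ty <- sample(.SV_TYPES, 1L, prob = cfg$type_weights)
    placed <- FALSE
    for (try in 1:500) {
      if (ty == "TRA") {
        a <- .pickPos(cfg); b <- .pickPos(cfg)
        if (a$chrom == b$chrom) next
        p1 <- round(stats::runif(1L, 1, a$len - 1))
        p2 <- round(stats::runif(1L, 1, b$len - 1))
        if (.overlapsOccupied(a$chrom, p1, p1 + 1, occupied) ||
            .overlapsOccupied(b$chrom, p2, p2 + 1, occupied)) next
        ord <- order(c(a$chrom, b$chrom), c(p1, p2))
        sp <- sample(c("+-", "-+", "++", "--"), 1L)
        addsv(data.frame(
          svtype = "TRA",
          chrom1 = c(a$chrom, b$chrom)[ord[1L]],
          pos1 = c(p1, p2)[ord[1L]], strand1 = substr(sp, 1, 1),
          chrom2 = c(a$chrom, b$chrom)[ord[2L]],
          pos2 = c(p1, p2)[ord[2L]], strand2 = substr(sp, 2, 2),
          length = NA_real_,
          tra_segment = round(.logUnif(1L, cfg$tra_segment_range)),
          germline = FALSE, fusion = FALSE, stringsAsFactors = FALSE))
      } else {
        w <- round(.logUnif(1L, cfg$size_range))
        at <- .pickPos(cfg)
        if (at$len <= w + 2) next
        s <- round(stats::runif(1L, 1, at$len - w - 1))
        e <- if (ty == "INS") s else s + w
        if (.overlapsOccupied(at$chrom, s, max(e, s + 1), occupied)) next
        sp <- normalizeStrand(ty, "WGS")[1L]
        addsv(data.frame(
          svtype = ty, chrom1 = at$chrom, pos1 = s,
          strand1 = substr(sp, 1, 1), chrom2 = at$chrom, pos2 = e,
          strand2 = substr(sp, 2, 2), length = w,
          tra_segment = NA_real_,
          germline = stats::runif(1L) < cfg$germline_fraction,
          fusion = FALSE, stringsAsFactors = FALSE))
      }
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible packing: too many SVs for the genome")
  }
  svs <- do.call(rbind, svs)
  svs <- svs[, c("id", setdiff(names(svs), "id"))]
  rownames(svs) <- NULL

  germ <- svs[svs$germline & svs$svtype %in% c("DEL", "DUP", "INV"), ,
              drop = FALSE]
  control_db <- if (nrow(germ)) data.frame(
    id = paste0("ctrl_", germ$id), chrom = germ$chrom1, start = germ$pos1,
    end = germ$pos2, svtype = germ$svtype, length = germ$length,
    n_individuals = sample(5:30, nrow(germ), replace = TRUE),
    stringsAsFactors = FALSE)
  else data.frame(id = character(), chrom = character(), start = numeric(),
                  end = numeric(), svtype = character(), length = numeric(),
                  n_individuals = integer(), stringsAsFactors = FALSE)
  ## germline TRAs cannot live in an interval database; they form a
  ## control call set screened by breakend identity
  gtra <- svs[svs$germline & svs$svtype == "TRA", , drop = FALSE]
  control_calls <- SVCallSet(if (nrow(gtra)) data.frame(
    id = paste0("ctrl_", gtra$id), svtype = "TRA", chrom1 = gtra$chrom1,
    pos1 = gtra$pos1, strand1 = gtra$strand1, chrom2 = gtra$chrom2,
    pos2 = gtra$pos2, strand2 = gtra$strand2, length = NA_real_,
    support_sr = 0L, support_pe = 0L, support_mol = 0L, source = "OGM",
    sample = "controls", flags = "", stringsAsFactors = FALSE)
    else emptyCalls(), sample = "controls", technology = "OGM")

  structure(list(svs = svs, fusions = fusions, tracks = tracks,
                 control_db = control_db, control_calls = control_calls,
                 config = cfg),
            class = c("TruthSet", "list"))
}

.jitter1 <- function(pos, j) {
  if (j <= 0) return(pos)
  pmax(pos + round(stats::runif(length(pos), -j, j)), 0)
}

#' Observe the truth through a short-read caller
#'
#' Applies per-call detection, breakpoint jitter and Poisson read support.
#' The LUMPY-style caller emits no insertions. Insertion lengths are
#' unknown (`NA`) as short-read callers cannot size them. Additionally,
#' truth insertions inside repeat intervals may spawn a spurious
#' translocation to another repeat copy (short reads from the inserted
#' repeat mis-mapping elsewhere); spurious events are shared between the
#' two callers, as the error is in the mapping, not the caller.
#'
#' @param truth a [simulateTruth()] result.
#' @param cfg the [simConfig()] used.
#' @param caller `"lumpy"` or `"delly"`.
#' @return An [SVCallSet-class] (`technology = "WGS"`); metadata carries
#'   `truth_id` per call (`NA` for spurious calls).
#' @export
observeWgs <- function(truth, cfg = truth$config,
                       caller = c("lumpy", "delly")) {
  caller <- match.arg(caller)
  svs <- truth$svs
  rep_track <- truth$tracks$repeats

  ## spurious translocations: shared between callers (same mapping error)
  set.seed(cfg$seed + 10L)
  spurious <- list(); ns <- 0L
  ins <- svs[svs$svtype == "INS", , drop = FALSE]
  for (i in seq_len(nrow(ins))) {
    hit <- which(rep_track$chrom == ins$chrom1[i] &
                 rep_track$start <= ins$pos1[i] &
                 rep_track$end > ins$pos1[i])
    if (!length(hit)) next
    if (stats::runif(1L) >= cfg$spurious_tra_rate) next
    other <- rep_track[-hit[1L], , drop = FALSE]
    other <- other[other$chrom != ins$chrom1[i], , drop = FALSE]
    if (!nrow(other)) next
    tgt <- other[sample(nrow(other), 1L), ]
    p2 <- round(stats::runif(1L, tgt$start, tgt$end - 1))
    ord <- order(c(ins$chrom1[i], tgt$chrom), c(ins$pos1[i], p2))
    ns <- ns + 1L
    spurious[[ns]] <- data.frame(
      svtype = "TRA",
      chrom1 = c(ins$chrom1[i], tgt$chrom)[ord[1L]],
      pos1 = c(ins$pos1[i], p2)[ord[1L]], strand1 = "+",
      chrom2 = c(ins$chrom1[i], tgt$chrom)[ord[2L]],
      pos2 = c(ins$pos1[i], p2)[ord[2L]], strand2 = "-",
      truth_id = NA_character_, stringsAsFactors = FALSE)
  }

  set.seed(cfg$seed + if (caller == "lumpy") 101L else 102L)
  keep <- stats::runif(nrow(svs)) >= cfg$wgs_fn
  if (caller == "lumpy") keep <- keep & svs$svtype != "INS"
  obs <- svs[keep, , drop = FALSE]

  mk <- function(df, prefix) {
    n <- nrow(df)
    if (!n) return(emptyCalls())
    pos1 <- .jitter1(df$pos1, cfg$wgs_jitter)
    pos2 <- ifelse(df$svtype == "INS", pos1,
                   .jitter1(df$pos2, cfg$wgs_jitter))
    intra <- df$svtype %in% c("DEL", "DUP", "INV")
    swap <- intra & pos1 > pos2
    t1 <- pos1; pos1 <- ifelse(swap, pos2, pos1)
    pos2 <- ifelse(swap, t1, pos2)
    is_tra <- df$svtype == "TRA"
    sr <- stats::rpois(n, cfg$support_mean_sr)
    pe <- stats::rpois(n, cfg$support_mean_pe)
    data.frame(
      id = sprintf("%s%04d", prefix, seq_len(n)), svtype = df$svtype,
      chrom1 = df$chrom1, pos1 = pos1, strand1 = df$strand1,
      chrom2 = df$chrom2, pos2 = pos2, strand2 = df$strand2,
      length = ifelse(intra, pos2 - pos1, NA_real_),
      support_sr = sr, support_pe = pe, support_mol = 0L,
      source = toupper(caller), sample = "sim", flags = "",
      truth_id = df$truth_id, stringsAsFactors = FALSE)
  }
  obs$truth_id <- obs$id
  obs$strand1 <- ifelse(obs$svtype == "TRA", obs$strand1,
                        substr(vapply(obs$svtype, function(t)
                          normalizeStrand(t, "WGS")[1L], character(1)),
                          1, 1))
  obs$strand2 <- ifelse(obs$svtype == "TRA", obs$strand2,
                        substr(vapply(obs$svtype, function(t)
                          normalizeStrand(t, "WGS")[1L], character(1)),
                          2, 2))
  rows <- obs[, c("svtype", "chrom1", "pos1", "strand1", "chrom2", "pos2",
                  "strand2", "truth_id")]
  if (ns) {
    rows <- rbind(rows, do.call(rbind, spurious))
  }
  prefix <- if (caller == "lumpy") "L" else "D"
  calls <- mk(rows, prefix)
  truth_id <- calls$truth_id
  calls$truth_id <- NULL
  SVCallSet(calls, sample = "sim", technology = "WGS",
            metadata = list(truth_id = stats::setNames(truth_id, calls$id)))
}

.snapNearest <- function(pos, s) round(pos / s) * s
.snapDown <- function(pos, s) floor(pos / s) * s
.snapUp <- function(pos, s) ceiling(pos / s) * s

#' Observe the truth through optical genome mapping
#'
#' SVs below the resolution floor (`ogm_min_size`, 500 bp) are dropped, as
#' are SVs with a breakend inside a sparse-label region. Intra-chromosomal
#' spans are reported bracketed by the flanking labels (start snapped down,
#' end snapped up to the label grid) while the label-derived SV size stays
#' accurate; insertion loci and translocation breakends snap to the nearest
#' label. A translocation whose moved segment is smaller than
#' `ogm_tra_ins_max` (50 kb) cannot be traced to its source chromosome and
#' is reported as an insertion at the acceptor locus instead.
#'
#' @param truth a [simulateTruth()] result.
#' @param cfg the [simConfig()] used.
#' @return An [SVCallSet-class] (`technology = "OGM"`); metadata carries
#'   `truth_id` per call.
#' @export
observeOgm <- function(truth, cfg = truth$config) {
  set.seed(cfg$seed + 103L)
  svs <- truth$svs
  s <- cfg$ogm_label_spacing
  sparse <- truth$tracks$sparse
  in_sparse <- function(chrom, pos) .inTrack(chrom, pos, sparse)

  keep <- stats::runif(nrow(svs)) >= cfg$ogm_fn
  keep <- keep & (is.na(svs$length) | svs$length >= cfg$ogm_min_size)
  keep <- keep & !(in_sparse(svs$chrom1, svs$pos1) |
                   in_sparse(svs$chrom2, svs$pos2))
  obs <- svs[keep, , drop = FALSE]
  n <- nrow(obs)
  if (!n) return(SVCallSet(sample = "sim", technology = "OGM"))

  out <- lapply(seq_len(n), function(i) {
    r <- obs[i, ]
    if (r$svtype == "TRA" && r$tra_segment < cfg$ogm_tra_ins_max) {
      ## source segment too short to map: insertion at the acceptor
      data.frame(svtype = "INS", chrom1 = r$chrom1,
                 pos1 = .snapNearest(r$pos1, s), strand1 = "+",
                 chrom2 = r$chrom1, pos2 = .snapNearest(r$pos1, s),
                 strand2 = "-", length = r$tra_segment,
                 truth_id = r$id, stringsAsFactors = FALSE)
    } else if (r$svtype == "TRA") {
      data.frame(svtype = "TRA", chrom1 = r$chrom1,
                 pos1 = .snapNearest(r$pos1, s), strand1 = r$strand1,
                 chrom2 = r$chrom2, pos2 = .snapNearest(r$pos2, s),
                 strand2 = r$strand2, length = NA_real_,
                 truth_id = r$id, stringsAsFactors = FALSE)
    } else if (r$svtype == "INS") {
      p <- .snapNearest(r$pos1, s)
      data.frame(svtype = "INS", chrom1 = r$chrom1, pos1 = p,
                 strand1 = "+", chrom2 = r$chrom1, pos2 = p,
                 strand2 = "-", length = r$length, truth_id = r$id,
                 stringsAsFactors = FALSE)
    } else {
      sp <- normalizeStrand(r$svtype, "OGM")[1L]
      data.frame(svtype = r$svtype, chrom1 = r$chrom1,
                 pos1 = .snapDown(r$pos1, s),
                 strand1 = substr(sp, 1, 1), chrom2 = r$chrom1,
                 pos2 = .snapUp(r$pos2, s), strand2 = substr(sp, 2, 2),
                 length = r$length, truth_id = r$id,
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, out)
  calls <- data.frame(
    id = sprintf("O%04d", seq_len(n)), svtype = df$svtype,
    chrom1 = df$chrom1, pos1 = df$pos1, strand1 = df$strand1,
    chrom2 = df$chrom2, pos2 = df$pos2, strand2 = df$strand2,
    length = df$length, support_sr = 0L, support_pe = 0L,
    support_mol = stats::rpois(n, cfg$support_mean_mol),
    source = "OGM", sample = "sim", flags = "", stringsAsFactors = FALSE)
  SVCallSet(calls, sample = "sim", technology = "OGM",
            metadata = list(truth_id = stats::setNames(df$truth_id,
                                                       calls$id)))
}

#' Observe truth fusions through RNA-Seq
#'
#' Expressed fusions draw supporting hybrid read counts from a negative
#' binomial (default mean 50); unexpressed fusions get 0-5 stray reads.
#' @param truth a [simulateTruth()] result (or its `fusions` table).
#' @param cfg the [simConfig()] used.
#' @return Fusion candidate data.frame in the [readFusionTable()] layout.
#' @export
observeRna <- function(truth, cfg = truth$config) {
  fus <- if (is.data.frame(truth)) truth else truth$fusions
  if (is.null(fus) || !nrow(fus)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      chrom_a = character(), pos_a = numeric(),
                      chrom_b = character(), pos_b = numeric(),
                      reads = integer(), stringsAsFactors = FALSE))
  }
  set.seed(cfg$seed + 104L)
  reads <- ifelse(fus$expressed,
                  stats::rnbinom(nrow(fus), size = cfg$rna_size,
                                 mu = cfg$rna_mean),
                  sample(0:5, nrow(fus), replace = TRUE))
  data.frame(gene_a = fus$gene_a, gene_b = fus$gene_b,
             chrom_a = fus$chrom_a, pos_a = fus$pos_a,
             chrom_b = fus$chrom_b, pos_b = fus$pos_b,
             reads = as.integer(reads), stringsAsFactors = FALSE)
}

#' Simulate a full dataset (truth plus all observed layers)
#' @param cfg a [simConfig()].
#' @return List with `truth`, `lumpy`, `delly`, `ogm`, `rna`.
#' @export
simulateDataset <- function(cfg = simConfig()) {
  truth <- simulateTruth(cfg)
  list(truth = truth,
       lumpy = observeWgs(truth, cfg, "lumpy"),
       delly = observeWgs(truth, cfg, "delly"),
       ogm = observeOgm(truth, cfg),
       rna = observeRna(truth, cfg))
}
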