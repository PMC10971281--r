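test_that("the simulator is deterministic under a fixed seed", {
  cfg <- smallSimConfig(5)
  expect_identical(simulateTruth(cfg), simulateTruth(cfg))
  s1 <- simulateDataset(cfg)
  s2 <- simulateDataset(cfg)
  expect_identical(svCalls(s1$lumpy), svCalls(s2$lumpy))
  expect_identical(svCalls(s1$ogm), svCalls(s2$ogm))
  expect_identical(s1$rna, s2$rna)
  ## different seed, different data
  expect_false(identical(svCalls(s1$lumpy),
                         svCalls(simulateDataset(smallSimConfig(6))$lumpy)))
})

test_that("type weights control the emitted SV types", {
  cfg <- smallSimConfig(7, type_weights = c(DEL = 1, DUP = 0, INS = 0,
                                            INV = 0, TRA = 0),
                        n_fusions = 0L)
  truth <- simulateTruth(cfg)
  expect_true(all(truth$svs$svtype == "DEL"))
})

test_that("repeat track coverage matches the requested fraction exactly", {
  cfg <- simConfig(seed = 8, chrom_lengths = c(chr1 = 1e7),
                   repeat_fraction = 0.3, n_sv = 5L, n_genes = 10L,
                   n_fusions = 0L, size_range = c(500, 5e4),
                   type_weights = c(DEL = 1, DUP = 0, INS = 0, INV = 0,
                                    TRA = 0))
  truth <- simulateTruth(cfg)
  reps <- truth$tracks$repeats
  cov <- sum(reps$end - reps$start)
  expect_equal(cov, 3e6, tolerance = 0.01)
  ## non-overlapping by construction
  reps <- reps[order(reps$start), ]
  expect_true(all(reps$start[-1] >= reps$end[-nrow(reps)]))
})

test_that("truth SVs are non-overlapping within the genome", {
  truth <- simulateTruth(smallSimConfig(9))
  intra <- truth$svs[truth$svs$svtype %in% c("DEL", "DUP", "INV"), ]
  gr <- intervalsAsGRanges(data.frame(chrom = intra$chrom1,
                                      start = intra$pos1,
                                      end = intra$pos2))
  expect_equal(sum(IRanges::overlapsAny(gr, drop.self = TRUE)), 0L)
})

test_that("zero-noise observation equals truth (minus LUMPY insertions)", {
  cfg <- smallSimConfig(10, wgs_fn = 0, wgs_jitter = 0,
                        spurious_tra_rate = 0)
  truth <- simulateTruth(cfg)
  lum <- svCalls(observeWgs(truth, cfg, "lumpy"))
  del <- svCalls(observeWgs(truth, cfg, "delly"))
  want <- truth$svs
  key <- function(df) sort(paste(df$svtype, df$chrom1, df$pos1,
                                 df$chrom2))
  expect_equal(key(del), key(want))
  expect_equal(key(lum), key(want[want$svtype != "INS", ]))
  expect_true(all(is.na(lum$length[lum$svtype == "INS"])))
})

test_that("insertions in repeats spawn shared spurious translocations at rate 1", {
  cfg <- smallSimConfig(12, spurious_tra_rate = 1,
                        repeat_fraction = 0.5,
                        type_weights = c(DEL = 0, DUP = 0, INS = 1,
                                         INV = 0, TRA = 0),
                        n_fusions = 0L)
  truth <- simulateTruth(cfg)
  reps <- truth$tracks$repeats
  in_rep <- vapply(seq_len(nrow(truth$svs)), function(i) {
    any(reps$chrom == truth$svs$chrom1[i] &
        reps$start <= truth$svs$pos1[i] & reps$end > truth$svs$pos1[i])
  }, logical(1))
  expect_gt(sum(in_rep), 0)
  lum <- observeWgs(truth, cfg, "lumpy")
  del <- observeWgs(truth, cfg, "delly")
  spur_l <- svCalls(lum)[svCalls(lum)$svtype == "TRA", ]
  spur_d <- svCalls(del)[svCalls(del)$svtype == "TRA", ]
  ## truth has no TRA, so every observed TRA is spurious and shared
  expect_equal(nrow(spur_l), sum(in_rep))
  expect_equal(nrow(spur_d), nrow(spur_l))
  ## the partner breakend lands in a repeat copy on another chromosome
  for (i in seq_len(nrow(spur_l))) {
    r <- spur_l[i, ]
    hit1 <- any(reps$chrom == r$chrom1 & reps$start <= r$pos1 + 10 &
                reps$end > r$pos1 - 10)
    hit2 <- any(reps$chrom == r$chrom2 & reps$start <= r$pos2 + 10 &
                reps$end > r$pos2 - 10)
    expect_true(hit1 && hit2)
    expect_true(r$chrom1 != r$chrom2)
  }
  ## shared events merge across callers
  m <- mergeCallers(filterSupport(lum), filterSupport(del))
  expect_equal(sum(svCalls(m)$svtype == "TRA"), nrow(spur_l))
})

test_that("read support draws pass the support filter for almost all calls", {
  sim <- simulateDataset(smallSimConfig(13))
  for (cs in list(sim$lumpy, sim$delly)) {
    kept <- length(filterSupport(cs)) / length(cs)
    ## Poisson(8) support: P(SR<3 and PE<3) ~ 2e-4 per call
    expect_gte(kept, 0.95)
  }
})

test_that("optical mapping drops sub-500 bp SVs and sparse-region breakends", {
  cfg <- smallSimConfig(14, ogm_fn = 0, size_range = c(50, 1e5))
  truth <- simulateTruth(cfg)
  ogm <- observeOgm(truth, cfg)
  tid <- metadata(ogm)$truth_id
  small <- truth$svs$id[!is.na(truth$svs$length) &
                        truth$svs$length < 500]
  expect_gt(length(small), 0)
  expect_false(any(small %in% tid))
  sparse <- truth$tracks$sparse
  for (id in tid) {
    r <- truth$svs[truth$svs$id == id, ]
    expect_false(any(sparse$chrom == r$chrom1 & sparse$start <= r$pos1 &
                     sparse$end > r$pos1))
  }
})

test_that("short-segment translocations become OGM insertions at the acceptor locus", {
  cfg <- smallSimConfig(15, ogm_fn = 0,
                        type_weights = c(DEL = 0, DUP = 0, INS = 0,
                                         INV = 0, TRA = 1),
                        n_fusions = 0L)
  truth <- simulateTruth(cfg)
  ogm <- observeOgm(truth, cfg)
  ocl <- svCalls(ogm)
  tid <- metadata(ogm)$truth_id
  short <- truth$svs[truth$svs$tra_segment < cfg$ogm_tra_ins_max, ]
  seen_short <- ocl[match(intersect(short$id, tid), tid), ]
  expect_gt(nrow(seen_short), 0)
  expect_true(all(seen_short$svtype == "INS"))
  for (i in seq_len(nrow(seen_short))) {
    tr <- truth$svs[truth$svs$id == tid[match(seen_short$id[i],
                                              ocl$id)], ]
    expect_equal(seen_short$chrom1[i], tr$chrom1)
    expect_lte(abs(seen_short$pos1[i] - tr$pos1),
               cfg$ogm_label_spacing / 2)
    expect_equal(seen_short$length[i], tr$tra_segment)
  }
  long <- truth$svs[truth$svs$tra_segment >= cfg$ogm_tra_ins_max, ]
  seen_long <- ocl[ocl$id %in% names(tid)[tid %in% long$id], ]
  expect_true(all(seen_long$svtype == "TRA"))
})

test_that("label snapping offsets match the bracketing model's expectation", {
  cfg <- simConfig(seed = 16, chrom_lengths = c(chr1 = 5e7, chr2 = 5e7),
                   n_sv = 80L, n_genes = 20L, n_fusions = 0L,
                   ogm_fn = 0, sparse_fraction = 0,
                   size_range = c(1e4, 1e6),
                   type_weights = c(DEL = 1, DUP = 0, INS = 0, INV = 0,
                                    TRA = 0))
  truth <- simulateTruth(cfg)
  ogm <- observeOgm(truth, cfg)
  ocl <- svCalls(ogm)
  tid <- metadata(ogm)$truth_id
  tr <- truth$svs[match(tid, truth$svs$id), ]
  off1 <- tr$pos1 - ocl$pos1   # start snapped down: non-negative
  off2 <- ocl$pos2 - tr$pos2   # end snapped up: non-negative
  expect_true(all(off1 >= 0 & off1 < cfg$ogm_label_spacing))
  expect_true(all(off2 >= 0 & off2 < cfg$ogm_label_spacing))
  ## per-end offset ~ U(0, spacing): mean near spacing/2
  m <- mean(c(off1, off2))
  expect_gt(m, 0.3 * cfg$ogm_label_spacing)
  expect_lt(m, 0.7 * cfg$ogm_label_spacing)
  ## the reported size stays the accurate truth size, not the bracket span
  expect_equal(ocl$length, tr$length)
})

test_that("RNA read counts separate expressed from unexpressed fusions", {
  counts <- integer(); expr <- logical()
  for (seed in 1:6) {
    sim <- simulateDataset(smallSimConfig(seed, n_fusions = 4L))
    if (is.null(sim$truth$fusions)) next
    counts <- c(counts, sim$rna$reads)
    expr <- c(expr, sim$truth$fusions$expressed)
  }
  expect_true(all(counts[!expr] <= 5))
  ## NB(mu = 50, size = 10): P(reads >= 16) ~ 0.995 per fusion
  expect_gte(mean(counts[expr] >= 16), 0.9)
  expect_gt(mean(counts[expr]), 16)
  ## empty fusion list gives an empty table
  none <- simulateDataset(smallSimConfig(3, n_fusions = 0L))
  expect_equal(nrow(none$rna), 0L)
})
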