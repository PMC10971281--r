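test_that("support filter applies read, size and chromosome rules", {
  cs <- mkSet(
    mkCall("k1", "DEL", "chr1", 1000, 2000, sr = 3L, pe = 0L),
    mkCall("k2", "DEL", "chr1", 5000, 6000, sr = 0L, pe = 3L),
    mkCall("d1", "DEL", "chr1", 9000, 9600, sr = 2L, pe = 2L),
    mkCall("t1", "TRA", "chr1", 100, 200, chrom2 = "chr2", sr = 2L,
           pe = 2L),
    mkCall("t2", "TRA", "chr1", 300, 400, chrom2 = "chr2", sr = 2L,
           pe = 3L),
    mkCall("d2", "DEL", "chr1", 20000, 20049, sr = 10L, pe = 10L),
    mkCall("y1", "DEL", "chrY", 1000, 2000, sr = 10L, pe = 10L)
  )
  kept <- svCalls(filterSupport(cs))$id
  expect_setequal(kept, c("k1", "k2", "t2"))
})

test_that("support filter is idempotent", {
  sim <- simulateDataset(smallSimConfig(21))
  once <- filterSupport(sim$delly)
  twice <- filterSupport(once)
  expect_equal(svCalls(once), svCalls(twice))
})

test_that("caller merge applies type-specific rules with LUMPY coordinates", {
  lumpy <- mkSet(
    mkCall("L1", "DEL", "chr1", 0, 1000),
    mkCall("L2", "INV", "chr2", 0, 1000),
    mkCall("L3", "TRA", "chr3", 1000, 2000, chrom2 = "chr4",
           strands = "+-"),
    mkCall("L4", "TRA", "chr3", 50000, 60000, chrom2 = "chr4",
           strands = "++"))
  delly <- mkSet(
    mkCall("D1", "DEL", "chr1", 400, 1400, source = "DELLY"),
    mkCall("D2", "INV", "chr2", 100, 1100, source = "DELLY"),
    mkCall("D3", "TRA", "chr3", 1050, 1950, chrom2 = "chr4",
           strands = "+-", source = "DELLY"),
    mkCall("D4", "TRA", "chr3", 50051, 60000, chrom2 = "chr4",
           strands = "++", source = "DELLY"),
    mkCall("D5", "INS", "chr1", 9000, 9000, source = "DELLY"))
  m <- mergeCallers(lumpy, delly)
  cl <- svCalls(m)
  aud <- metadata(m)$merge_audit
  ## DEL: RO = 600/1000 = 0.6 >= 0.5, coordinates from LUMPY
  del <- cl[cl$svtype == "DEL", ]
  expect_equal(nrow(del), 1L)
  expect_equal(c(del$pos1, del$pos2), c(0, 1000))
  ## INV: RO = 900/1000 = 0.9, boundary inclusive
  expect_equal(sum(cl$svtype == "INV"), 1L)
  ## TRA: both ends within 50 bp match; 51 bp does not
  expect_equal(aud$lumpy_id[aud$criterion == "TRA_BND"], "L3")
  ## INS comes from DELLY alone
  ins <- cl[cl$svtype == "INS", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(aud$delly_id[aud$criterion == "INS_DELLY"], "D5")
  expect_true(all(cl$source == "WGS_MERGED"))
})

test_that("inversions below RO 0.9 and strand-discordant translocations do not merge", {
  lumpy <- mkSet(mkCall("L1", "INV", "chr2", 0, 1000),
                 mkCall("L2", "TRA", "chr3", 1000, 2000, chrom2 = "chr4",
                        strands = "+-"))
  delly <- mkSet(mkCall("D1", "INV", "chr2", 150, 1150, source = "DELLY"),
                 mkCall("D2", "TRA", "chr3", 1000, 2000, chrom2 = "chr4",
                        strands = "++", source = "DELLY"))
  expect_equal(length(mergeCallers(lumpy, delly)), 0L)
})

test_that("merge size is bounded and every merged record has a valid witness", {
  th <- svThresholds()
  for (seed in c(31, 32, 33)) {
    sim <- simulateDataset(smallSimConfig(seed))
    l <- filterSupport(sim$lumpy); d <- filterSupport(sim$delly)
    m <- mergeCallers(l, d, th)
    lcl <- svCalls(l); dcl <- svCalls(d)
    n_ins <- sum(dcl$svtype == "INS")
    expect_lte(length(m), min(sum(lcl$svtype != "INS"),
                              sum(dcl$svtype != "INS")) + n_ins)
    aud <- metadata(m)$merge_audit
    for (i in seq_len(nrow(aud))) {
      if (aud$criterion[i] == "INS_DELLY") next
      a <- lcl[lcl$id == aud$lumpy_id[i], ]
      b <- dcl[dcl$id == aud$delly_id[i], ]
      if (aud$criterion[i] == "TRA_BND") {
        expect_true(sameEvent(a, b, th["tra_bnd_window"]))
      } else {
        ro <- reciprocalOverlap(a$chrom1, a$pos1, a$pos2,
                                b$chrom1, b$pos1, b$pos2)
        expect_gte(ro, if (aud$criterion[i] == "INV_RO") 0.9 else 0.5)
      }
    }
    ## each input call used at most once
    expect_false(anyDuplicated(stats::na.omit(aud$lumpy_id)) > 0)
    expect_false(anyDuplicated(stats::na.omit(aud$delly_id)) > 0)
  }
})

test_that("zero-noise merge recovers exactly the truth seen by both callers", {
  cfg <- smallSimConfig(41, wgs_fn = 0, wgs_jitter = 0,
                        spurious_tra_rate = 0)
  sim <- simulateDataset(cfg)
  m <- mergeCallers(filterSupport(sim$lumpy), filterSupport(sim$delly))
  truth <- sim$truth$svs
  cl <- svCalls(m)
  expect_equal(nrow(cl), nrow(truth))
  key <- function(df, p1, p2) {
    sort(paste(df$svtype, df$chrom1, p1, df$chrom2, p2))
  }
  expect_equal(key(cl, cl$pos1, cl$pos2),
               key(truth, truth$pos1,
                   ifelse(truth$svtype == "INS", truth$pos1, truth$pos2)))
})

test_that("gap and centromere deletion filters follow the padded-RO and any-overlap rules", {
  tracks <- emptyTracks()
  tracks$gaps <- data.frame(chrom = "chr1", start = 10000, end = 20000)
  tracks$centromeres <- data.frame(chrom = "chr2", start = 5e6, end = 6e6)
  cs <- mkSet(
    mkCall("g1", "DEL", "chr1", 10000, 20000, source = "WGS_MERGED"),
    mkCall("c1", "DEL", "chr2", 4990000, 5000001,
           source = "WGS_MERGED"),
    mkCall("ok", "DEL", "chr1", 40000, 50000, source = "WGS_MERGED"),
    mkCall("tra", "TRA", "chr1", 10000, 1000, chrom2 = "chr3",
           source = "WGS_MERGED"))
  out <- filterGapCentromere(cs, tracks)
  expect_setequal(svCalls(out)$id, c("ok", "tra"))
  ## idempotent
  expect_equal(svCalls(filterGapCentromere(out, tracks)), svCalls(out))
})

test_that("germline filter needs >50% overlap, >70% size similarity and >=5 individuals", {
  db <- data.frame(
    id = c("p5", "p4", "half"),
    chrom = c("chr1", "chr2", "chr3"),
    start = c(1000, 1000, 0), end = c(2000, 2000, 1000),
    svtype = "DEL", length = c(1000, 1000, 1000),
    n_individuals = c(5L, 4L, 20L), stringsAsFactors = FALSE)
  cs <- mkSet(
    mkCall("v5", "DEL", "chr1", 1000, 2000, source = "WGS_MERGED"),
    mkCall("v4", "DEL", "chr2", 1000, 2000, source = "WGS_MERGED"),
    mkCall("vhalf", "DEL", "chr3", 500, 1500, source = "WGS_MERGED"))
  out <- filterGermline(cs, db)
  ## v5 matches a >=5-individual record; v4 fails the individual count;
  ## vhalf has RO exactly 0.5, not strictly greater
  expect_setequal(svCalls(out)$id, c("v4", "vhalf"))
  log <- metadata(out)$germline_removed
  expect_equal(log$id, "v5")
  expect_equal(log$matched, "p5")
  expect_equal(svCalls(filterGermline(out, db)), svCalls(out))
})

test_that("germline translocations are screened against a control call set", {
  ctrl <- mkSet(mkCall("c1", "TRA", "chr1", 1000, 2000, chrom2 = "chr2",
                       strands = "+-"), technology = "OGM")
  cs <- mkSet(
    mkCall("t1", "TRA", "chr1", 1030, 1980, chrom2 = "chr2",
           strands = "+-", source = "WGS_MERGED"),
    mkCall("t2", "TRA", "chr1", 5000, 9000, chrom2 = "chr2",
           strands = "+-", source = "WGS_MERGED"))
  out <- filterGermline(cs, db = data.frame(), control_calls = ctrl)
  expect_equal(svCalls(out)$id, "t2")
})
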