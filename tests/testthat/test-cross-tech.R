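test_that("deletion matching needs WGS-anchored coverage and the size-ratio band", {
  wgs <- mkSet(mkCall("W1", "DEL", "chr1", 0, 100000,
                      source = "WGS_MERGED"))
  ogm_good <- mkSet(mkCall("O1", "DEL", "chr1", 10000, 110000, mol = 12L,
                           source = "OGM"), technology = "OGM")
  mt <- matchCrossTech(wgs, ogm_good)
  expect_equal(nrow(mt$matches), 1L)
  expect_equal(mt$matches$rule, "DEL_OVERLAP")
  ## reported coordinates are the WGS coordinates
  rep <- svCalls(mt$reported)
  expect_equal(c(rep$pos1, rep$pos2), c(0, 100000))
  expect_true(grepl("OGM_CONFIRMED", rep$flags))

  ## full coverage but OGM size 130% of WGS: rejected
  ogm_big <- mkSet(mkCall("O2", "DEL", "chr1", -0, 130000, mol = 12L,
                          source = "OGM"), technology = "OGM")
  mt2 <- matchCrossTech(wgs, ogm_big)
  expect_equal(nrow(mt2$matches), 0L)
  expect_equal(length(mt2$wgs_only), 1L)
  expect_equal(length(mt2$ogm_only), 1L)
})

test_that("translocations match as the same event within the 500 kb window", {
  wgs <- mkSet(mkCall("W1", "TRA", "chr7", 1e6, 2e6, chrom2 = "chr11",
                      strands = "+-", source = "WGS_MERGED"))
  ogm <- mkSet(mkCall("O1", "TRA", "chr7", 1e6 + 3e5, 2e6 - 4e5,
                      chrom2 = "chr11", strands = "+-", source = "OGM"),
               technology = "OGM")
  mt <- matchCrossTech(wgs, ogm)
  expect_equal(mt$matches$rule, "TRA_WINDOW")

  far <- mkSet(mkCall("O2", "TRA", "chr7", 1e6 + 6e5, 2e6,
                      chrom2 = "chr11", strands = "+-", source = "OGM"),
               technology = "OGM")
  expect_equal(nrow(matchCrossTech(wgs, far)$matches), 0L)
})

test_that("a WGS duplication matches an OGM insertion at the same locus", {
  wgs <- mkSet(mkCall("W1", "DUP", "chr2", 5e6, 5.01e6,
                      source = "WGS_MERGED"))
  ogm <- mkSet(mkCall("O1", "INS", "chr2", 5e6 + 2e4, 5e6 + 2e4,
                      length = 9000, source = "OGM"), technology = "OGM")
  mt <- matchCrossTech(wgs, ogm)
  expect_equal(mt$matches$rule, "DUP_AS_INS")
  ## concordance counts the matched pair as a duplication on both sides
  cs <- concordanceSummary(mt$matches, wgs, ogm)
  dup <- cs$per_type[cs$per_type$svtype == "DUP", ]
  expect_equal(dup$n_both, 1L)
  expect_equal(dup$n_ogm, 1L)
  expect_equal(dup$pct_both, 100)
})

test_that("match output partitions both call sets (seeded simulations)", {
  for (seed in c(51, 52, 53)) {
    sim <- simulateDataset(smallSimConfig(seed))
    wgs <- mergeCallers(filterSupport(sim$lumpy),
                        filterSupport(sim$delly))
    mt <- matchCrossTech(wgs, sim$ogm)
    expect_equal(nrow(mt$matches) + length(mt$wgs_only), length(wgs))
    expect_equal(nrow(mt$matches) + length(mt$ogm_only), length(sim$ogm))
    expect_false(any(svCalls(mt$wgs_only)$id %in% mt$matches$wgs_id))
    expect_false(any(svCalls(mt$ogm_only)$id %in% mt$matches$ogm_id))
    ## 1-to-1
    expect_false(anyDuplicated(mt$matches$wgs_id) > 0)
    expect_false(anyDuplicated(mt$matches$ogm_id) > 0)
  }
})

test_that("translocation reclassification honors the 100 kb window", {
  tra_near <- mkCall("T1", "TRA", "chr5", 1e6, 2e6, chrom2 = "chr8",
                     strands = "+-", source = "WGS_MERGED")
  tra_far <- mkCall("T2", "TRA", "chr5", 4e6, 5e6, chrom2 = "chr8",
                    strands = "+-", source = "WGS_MERGED")
  ins <- mkCall("O1", "INS", "chr5", 1e6 + 5e4, 1e6 + 5e4,
                length = 6100, source = "OGM")
  ins_far <- mkCall("O2", "INS", "chr5", 4e6 + 100001, 4e6 + 100001,
                    length = 6100, source = "OGM")
  rc <- reclassifyTraToIns(mkSet(tra_near, tra_far),
                           mkSet(ins, ins_far, technology = "OGM"))
  expect_equal(rc$audit$tra_id, "T1")
  expect_equal(rc$remaining_tra$id, "T2")
  out <- rc$reclassified
  expect_equal(out$svtype, "INS")
  expect_equal(out$pos1, 1e6 + 5e4)
  expect_equal(out$length, 6100)
  expect_true(grepl("RECLASSIFIED_FROM_TRA", out$flags))
})

test_that("reclassification with no OGM insertions is the identity", {
  tra <- mkSet(mkCall("T1", "TRA", "chr5", 1e6, 2e6, chrom2 = "chr8",
                      strands = "+-", source = "WGS_MERGED"))
  rc <- reclassifyTraToIns(tra, SVCallSet(technology = "OGM"))
  expect_equal(nrow(rc$reclassified), 0L)
  expect_equal(rc$remaining_tra$id, "T1")
})

test_that("reclassification conserves events and each insertion consumes one translocation", {
  for (seed in c(61, 62)) {
    sim <- simulateDataset(smallSimConfig(seed))
    wgs <- mergeCallers(filterSupport(sim$lumpy),
                        filterSupport(sim$delly))
    mt <- matchCrossTech(wgs, sim$ogm)
    rc <- reclassifyTraToIns(mt$wgs_only, sim$ogm)
    n_tra_before <- sum(svCalls(mt$wgs_only)$svtype == "TRA")
    expect_equal(n_tra_before,
                 nrow(rc$remaining_tra) + nrow(rc$reclassified))
    expect_false(anyDuplicated(rc$audit$ogm_id) > 0)
    expect_true(all(rc$audit$distance <= svThresholds()["tra_ins_window"]))
  }
})

test_that("concordance uses the union denominator", {
  wgs <- SVCallSet(do.call(rbind, lapply(1:652, function(i)
    mkCall(paste0("W", i), "TRA", "chr1", i * 1e4, i * 1e4 + 5000,
           chrom2 = "chr2", source = "WGS_MERGED"))))
  ogm <- SVCallSet(do.call(rbind, lapply(1:145, function(i)
    mkCall(paste0("O", i), "TRA", "chr3", i * 1e4, i * 1e4 + 5000,
           chrom2 = "chr4", source = "OGM"))), technology = "OGM")
  matches <- data.frame(wgs_id = paste0("W", 1:18),
                        ogm_id = paste0("O", 1:18),
                        rule = "TRA_WINDOW", stringsAsFactors = FALSE)
  cs <- concordanceSummary(matches, wgs, ogm)
  tra <- cs$per_type[cs$per_type$svtype == "TRA", ]
  expect_equal(tra$n_wgs, 652L)
  expect_equal(tra$n_ogm, 145L)
  expect_equal(tra$n_both, 18L)
  expect_equal(tra$pct_both, 100 * 18 / (652 + 145 - 18), tolerance = 1e-9)
  expect_equal(tra$ogm_only, 127L)
  ## degenerate corners
  one <- mkSet(mkCall("a", "DEL", "chr1", 0, 1000, source = "WGS_MERGED"))
  oneo <- mkSet(mkCall("b", "DEL", "chr1", 0, 1000, source = "OGM"),
                technology = "OGM")
  full <- concordanceSummary(data.frame(wgs_id = "a", ogm_id = "b",
                                        rule = "DEL_OVERLAP"), one, oneo)
  expect_equal(full$overall, 100)
  none <- concordanceSummary(matches[0, ], one, oneo)
  expect_equal(none$overall, 0)
})

test_that("reclassification does not decrease overall concordance", {
  th <- svThresholds()
  for (seed in c(71, 72)) {
    sim <- simulateDataset(smallSimConfig(seed))
    wgs <- mergeCallers(filterSupport(sim$lumpy),
                        filterSupport(sim$delly))
    mt <- matchCrossTech(wgs, sim$ogm, th)
    before <- concordanceSummary(mt$matches, wgs, sim$ogm)$overall
    rc <- reclassifyTraToIns(mt$wgs_only, sim$ogm, th)
    wgs_after <- setCalls(wgs, rbind(
      svCalls(wgs)[!svCalls(wgs)$id %in% rc$audit$tra_id, , drop = FALSE],
      rc$reclassified))
    mt2 <- matchCrossTech(wgs_after, sim$ogm, th)
    after <- concordanceSummary(mt2$matches, wgs_after, sim$ogm)$overall
    expect_gte(after, before)
  }
})
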