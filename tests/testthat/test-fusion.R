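fusion_genes <- data.frame(
  chrom = c("chr9", "chr10", "chr7"),
  start = c(1e6, 2e6, 3e6),
  end = c(1.2e6, 2.2e6, 3.2e6),
  name = c("GENEA", "GENEB", "GENEC"),
  strand = c("+", "+", "-"),
  stringsAsFactors = FALSE)

test_that("a translocation inside two genes yields a candidate with orientation", {
  ## GENEA(+) keeps its 5' arm ('+' breakend), GENEB(+) its 3' arm ('-')
  compat <- mkSet(mkCall("T1", "TRA", "chr9", 1.1e6, 2.1e6,
                         chrom2 = "chr10", strands = "+-",
                         source = "WGS_MERGED"))
  f <- candidateFusionsFromSv(compat, fusion_genes)
  expect_equal(nrow(f), 1L)
  expect_true(f$orientation_compatible)
  expect_equal(f$gene_a, "GENEA")
  expect_equal(f$gene_b, "GENEB")

  ## both arms keep their 5' ends: genes juxtaposed head-to-head
  incompat <- mkSet(mkCall("T2", "TRA", "chr9", 1.1e6, 2.1e6,
                           chrom2 = "chr10", strands = "++",
                           source = "WGS_MERGED"))
  f2 <- candidateFusionsFromSv(incompat, fusion_genes)
  expect_equal(nrow(f2), 1L)
  expect_false(f2$orientation_compatible)

  ## donor ordering puts the 5'-contributing gene first
  rev <- mkSet(mkCall("T3", "TRA", "chr9", 1.1e6, 2.1e6,
                      chrom2 = "chr10", strands = "-+",
                      source = "WGS_MERGED"))
  f3 <- candidateFusionsFromSv(rev, fusion_genes)
  expect_true(f3$orientation_compatible)
  expect_equal(f3$gene_a, "GENEB")

  ## minus-strand partner: '-' breakend keeps the 5' arm of a '-' gene
  minus <- mkSet(mkCall("T4", "TRA", "chr7", 3.1e6, 2.1e6,
                        chrom2 = "chr10", strands = "--",
                        source = "WGS_MERGED"))
  f4 <- candidateFusionsFromSv(minus, fusion_genes)
  expect_equal(nrow(f4), 1L)
  expect_true(f4$orientation_compatible)
  expect_equal(f4$gene_a, "GENEC")
})

test_that("intergenic or single-gene breakends yield no candidate", {
  cs <- mkSet(
    mkCall("T1", "TRA", "chr9", 1.1e6, 9e6, chrom2 = "chr10",
           source = "WGS_MERGED"),
    mkCall("T2", "TRA", "chr1", 5e6, 6e6, chrom2 = "chr2",
           source = "WGS_MERGED"))
  expect_equal(nrow(candidateFusionsFromSv(cs, fusion_genes)), 0L)
})

test_that("putative flagging needs a repeat overlap and no second method", {
  reps <- data.frame(chrom = "chr9", start = 1.05e6, end = 1.15e6)
  cand <- candidateFusionsFromSv(
    mkSet(mkCall("T1", "TRA", "chr9", 1.1e6, 2.1e6, chrom2 = "chr10",
                 strands = "+-", source = "WGS_MERGED")), fusion_genes)
  wgs_only <- markPutative(cand, reps)
  expect_true(grepl("PUTATIVE", wgs_only$flags))
  with_ogm <- markPutative(cand, reps, ogm_support = TRUE)
  expect_false(grepl("PUTATIVE", with_ogm$flags))
  with_rna <- markPutative(cand, reps, rna_support = TRUE)
  expect_false(grepl("PUTATIVE", with_rna$flags))
  off_repeat <- markPutative(cand,
    data.frame(chrom = "chr9", start = 5e6, end = 6e6))
  expect_false(grepl("PUTATIVE", off_repeat$flags))
})

test_that("RNA support threshold is exact at 16 reads", {
  cand <- candidateFusionsFromSv(
    mkSet(mkCall("T1", "TRA", "chr9", 1.1e6, 2.1e6, chrom2 = "chr10",
                 strands = "+-", source = "WGS_MERGED")), fusion_genes)
  rna15 <- data.frame(gene_a = "GENEA", gene_b = "GENEB", reads = 15L)
  rna16 <- data.frame(gene_a = "GENEA", gene_b = "GENEB", reads = 16L)
  ev15 <- integrateFusionEvidence(cand, NULL, rna15)
  ev16 <- integrateFusionEvidence(cand, NULL, rna16)
  expect_false(ev15$rna_support)
  expect_true(ev16$rna_support)
  expect_equal(ev16$rna_reads, 16L)
})

test_that("gene-pair matching is unordered and symmetric in technology order", {
  wgs_f <- candidateFusionsFromSv(
    mkSet(mkCall("T1", "TRA", "chr9", 1.1e6, 2.1e6, chrom2 = "chr10",
                 strands = "+-", source = "WGS_MERGED")), fusion_genes)
  ogm_f <- wgs_f
  ogm_f$technology <- "OGM"
  ## swap gene order and shift breakends within the window
  ogm_f[, c("gene_a", "gene_b")] <- ogm_f[, c("gene_b", "gene_a")]
  ogm_f[, c("chrom_a", "chrom_b")] <- ogm_f[, c("chrom_b", "chrom_a")]
  ogm_f[, c("pos_a", "pos_b")] <- ogm_f[, c("pos_b", "pos_a")] + 2000
  ev <- integrateFusionEvidence(wgs_f, ogm_f, NULL)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$dual_confirmed)
  ev_swapped <- integrateFusionEvidence(ogm_f, wgs_f, NULL)
  expect_equal(ev_swapped$dual_confirmed, ev$dual_confirmed)
  ## same pair beyond the window is not dual-confirmed
  ogm_far <- ogm_f
  ogm_far$pos_a <- ogm_far$pos_a + 6e5
  ev_far <- integrateFusionEvidence(wgs_f, ogm_far, NULL)
  expect_false(ev_far$dual_confirmed)
})

test_that("novelty flags pairs absent from the known list; empty list means all novel", {
  cand <- candidateFusionsFromSv(
    mkSet(mkCall("T1", "TRA", "chr9", 1.1e6, 2.1e6, chrom2 = "chr10",
                 strands = "+-", source = "WGS_MERGED")), fusion_genes)
  ev_none <- integrateFusionEvidence(cand, NULL, NULL)
  expect_true(grepl("NOVEL", ev_none$flags))
  ev_known <- integrateFusionEvidence(cand, NULL, NULL,
                                      known_fusions = "GENEB::GENEA")
  expect_false(grepl("NOVEL", ev_known$flags))
})

test_that("triple-supported is a subset of dual-confirmed on simulated data", {
  sim <- simulateDataset(smallSimConfig(81, n_fusions = 4L))
  genes <- sim$truth$tracks$genes
  wgs <- mergeCallers(filterSupport(sim$lumpy), filterSupport(sim$delly))
  wgs_f <- candidateFusionsFromSv(wgs, genes)
  ogm_f <- candidateFusionsFromSv(sim$ogm, genes)
  ev <- integrateFusionEvidence(wgs_f, ogm_f, sim$rna)
  n_dual <- sum(ev$dual_confirmed)
  n_triple <- sum(ev$dual_confirmed & ev$rna_support)
  expect_lte(n_triple, n_dual)
  expect_lte(n_dual, min(nrow(wgs_f), nrow(ogm_f)))
})
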