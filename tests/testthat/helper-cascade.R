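## Breakend fixture whose category memberships under the resolution
## cascade are induced geometrically: each stage's count is controlled by
## where the breakends sit relative to the tracks and OGM calls.
makeCascadeFixture <- function(n_sparse = 17, n_repeat = 747,
                               n_ins = 74, n_dup = 2, n_del = 2,
                               n_rest = 566) {
  tracks <- emptyTracks()
  tracks$sparse <- data.frame(chrom = "chr1", start = 0, end = 2e6)
  tracks$repeats <- data.frame(chrom = "chr2", start = 0, end = 2e7)
  ogm <- mkSet(
    mkCall("OI", "INS", "chr3", 5e6, 5e6, length = 2000, source = "OGM"),
    mkCall("OD", "DUP", "chr4", 1e6, 2e6, source = "OGM"),
    mkCall("OL", "DEL", "chr4", 5e6, 6e6, source = "OGM"),
    technology = "OGM", sample = "s1")
  at <- function(n, chrom, from, by = 997) {
    if (n == 0) return(NULL)
    data.frame(chrom = chrom, pos = from + seq_len(n) * by,
               stringsAsFactors = FALSE)
  }
  bnds <- rbind(
    at(n_sparse, "chr1", 0),
    at(n_repeat, "chr2", 0),
    at(n_ins, "chr3", 4.95e6),            # within 100 kb of the insertion
    at(n_dup, "chr4", 1e6),
    at(n_del, "chr4", 5e6),
    at(n_rest, "chr5", 1e6, by = 1e4))
  bnds$id <- paste0("b", seq_len(nrow(bnds)))
  bnds$is_tra <- bnds$chrom == "chr5" & seq_len(nrow(bnds)) %% 2 == 0
  bnds$support <- 5L + (seq_len(nrow(bnds)) %% 7L)
  list(bnds = bnds, tracks = tracks, ogm = ogm)
}
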