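## Builders for in-memory fixtures used across the suite.

mkCall <- function(id, svtype, chrom1, pos1, pos2, chrom2 = chrom1,
                   strands = NULL, length = NULL, sr = 5L, pe = 5L,
                   mol = 0L, source = "LUMPY", sample = "s1", flags = "") {
  if (is.null(strands)) {
    strands <- if (svtype == "TRA") "+-"
      else normalizeStrand(svtype, "WGS")[1L]
  }
  if (is.null(length)) {
    length <- if (svtype %in% c("DEL", "DUP", "INV")) pos2 - pos1
      else NA_real_
  }
  data.frame(id = id, svtype = svtype, chrom1 = chrom1, pos1 = pos1,
             strand1 = substr(strands, 1, 1), chrom2 = chrom2, pos2 = pos2,
             strand2 = substr(strands, 2, 2), length = length,
             support_sr = sr, support_pe = pe, support_mol = mol,
             source = source, sample = sample, flags = flags,
             stringsAsFactors = FALSE)
}

mkSet <- function(..., technology = "WGS", sample = "s1") {
  SVCallSet(do.call(rbind, list(...)), sample = sample,
            technology = technology)
}

emptyTracks <- function() {
  e3 <- data.frame(chrom = character(), start = numeric(),
                   end = numeric(), stringsAsFactors = FALSE)
  list(repeats = e3, gaps = e3, centromeres = e3, sparse = e3,
       genes = cbind(e3, name = character(), strand = character()))
}

## small, fast simulator configuration for property loops
smallSimConfig <- function(seed, ...) {
  args <- list(seed = seed,
               chrom_lengths = c(chr1 = 2e7, chr2 = 2e7, chr3 = 2e7),
               n_sv = 20L, n_genes = 40L, n_fusions = 2L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}
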