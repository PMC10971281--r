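## End-to-end truth recovery on a simulated dataset: runs the consensus,
## filtering, matching and reclassification stages and maps results back to
## truth ids through the observation metadata.
##
## "Dual-visible" truth SVs are the somatic truth SVs >= 500 bp (or
## translocations) present in the WGS consensus inputs (both callers, or
## the DELLY-style caller alone for insertions) and in the OGM observation.

pipelineRecovery <- function(sim, th = svThresholds()) {
  l <- filterSupport(sim$lumpy, th)
  d <- filterSupport(sim$delly, th)
  wgs <- mergeCallers(l, d, th)
  wgs <- filterGapCentromere(wgs, sim$truth$tracks, th)
  wgs <- filterGermline(wgs, sim$truth$control_db, th,
                        control_calls = sim$truth$control_calls)
  ogm <- filterGermline(sim$ogm, sim$truth$control_db, th,
                        control_calls = sim$truth$control_calls)
  mt <- matchCrossTech(wgs, ogm, th)
  rc <- reclassifyTraToIns(mt$wgs_only, ogm, th)

  aud <- metadata(wgs)$merge_audit
  tl <- metadata(sim$lumpy)$truth_id
  td <- metadata(sim$delly)$truth_id
  truth_of <- ifelse(is.na(aud$lumpy_id), td[aud$delly_id],
                     tl[aud$lumpy_id])
  names(truth_of) <- aud$merged_id
  to <- metadata(sim$ogm)$truth_id

  truth <- sim$truth$svs
  somatic <- truth$id[!truth$germline]
  vis_w <- intersect(td[svCalls(d)$id], tl[svCalls(l)$id])
  vis_w <- union(vis_w, td[svCalls(d)$id[svCalls(d)$svtype == "INS"]])
  vis <- intersect(intersect(vis_w, to[svCalls(sim$ogm)$id]), somatic)
  vis <- vis[!is.na(vis)]
  vis <- intersect(vis,
                   truth$id[is.na(truth$length) | truth$length >= 500])

  recovered <- union(truth_of[mt$matches$wgs_id],
                     truth_of[rc$audit$tra_id])
  germ_log <- metadata(wgs)$germline_removed
  somatic_removed <- sum(truth_of[germ_log$id] %in% somatic, na.rm = TRUE)

  list(visible = vis, recovered = recovered,
       n_visible = length(vis), n_recovered = sum(vis %in% recovered),
       somatic_germline_removed = somatic_removed,
       wgs = wgs, ogm = ogm, match = mt, reclass = rc,
       truth_of = truth_of, ogm_truth = to)
}
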