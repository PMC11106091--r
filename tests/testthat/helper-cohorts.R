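# Default synthetic cohorts are expensive to build, and several tests look
# at the same ones; cache per-seed results for the whole test run.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort_features <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  coh <- generate_cohort(cohort_spec(seed = seed))
  feats <- cohort_features(coh, plexuses = c("SCP", "DCP"))
  out <- merge(feats, coh$eyes[, c("eye_id", "npa_quadrants", "group")],
               by = "eye_id")
  .cohort_cache[[key]] <- out
  out
}
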