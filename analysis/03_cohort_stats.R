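#!/usr/bin/env Rscript
# Cohort statistics: group summary table (NPA vs well-perfused means with
# Welch t tests) and Pearson correlations of FD/LAC against the extent of
# peripheral non-perfusion (quadrant count 0-4).

library(octafractal)

eyes <- read_eye_table(file.path("results", "cohort", "eyes.csv"))
feats <- read_feature_table(file.path("results", "run", "features.csv"))
cs <- run_cohort_analysis(eyes, feats)

print(cs)

write.csv(cs$summary, file.path("results", "group_summary.csv"),
          row.names = FALSE)
write.csv(cs$correlations, file.path("results", "extent_correlations.csv"),
          row.names = FALSE)

fd_scp <- cs$summary[cs$summary$variable == "FD SCP", ]
cat(sprintf("\nSCP FD: NPA %.2f +/- %.2f vs well-perfused %.2f +/- %.2f (p = %.2g)\n",
            fd_scp$npa_mean, fd_scp$npa_sd, fd_scp$wp_mean, fd_scp$wp_sd,
            fd_scp$p_value))
r_fd <- cs$correlations[cs$correlations$x == "fd_scp", ]
cat(sprintf("corr(SCP FD, quadrant count): r = %.2f, p = %.2g, n = %d\n",
            r_fd$r, r_fd$p_value, r_fd$n))
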