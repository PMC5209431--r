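#!/usr/bin/env Rscript
# Step 3 — collapse the frame-level measurements into per-(subject,
# study, reader) mobility metrics: VFPa, VFRa, VFAP and the glottal-angle
# variants. Requires results/simulation/ from step 1.

suppressPackageStartupMessages(library(glottocine))

meas <- read_measurements("results/simulation/measurements.csv")
subjects <- read.csv("results/simulation/subjects.csv")

metrics <- suppressWarnings(metrics_from_measurements(meas))
metrics <- merge(metrics, subjects[, c("subject", "cohort")], by = "subject")
write_table_csv(metrics, "results/metrics.csv")

n_undef <- sum(is.na(metrics$vfpa))
cat(sprintf("Computed metrics for %d (subject, study, reader) combinations\n",
            nrow(metrics)))
cat(sprintf("VFPa undefined (near-total glottal closure) in %d of them\n",
            n_undef))
s1 <- metrics[metrics$study == 1 & metrics$reader == 1, ]
for (g in c("healthy", "uvfp"))
  cat(sprintf("  %-8s study-1 VFAP: %s %%\n", g,
              sprintf("%.1f (SD %.1f)", mean(s1$vfap[s1$cohort == g]),
                      sd(s1$vfap[s1$cohort == g]))))
cat("Written to results/metrics.csv\n")
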