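#!/usr/bin/env Rscript
# Step 4 — group comparison. Two parts:
#   (a) re-analysis of the published study-1 summary statistics (pooled
#       unpaired t-tests from printed means/SDs alone);
#   (b) the same comparison on the synthetic cohort's metrics (step 3).

suppressPackageStartupMessages(library(glottocine))

cat("-- (a) published study-1 summaries, pooled t-tests --\n")
published <- list(
  # metric, healthy mean/sd (n=5), UVFP mean/sd (n=9)
  vfpa = c(0.08, 0.05, 1.13, 0.85),
  vfra = c(0.08, 0.07, 0.47, 0.20),
  vfap = c(87.32, 14.35, 57.61, 18.10))
for (m in names(published)) {
  v <- published[[m]]
  tt <- t_test_summary(v[1], v[2], 5, v[3], v[4], 9, "pooled")
  cat(sprintf("  %-5s healthy %.2f (%.2f) vs UVFP %.2f (%.2f): t=%.2f, p=%.4f\n",
              m, v[1], v[2], v[3], v[4], tt$t, tt$p))
}

cat("\n-- (b) synthetic cohort, study 1 reader 1 --\n")
metrics <- read.csv("results/metrics.csv")
subjects <- read.csv("results/simulation/subjects.csv")
cmp <- compare_groups(metrics, subjects, study = 1, reader = 1)
write_table_csv(cmp, "results/comparison.csv")
print(cmp[, c("metric", "healthy", "uvfp", "p")], row.names = FALSE)
cat("Written to results/comparison.csv\n")
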