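#!/usr/bin/env Rscript
# Step 1 — generate the synthetic cohort emulating the study design:
# 5 healthy + 9 left-UVFP subjects, studies 1-2 intra-session, study 3
# inter-session (all healthy + 5 patients), two readers on study 1.
# Writes frame-level measurements, closed-form ground truth and the
# subject table under results/simulation/.

suppressPackageStartupMessages(library(glottocine))

seed <- 17
out <- "results/simulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dataset <- simulate_cohort(cohort_config(), master_seed = seed)

write_table_csv(dataset$measurements, file.path(out, "measurements.csv"))
write_table_csv(dataset$ground_truth, file.path(out, "ground_truth.csv"))
write_table_csv(dataset$subjects, file.path(out, "subjects.csv"))

cat(sprintf("Simulated %d subjects (%d UVFP), %d frame measurements, seed %d\n",
            nrow(dataset$subjects), sum(dataset$subjects$cohort == "uvfp"),
            nrow(dataset$measurements), seed))
cat(sprintf("Subjects with the 1-week inter-session study: %d\n",
            sum(dataset$subjects$has_study3)))
cat("Written to", out, "\n")
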