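#!/usr/bin/env Rscript
# Step 5 — repeatability of the six metrics on the synthetic cohort:
# intra-session (study 1 vs 2), inter-session (study 1 vs 3, 1-week
# interval) and inter-reader (study 1, two readers), as single-measure
# two-way random-effects agreement ICCs with 95% CIs. Also writes the
# cohort distribution figure.

suppressPackageStartupMessages(library(glottocine))

metrics <- read.csv("results/metrics.csv")
tab <- repeatability_icc(metrics, form = "ICC2")
write_table_csv(tab, "results/icc.csv")

cat("ICC (95% CI) by design:\n")
for (cmp in unique(tab$comparison)) {
  cat(" ", cmp, "\n")
  sel <- tab[tab$comparison == cmp, ]
  for (i in seq_len(nrow(sel)))
    cat(sprintf("    %-9s %5.2f (%5.2f, %5.2f)  %s\n", sel$metric[i],
                sel$icc[i], sel$ci_low[i], sel$ci_high[i], sel$band[i]))
}

fig <- plot_metric_distributions(metrics)
ggplot2::ggsave("results/metric_distributions.png", fig,
                width = 8, height = 5, dpi = 150)
cat("Written results/icc.csv and results/metric_distributions.png\n")
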