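#!/usr/bin/env Rscript
# Step 1: simulate the study design — a 30-province x 13-year panel with
# 3 inputs (institutions, beds, workers), 2 desirable outputs (visits,
# admissions), 1 undesirable output, drawn around a known concave VRS
# frontier with known true efficiency multipliers u.

library(phcfrontier)

dir.create("results", showWarnings = FALSE)
seed <- 2026L

gen <- generate_panel(synthetic_spec(seed = seed))
write_panel(gen$panel, "results/synthetic_panel.csv", layout = "long")
write.csv(gen$truth, "results/synthetic_truth.csv", row.names = FALSE)

cat("Simulated panel:", length(gen$panel$dmus), "DMUs x",
    length(gen$panel$periods), "periods\n")
cat("True efficiency multipliers: range",
    sprintf("[%.3f, %.3f];", min(gen$truth$u), max(gen$truth$u)),
    sum(gen$truth$u == 1), "frontier observations\n")
cat("Wrote results/synthetic_panel.csv and results/synthetic_truth.csv\n")
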