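#!/usr/bin/env Rscript
# Step 2 — estimate the endogenous AXIN1:AXIN2 ratio by bridging.
#
# Endogenous AXIN1 and AXIN2 are detected by different antibodies with
# unknown affinities, so their bands cannot be compared directly. The
# bridge chains three same-antibody comparisons through GFP-AXIN1 and
# GFP-AXIN2; in the product of the three dilution-fit slope ratios every
# affinity (and every construct amount) cancels, leaving the endogenous
# amount ratio. Run analysis/01_simulate.R first.

suppressMessages(library(axinpool))

inp <- "results/synthetic_inputs"
bands <- read_bands_csv(file.path(inp, "bands.csv"))
design <- read.csv(file.path(inp, "bridge_design.csv"),
                   stringsAsFactors = FALSE)
exps <- assemble_bridge_experiments(bands, design)
est <- aggregate_ratio(exps)

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(per_experiment = est$per_experiment, mean = est$mean, sem = est$sem,
       n = est$n, qc = list(excluded_saturated = est$qc$excluded_saturated)),
  "results/ratio.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

truth <- jsonlite::read_json(file.path(inp, "truth.json"))
cat(sprintf("per-experiment ratios: %s\n",
            paste(sprintf("%.2f", est$per_experiment), collapse = ", ")))
print(est)
cat(sprintf("ground truth %.2f lies within mean +/- 3 SEM: %s\n",
            truth$true_ratio,
            abs(est$mean - truth$true_ratio) <= 3 * est$sem))
cat("wrote results/ratio.json\n")
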