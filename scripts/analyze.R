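#!/usr/bin/env Rscript
# Recompute the metric series from a stored trajectory.
#
# Usage: Rscript scripts/analyze.R --frames trajectory.jsonl --out metrics.csv

suppressPackageStartupMessages({
  library(optparse)
  library(autopoiesim)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--frames", type = "character"),
  make_option("--out", type = "character", default = "metrics.csv"),
  make_option("--pooled", action = "store_true", default = FALSE)
)))

frames <- read_trajectory(opts$frames)
write_metrics_csv(metrics_series(frames, pooled_colors = opts$pooled), opts$out)
cat("wrote", opts$out, "(", length(frames), "frames )\n")
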