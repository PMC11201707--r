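#!/usr/bin/env Rscript
# Steady-state summary (mean and population SD over the final window) of a
# metric series.
#
# Usage: Rscript scripts/report.R --metrics metrics.csv --window 60

suppressPackageStartupMessages({
  library(optparse)
  library(autopoiesim)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--metrics", type = "character"),
  make_option("--window", type = "double", default = 60)
)))

series <- utils::read.csv(opts$metrics)
print(steady_state_summary(series, window_s = opts$window), digits = 4)
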