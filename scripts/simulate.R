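#!/usr/bin/env Rscript
# Run one experiment and write its outputs.
#
# Usage:
#   Rscript scripts/simulate.R --experiment II --seed 1 --duration 300 \
#     --out outdir [--config schema.yaml] [--frames-every 1] [--events]

suppressPackageStartupMessages({
  library(optparse)
  library(autopoiesim)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--experiment", type = "character", default = "I"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--duration", type = "double", default = 300),
  make_option("--out", type = "character", default = "simout"),
  make_option("--config", type = "character", default = NULL),
  make_option("--frames-every", type = "double", default = 1, dest = "frames_every"),
  make_option("--events", action = "store_true", default = FALSE),
  make_option("--no-retry", action = "store_true", default = FALSE, dest = "no_retry")
)))

schema <- if (!is.null(opts$config)) read_schema_config(opts$config) else NULL
cfg <- experiment_config(
  experiment = opts$experiment, schema = schema, seed = opts$seed,
  duration_s = opts$duration, sample_interval_s = opts$frames_every,
  retry_until_coexistence = !opts$no_retry, record_events = opts$events
)

res <- run_simulation(cfg)
print(res)

dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
write_metrics_csv(res$metrics, file.path(opts$out, "metrics.csv"))
write_trajectory(res$frames, file.path(opts$out, "trajectory.jsonl"))
if (opts$events) write_events(res$events, file.path(opts$out, "events.jsonl"))
cat("outputs written to", opts$out, "\n")
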