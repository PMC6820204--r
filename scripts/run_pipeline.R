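#!/usr/bin/env Rscript

# Thin shell wrapper around hgalpha::run_full_analysis(): simulates the
# default eight-hemisphere synthetic study, runs the complete analysis and
# writes CSV results plus a run log.
#
# Usage: Rscript scripts/run_pipeline.R [--seed <int>] [--out-dir <path>]
#        [--config <yaml>]
# The optional YAML config may override any simulation_params() field.

suppressPackageStartupMessages(library(hgalpha))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out_dir <- get_arg("--out-dir", "results/pipeline")
config_path <- get_arg("--config", NA)

sim_args <- list(seed = seed)
if (!is.na(config_path)) {
  overrides <- yaml::read_yaml(config_path)
  sim_args <- utils::modifyList(overrides, sim_args)
}
sim <- do.call(simulation_params, sim_args)

res <- run_full_analysis(run_config(sim = sim, output_dir = out_dir))
print(res)
cat("results written to", out_dir, "\n")
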