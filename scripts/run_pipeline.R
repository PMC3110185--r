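#!/usr/bin/env Rscript
# Thin shell entry point over escreen::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R [--config <yaml>] [--seed <int>]
#                                       [--out <dir>]

suppressPackageStartupMessages(library(escreen))

args <- commandArgs(trailingOnly = TRUE)
arg_value <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

config <- arg_value("--config", NA)
config <- if (is.na(config)) list() else config
out_dir <- arg_value("--out", "escreen_run")
seed <- arg_value("--seed", NA)
if (is.character(config) && !is.na(seed)) {
  config <- yaml::read_yaml(config)
}
if (!is.na(seed)) config$seed <- as.integer(seed)

res <- run_pipeline(config, out_dir = out_dir)
print(res$summary)
cat("artifacts in", res$out_dir, "\n")
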