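#!/usr/bin/env Rscript
# Thin command-line wrapper over enhancerEvo::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --bundle <dir> [--outdir results]
#          [--seed 1] [--stages classify,loci,...] [--config config.yaml]
#
# The optional YAML config holds pipeline_config() fields; command-line
# flags override it.

suppressPackageStartupMessages({
  library(optparse)
  library(enhancerEvo)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--bundle", type = "character"),
  make_option("--outdir", type = "character", default = "results"),
  make_option("--seed", type = "integer", default = NA_integer_),
  make_option("--stages", type = "character", default = ""),
  make_option("--config", type = "character", default = "")
)))
if (is.null(opt$bundle)) stop("--bundle is required")

args <- list()
if (nzchar(opt$config)) args <- yaml::read_yaml(opt$config)
if (!is.na(opt$seed)) args$seed <- opt$seed
cfg <- do.call(pipeline_config, args)

stages <- c("classify", "loci", "expression", "selection", "enrich",
            "signal", "compensate")
if (nzchar(opt$stages))
  stages <- strsplit(opt$stages, ",", fixed = TRUE)[[1]]

report <- run_pipeline(opt$bundle, cfg, stages = stages)
files <- write_report(report, opt$outdir)
cat("wrote:\n", paste(" ", files, collapse = "\n"), "\n")
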