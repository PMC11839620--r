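#!/usr/bin/env Rscript
# Thin shell entry point for the full analysis pipeline.
#
# Usage: Rscript scripts/run_pipeline.R --config run.yaml --outdir results/run1

suppressPackageStartupMessages({
  library(optparse)
  library(heterofit)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML config; omit to run the default simulated study"),
  make_option("--outdir", type = "character", default = "pipeline_out")
)))

config <- if (is.null(opts$config)) list() else opts$config
manifest <- run_pipeline(config, opts$outdir)
cat(jsonlite::toJSON(manifest$stages, auto_unbox = TRUE, pretty = TRUE), "\n")
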