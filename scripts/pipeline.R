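#!/usr/bin/env Rscript
# Thin command-line wrapper over eyescale::run_pipeline().
#
# Usage:
#   Rscript scripts/pipeline.R --config run.yaml
#   Rscript scripts/pipeline.R --seed 7 --outdir results/run7 \
#       --skip varrates,habitat

suppressPackageStartupMessages({
  library(optparse)
  library(eyescale)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML configuration file (overrides the other flags)"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--outdir", type = "character", default = "eyescale_run"),
  make_option("--skip", type = "character", default = "",
              help = "comma-separated stages to skip")
)))

if (!is.null(opts$config)) {
  run_pipeline(opts$config)
} else {
  stages <- list()
  for (s in strsplit(opts$skip, ",")[[1]])
    if (nzchar(s)) stages[[trimws(s)]] <- FALSE
  run_pipeline(list(seed = opts$seed, outdir = opts$outdir, stages = stages))
}
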