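#!/usr/bin/env Rscript
# Thin command-line wrapper over nirhsi::run_all():
#   Rscript scripts/run_pipeline.R --n 10 --seed 1 --out report/
suppressPackageStartupMessages({
  library(optparse)
  library(nirhsi)
})

parser <- OptionParser(option_list = list(
  make_option("--n", type = "integer", default = 10L,
              help = "cohort size [default %default]"),
  make_option("--n-per-class", dest = "n_per_class", type = "integer",
              default = 200L,
              help = "training pixels per class per specimen"),
  make_option("--C", type = "double", default = 1,
              help = "SVM soft-margin cost"),
  make_option("--seed", type = "integer", default = 1L,
              help = "master seed"),
  make_option("--out", type = "character", default = "report",
              help = "output directory for the metrics CSVs")))
opt <- parse_args(parser)

res <- run_all(pipeline_config(n_specimens = opt$n,
                               n_per_class = opt$n_per_class,
                               C = opt$C, seed = opt$seed,
                               out_dir = opt$out),
               verbose = TRUE)
print(res)
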