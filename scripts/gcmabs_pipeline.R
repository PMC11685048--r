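#!/usr/bin/env Rscript
# Thin command-line driver over gcmabs::run_pipeline().
#
#   Rscript scripts/gcmabs_pipeline.R [stages] --outdir DIR [--config PATH]
#                                     [--seed INT] [--force]
#
# stages: comma-separated subset of
#   simulate,qc,bcr,annotate,facs,elisa,integrate   (default: all)

suppressPackageStartupMessages(library(gcmabs))

args <- commandArgs(trailingOnly = TRUE)
stages <- c("simulate", "qc", "bcr", "annotate", "facs", "elisa", "integrate")
outdir <- "gcmabs_run"
config_path <- NULL
seed <- 1L
force <- FALSE
i <- 1L
while (i <= length(args)) {
  a <- args[i]
  if (a == "--outdir") { outdir <- args[i + 1L]; i <- i + 2L }
  else if (a == "--config") { config_path <- args[i + 1L]; i <- i + 2L }
  else if (a == "--seed") { seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (a == "--force") { force <- TRUE; i <- i + 1L }
  else if (!startsWith(a, "--")) { stages <- strsplit(a, ",")[[1]]; i <- i + 1L }
  else stop("unknown flag: ", a)
}

cfg <- pipeline_config(path = config_path, outdir = outdir, seed = seed)
manifest <- run_pipeline(cfg, stages = stages, force = force)
cat("completed stages:", paste(names(manifest), collapse = ", "), "\n")
cat("outputs in:", normalizePath(outdir), "\n")
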