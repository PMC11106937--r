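#!/usr/bin/env Rscript

# Stage 1: generate the synthetic input corpus.
#
# Emulates the structure of a multi-study selective-sweep catalog on a
# small genome: 15 planted confirmed-sweep loci supported by prescribed
# mixes of production/adaptation studies, background sweeps at 0.1 per
# Mb, a gene annotation, a QTL database with one planted enriched trait,
# and a GO DAG with six planted enriched terms. Everything is a pure
# function of the seed.

suppressMessages(library(sweepcss))

seed <- 42
out <- "results/simulated_input"
bundle <- simulate_bundle(out, seed = seed)

truth <- bundle$truth
cat("simulated input bundle written to", out, "\n")
cat("  genome:", nrow(bundle$layout), "chromosomes,",
    round(sum(bundle$layout$length) / 1e6, 1), "Mb total\n")
cat("  planted loci:", nrow(truth), "(",
    sum(truth$intended_class == "prodCSS"), "production,",
    sum(truth$intended_class == "adapCSS"), "adaptation,",
    sum(truth$intended_class == "unclassified"), "mixed )\n")
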