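#!/usr/bin/env Rscript

# Stage 1: generate the study's synthetic two-condition transcriptome.
#
# The primary dataset emulates a progressive-disease contrast: six
# 15-gene pathways whose within-pathway correlation attenuates from 0.8
# (baseline) to 0.1 (perturbed), each with a planted hub gene, plus 30
# uncorrelated background genes, 50 samples per condition. Files are written
# in the exact formats the pipeline consumes (expression TSV, design TSV,
# GMT, truth YAML).

suppressPackageStartupMessages(library(coexrewire))

out_dir <- "results/data"
cfg <- synth_config(rng_seed = 101)
sim <- generate_synthetic(cfg)
write_synthetic(sim, out_dir)

cat("Wrote synthetic dataset to", out_dir, "\n")
print(sim$dataset)
cat("Planted pathway classes:",
    paste(unique(sim$truth$classes), collapse = ", "), "\n")
cat("Planted hubs:", paste(sim$truth$hubs, collapse = ", "), "\n")
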