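#!/usr/bin/env Rscript
# Run the full analysis pipeline on the inputs produced by
# analysis/01_simulate_inputs.R.
#
# Stages: input validation -> dense-region calling -> differential network
# construction -> k-core decomposition -> five-class bin classification ->
# compartment scoring -> integration reports.  All outputs, a manifest with
# md5 checksums and per-stage timings, and an event log are written under
# results/pipeline/.
#
# Run from the repository root:  Rscript analysis/02_run_pipeline.R

suppressPackageStartupMessages(library(chromcore))

inp <- file.path("results", "inputs")
if (!file.exists(file.path(inp, "chrom.sizes")))
  stop("inputs not found; run analysis/01_simulate_inputs.R first")

contrasts <- sub("^diffnet_(.*)\\.tsv$", "\\1",
                 list.files(inp, pattern = "^diffnet_.*\\.tsv$"))
chroms <- sub("^contacts_(.*)\\.tsv$", "\\1",
              list.files(inp, pattern = "^contacts_.*\\.tsv$"))

config <- list(
  out_dir = file.path("results", "pipeline"),
  seed = 42L,
  inputs = list(
    chrom_sizes = file.path(inp, "chrom.sizes"),
    peaks = file.path(inp, "peaks.bed"),
    diffnet = stats::setNames(
      as.list(file.path(inp, paste0("diffnet_", contrasts, ".tsv"))),
      contrasts),
    contacts = stats::setNames(
      as.list(file.path(inp, paste0("contacts_", chroms, ".tsv"))),
      chroms),
    genes = file.path(inp, "genes.tsv"),
    reference = file.path(inp, "truth", "compartments.bedgraph")))

res <- run_pipeline(config)

cat("Pipeline finished.\n")
cat("Stage timings (s):\n")
print(unlist(res$manifest$stage_seconds))
cat("Outputs under", config$out_dir, "\n")
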