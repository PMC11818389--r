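#!/usr/bin/env Rscript
# Generates the two synthetic cohorts the study needs and writes them as
# delimited text under results/:
#   - a training cohort (200 lesions) whose traces carry ground-truth AI/LSI
#     from the calibrated stand-in constants, used to train the surrogates;
#   - an analysis cohort (300 lesions) standing in for the LI-guided
#     procedures whose durations the stopping-rule comparison uses.
# Everything here is a thin driver over the rfablate package.

suppressPackageStartupMessages(library(rfablate))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

constants <- default_metric_constants()
write_metric_config(constants, file.path(out_dir, "metric_constants.cfg"))

message("Simulating training cohort (10 procedures x 20 lesions) ...")
train_traces <- simulate_cohort(10, layout = procedure_layout(n_lesions = 20),
                                seed = seed + 10L)
write_trace_table(train_traces, file.path(out_dir, "training_traces.tsv"))
write_param_manifest(train_traces, file.path(out_dir, "training_manifest.tsv"))

message("Simulating LI-guided analysis cohort (10 procedures x 30 lesions) ...")
analysis_traces <- simulate_cohort(10, seed = seed + 6L)
write_trace_table(analysis_traces, file.path(out_dir, "analysis_traces.tsv"))
write_param_manifest(analysis_traces, file.path(out_dir, "analysis_manifest.tsv"))

message("Wrote ", length(train_traces), " training and ",
        length(analysis_traces), " analysis traces under ", out_dir, "/")
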