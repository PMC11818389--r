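#!/usr/bin/env Rscript
# Trains the per-timepoint AI and LSI surrogate models on the training
# cohort written by 01_simulate_cohorts.R and reports lesion-grouped 30%
# holdout metrics for all five model families (random forest, gradient
# boosting, ridge, lasso, elastic net). The LSI target goes through the
# quantile transform. Writes results/surrogate_metrics.tsv.

suppressPackageStartupMessages(library(rfablate))

out_dir <- "results"
traces <- read_trace_table(file.path(out_dir, "training_traces.tsv"))
constants <- read_metric_config(file.path(out_dir, "metric_constants.cfg"))

message("Building per-timepoint training tables (stride 10, ~100 Hz) ...")
tab_ai <- build_training_table(traces, constants, "AI", stride = 10L)
tab_lsi <- build_training_table(traces, constants, "LSI", stride = 10L)
message("  AI: ", nrow(tab_ai), " rows; LSI: ", nrow(tab_lsi), " rows")

families <- list(
  random_forest = list(num_trees = 50L, mtry = 2L, min_node_size = 10L),
  gradient_boosting = list(nrounds = 200L, eta = 0.1, max_depth = 6L),
  ridge = list(lambda = c(0.001, 0.01, 0.1)),
  lasso = list(lambda = c(0.001, 0.01, 0.1)),
  elastic_net = list(lambda = c(0.001, 0.01, 0.1), alpha = 0.5)
)

rows <- list()
for (kind in c("AI", "LSI")) {
  tab <- if (kind == "AI") tab_ai else tab_lsi
  for (fam in names(families)) {
    fit <- tune_and_train(tab, fam, grid = families[[fam]], folds = 10L,
                          seed = 3L, transform_target = (kind == "LSI"))
    ev <- evaluate_holdout(fit, tab, holdout_fraction = 0.3, seed = 5L)
    message(sprintf("  %-4s %-18s holdout R2 = %.4f  MAE = %.4f",
                    kind, fam, ev$r2, ev$mae))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = kind, family = fam, holdout_r2 = ev$r2, holdout_mae = ev$mae,
      n_rows = nrow(tab), n_holdout_rows = ev$n_holdout_rows)
  }
}

metrics <- do.call(rbind, rows)
utils::write.table(metrics, file.path(out_dir, "surrogate_metrics.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
message("Wrote ", file.path(out_dir, "surrogate_metrics.tsv"))
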