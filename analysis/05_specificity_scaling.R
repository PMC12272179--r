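#!/usr/bin/env Rscript
# Individuality experiments: intra- vs inter-subject R^2 differences with
# Wilcoxon + Benjamini-Hochberg tests, a group model trained on the same
# amount of pooled data, and the learning curve over training-set size.

source(file.path("analysis", "00_setup.R"))

suppressMessages(run_experiment_suite(
  suite_cfg(c("subject_specificity", "group_model", "data_scaling"),
            run_counts = c(2, 4, 8, 12), scaling_repetitions = 3)))

st <- utils::read.csv(file.path(RESULTS_DIR, "subject_specificity_tests.csv"))
cat(sprintf("subject specificity at lag 1: mean intra-inter d = %.4f, %d/%d pairs significant (BH 0.05)\n",
            mean(st$mean_d), sum(st$reject), nrow(st)))

gm <- utils::read.csv(file.path(RESULTS_DIR, "group_model.csv"))
agg <- stats::aggregate(d ~ lag, gm, mean)
cat("individual - group mean R^2 difference by lag:\n")
print(agg, digits = 3)

ds <- utils::read.csv(file.path(RESULTS_DIR, "data_scaling.csv"))
agg_d <- stats::aggregate(r2_mean ~ n_runs, ds[ds$lag == 1, ], mean)
cat("learning curve (lag 1): mean validation R^2 by training runs:\n")
print(agg_d, digits = 3)
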