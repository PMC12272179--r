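#!/usr/bin/env Rscript
# Core benchmark: train the model zoo per subject (linear Chebnet on the
# functional graph, multivariate and univariate linear AR), evaluate test
# R^2 at lags 1-6 with adjacent-model Wilcoxon tests, and run the graph- and
# linearity-sensitivity analyses.

source(file.path("analysis", "00_setup.R"))

suppressMessages(run_experiment_suite(
  suite_cfg(c("model_comparison", "graph_sensitivity", "linearity_sensitivity"))))

mc <- utils::read.csv(file.path(RESULTS_DIR, "model_comparison.csv"))
agg <- stats::aggregate(r2_mean ~ model + lag, mc, mean)
cat("mean test R^2 by model and lag:\n")
print(utils::head(stats::reshape(agg, idvar = "model", timevar = "lag",
                                 direction = "wide"), 10), digits = 3)

gs <- utils::read.csv(file.path(RESULTS_DIR, "graph_sensitivity.csv"))
agg_g <- stats::aggregate(r2_mean ~ graph, gs[gs$lag == 1, ], mean)
cat("\ngraph sensitivity, lag-1 mean R^2 by prior:\n")
print(agg_g, digits = 3)

ls <- utils::read.csv(file.path(RESULTS_DIR, "linearity_sensitivity.csv"))
agg_l <- stats::aggregate(r2_mean ~ variant + lag, ls, mean)
cat("\nlinear vs non-linear Chebnet, mean R^2 by lag:\n")
print(stats::reshape(agg_l, idvar = "variant", timevar = "lag",
                     direction = "wide"), digits = 3)
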