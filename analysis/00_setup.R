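# Shared settings for the analysis workflow. Every numbered script sources
# this file, so the whole workflow is reproducible from one seed and one
# cohort definition. Sizes are desk-scale: 3 subjects, 30 parcels, 20
# movie-like runs of 240 time points (about 6 min at TR = 1.49 s) plus 2
# rest runs; a full 197-parcel, 68-run layout is a config change only.

library(neuroar)

SEED <- 20260919
RESULTS_DIR <- file.path("results")
COHORT_DIR <- file.path(RESULTS_DIR, "cohort")

cohort_cfg <- cohort_config(
  n_subjects = 3,
  n_parcels = 30,
  n_runs_per_condition = c(friends = 20, rest = 2),
  run_length = 240,
  tr = 1.49,
  coupling_density = 0.10,
  spectral_radius = 0.9,
  shared_amplitude = 0.5,
  subject_divergence = 0.5,
  seed = SEED
)

suite_cfg <- function(experiments, output_dir = RESULTS_DIR, ...) {
  experiment_config(
    cohort = cohort_cfg,
    cutoff_hz = 0.01,
    train_fraction = 0.6, # 12 train, 4 validation, 4 test runs
    graph_kind = "functional",
    model_grid = list(
      model_config("chebnet", k = 3, cheb_order = 3, nonlinear = FALSE, seed = 1),
      model_config("linear_multi", k = 1, seed = 1),
      model_config("linear_uni", k = 8, seed = 1)),
    lags = 1:6,
    experiments = experiments,
    epochs = 25, batch_size = 256, learning_rate = 0.02,
    seed = SEED, output_dir = output_dir, ...)
}

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
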