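# shared fixtures built in code

# small preprocessed cohort: list(runs, truth, train, test, subjects)
make_test_cohort <- function(n_subjects = 1, n_parcels = 20, n_runs = 6,
                             run_length = 240, divergence = 0, seed = 1,
                             n_train = 4) {
  cc <- cohort_config(n_subjects = n_subjects, n_parcels = n_parcels,
                      n_runs_per_condition = c(friends = n_runs),
                      run_length = run_length,
                      subject_divergence = divergence, seed = seed)
  coh <- generate_cohort(cc)
  runs <- lapply(coh$runs, function(r) zscore_per_run(dct_highpass(r, 0.01)))
  labels <- sort(unique(vapply(runs, function(r) r$run, character(1))))
  list(cohort = coh, runs = runs,
       subjects = sprintf("sub-%02d", seq_len(n_subjects)),
       train = filter_runs_by(runs, labels[seq_len(n_train)]),
       test = filter_runs_by(runs, labels[-seq_len(n_train)]))
}

filter_runs_by <- function(runs, labels, subject = NULL) {
  Filter(function(r) r$run %in% labels &&
           (is.null(subject) || r$subject %in% subject), runs)
}

subject_runs <- function(runs, s) Filter(function(r) r$subject == s, runs)

# quick training wrapper with test-scale defaults
quick_fit <- function(cfg, train_runs, spectral_op = NULL, epochs = 25,
                      lr = 0.02, seed = 1, batch_size = 256) {
  ws <- make_windows(train_runs, k = cfg$k, l = 1)
  fit_model(build_model(cfg, dim(ws$inputs)[3], spectral_op = spectral_op), ws,
            epochs = epochs, batch_size = batch_size, learning_rate = lr,
            seed = seed)
}

# brute-force two-sided Wilcoxon signed-rank p-value by enumerating all 2^n
# sign assignments (independent oracle for the DP implementation)
wilcoxon_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
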