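test_that("r2_score follows its definition, including negative values", {
  y <- cbind(c(0, 1, 2, 3))
  expect_equal(r2_score(y, y), 1)
  expect_equal(r2_score(y, matrix(mean(y), 4, 1)), 0)
  expect_equal(r2_score(y, cbind(c(0, 0, 2, 2))), 1 - 2 / 5)
  # worse than the mean predictor -> negative
  expect_lt(r2_score(y, cbind(c(3, 2, 1, 0))), 0)
  expect_error(r2_score(matrix(1, 4, 1), matrix(0, 4, 1)),
               class = "neuroar_undefined_score")
})

test_that("evaluate_model spans oracle, baseline, and noise-ceiling regimes", {
  # oracle: a noise-free VAR trajectory from a random start is perfectly
  # predicted (at every lag) by its own transition matrix
  cp <- make_coupling(6, 0.4, 1, 0.8, seed = 2)
  A <- cp$couplings[1, , ]
  X <- matrix(0, 40, 6)
  set.seed(3); X[1, ] <- rnorm(6)
  for (t in 2:40) X[t, ] <- A %*% X[t - 1, ]
  ts <- parcel_ts(X, "s", "r", "c", 1.49)
  mA <- build_model(model_config("linear_multi", k = 1, bias = FALSE, seed = 1), 6)
  mA$params$W <- A
  ev <- evaluate_model(mA, ts, lags = 1:3)
  expect_equal(ev$r2_mean, rep(1, 3), tolerance = 1e-10)

  # zero predictor on z-scored data scores ~0 (window-mean baseline)
  zts <- zscore_per_run(simulate_run(cp$couplings, NULL, 1, 500, 100, seed = 4))
  m0 <- build_model(model_config("linear_uni", k = 1, seed = 1), 6)
  m0$params$W[] <- 0; m0$params$b[] <- 0
  ev0 <- evaluate_model(m0, zts, lags = 1)
  expect_lt(abs(ev0$r2_mean), 0.05)

  # r2_mean is the mean of the masked per-parcel scores
  mask <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  evm <- evaluate_model(mA, ts, lags = 1, mask = mask)
  expect_equal(evm$r2_mean, mean(evm$r2_parcels[[1]][mask]))
})

test_that("a matched linear model reaches the theoretical noise ceiling", {
  # diagonal AR with a = sqrt(0.7): stationary noise/signal variance = 0.3,
  # so the ceiling is R2 = 0.70
  P <- 10
  A <- diag(sqrt(0.7), P)
  tr_ts <- simulate_run(A, NULL, noise_sd = 1, T_len = 4000, burn_in = 200, seed = 8)
  te_ts <- simulate_run(A, NULL, noise_sd = 1, T_len = 2000, burn_in = 200, seed = 9)
  ws <- make_windows(tr_ts, k = 1, l = 1)
  m <- fit_model(build_model(model_config("linear_uni", k = 1, seed = 1), P), ws,
                 epochs = 30, batch_size = 512, learning_rate = 0.02, seed = 1)
  ev <- evaluate_model(m, te_ts, lags = 1)
  expect_equal(ev$r2_mean, 0.70, tolerance = 0.05)
})

test_that("wilcoxon_paired matches exact enumeration and handles degeneracies", {
  # n = 6, all differences positive and distinct: p = 2/64
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(wilcoxon_paired(x, rep(0, 6)), 2 / 64)

  # degenerate: identical samples
  expect_warning(p <- wilcoxon_paired(x, x), "zero")
  expect_equal(p, 1)

  # antisymmetric differences: exact two-sided p = 1 despite tied ranks
  d <- c(1.5, 2.5, 3.5, -1.5, -2.5, -3.5)
  expect_equal(wilcoxon_paired(d, rep(0, 6)), 1)

  # 2^n enumeration oracle on random cases (with and without ties)
  set.seed(77)
  for (i in 1:5) {
    d <- round(rnorm(8), 1)
    d <- d[d != 0]
    expect_equal(wilcoxon_paired(d, rep(0, length(d))), wilcoxon_enumerate(d),
                 tolerance = 1e-12)
  }

  # agreement with stats::wilcox.test exact branch when there are no ties
  d2 <- c(0.3, -1.2, 2.4, 0.7, -0.5, 1.9, 1.1)
  expect_equal(wilcoxon_paired(d2, rep(0, 7)),
               stats::wilcox.test(d2, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("bh_fdr implements the step-up rule with monotone adjusted p", {
  res <- bh_fdr(c(0.01, 0.04, 0.3), alpha = 0.05)
  expect_identical(res$reject, c(TRUE, FALSE, FALSE)) # 0.04 > 0.05 * 2/3
  expect_identical(bh_fdr(rep(1, 5))$reject, rep(FALSE, 5))
  expect_identical(bh_fdr(0.04, alpha = 0.05)$reject, TRUE)
  expect_identical(bh_fdr(numeric(0))$p_adj, numeric(0))

  set.seed(5)
  p <- runif(30)
  adj <- bh_fdr(p)$p_adj
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("subject_specificity requires at least two aligned subjects", {
  coh <- make_test_cohort(n_subjects = 1, n_parcels = 6, n_runs = 4,
                          run_length = 120, seed = 3, n_train = 2)
  m <- quick_fit(model_config("linear_multi", k = 1, seed = 1), coh$train,
                 epochs = 5)
  expect_error(subject_specificity(list("sub-01" = m), coh$test),
               class = "neuroar_alignment")
})

test_that("group and individual models coincide for a single subject", {
  coh <- make_test_cohort(n_subjects = 1, n_parcels = 8, n_runs = 6,
                          run_length = 160, seed = 13, n_train = 4)
  tab <- group_vs_individual(coh$train, coh$test,
                             model_config("linear_multi", k = 1, seed = 1),
                             total_train_runs = 4, lags = 1, epochs = 8,
                             seed = 5)
  expect_equal(tab$d, rep(0, nrow(tab)))
})

test_that("data_scaling is reproducible and its full-set point equals standard training", {
  coh <- make_test_cohort(n_subjects = 1, n_parcels = 8, n_runs = 7,
                          run_length = 160, seed = 17, n_train = 5)
  cfg <- model_config("linear_multi", k = 1, seed = 1)
  t1 <- data_scaling(coh$train, coh$test, cfg, run_counts = c(2, 5),
                     repetitions = 2, epochs = 8, seed = 3)
  t2 <- data_scaling(coh$train, coh$test, cfg, run_counts = c(2, 5),
                     repetitions = 2, epochs = 8, seed = 3)
  expect_identical(t1, t2)

  # the n = all point reproduces training on the full set with the same stream
  full <- fit_model(build_model(cfg, 8), make_windows(coh$train, k = 1, l = 1),
                    epochs = 8, batch_size = 128, learning_rate = 0.01,
                    seed = substream_seed(3, "fit", 5, 1))
  ev <- evaluate_model(full, coh$test, lags = 1)
  expect_equal(t1$r2_mean[t1$n_runs == 5 & t1$repetition == 1],
               mean(ev$r2_mean))

  expect_error(data_scaling(coh$train, coh$test, cfg, run_counts = 99),
               class = "neuroar_config_error")
})

test_that("learning curves rise with more training runs", {
  coh <- make_test_cohort(n_subjects = 1, n_parcels = 15, n_runs = 10,
                          run_length = 240, seed = 23, n_train = 8)
  cfg <- model_config("linear_multi", k = 1, seed = 1)
  tab <- data_scaling(coh$train, coh$test, cfg, run_counts = c(1, 8),
                      repetitions = 3, epochs = 20, batch_size = 256,
                      learning_rate = 0.02, seed = 11)
  lo <- mean(tab$r2_mean[tab$n_runs == 1])
  hi <- mean(tab$r2_mean[tab$n_runs == 8])
  expect_gt(hi, lo)
})
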