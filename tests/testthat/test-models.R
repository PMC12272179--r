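test_that("forward passes follow each family's wiring", {
  # univariate linear, k = 1: prediction = w * last value
  m <- build_model(model_config("linear_uni", k = 1, bias = FALSE, seed = 1), 2)
  m$params$W <- matrix(0.5, 2, 1)
  win <- array(2, c(3, 1, 2))
  expect_equal(model_forward(m, win), matrix(1, 3, 2))

  # multivariate linear with a window-selector W reduces to persistence
  P <- 3; k <- 2
  m2 <- build_model(model_config("linear_multi", k = k, bias = FALSE, seed = 1), P)
  W <- matrix(0, P, k * P)
  for (p in seq_len(P)) W[p, (p - 1) * k + k] <- 1 # select last time point
  m2$params$W <- W
  win2 <- array(rnorm(5 * k * P), c(5, k, P))
  expect_equal(model_forward(m2, win2), win2[, k, ])

  expect_error(model_forward(m2, array(0, c(5, 3, P))),
               class = "neuroar_contract")
})

test_that("a linear-mode MLP collapses to the product of its layer matrices", {
  P <- 4; k <- 3
  cfg <- model_config("mlp_multi", k = k, hidden_sizes = c(6, 5),
                      nonlinear = FALSE, bias = FALSE, seed = 8)
  m <- build_model(cfg, P)
  win <- array(rnorm(7 * k * P), c(7, k, P))
  dense <- m$params[[3]]$W %*% m$params[[2]]$W %*% m$params[[1]]$W
  X <- matrix(win, 7, k * P)
  expect_equal(model_forward(m, win), X %*% t(dense), tolerance = 1e-6)

  # univariate MLP: parcels are fully independent
  cfg_u <- model_config("mlp_uni", k = k, hidden_sizes = 4, seed = 3)
  mu <- build_model(cfg_u, P)
  win2 <- win
  win2[, , 2] <- win2[, , 2] + 1 # perturb one parcel's inputs only
  p1 <- model_forward(mu, win)
  p2 <- model_forward(mu, win2)
  expect_equal(p1[, -2], p2[, -2])
  expect_false(isTRUE(all.equal(p1[, 2], p2[, 2])))
})

test_that("Chebyshev recurrence matches the spectral-domain evaluation", {
  sp <- scaled_laplacian(random_connectome(6, 0.4, seed = 2))
  x <- matrix(rnorm(12), 6, 2)
  expect_equal(chebyshev_basis_apply(sp, x, 1), list(x))
  b2 <- chebyshev_basis_apply(sp, x, 2)
  expect_equal(b2[[2]], sp$scaled_laplacian %*% x)

  # dense-eigendecomposition oracle: T_k(L~) = U T_k(Lambda~) U'
  eg <- eigen(sp$scaled_laplacian, symmetric = TRUE)
  B <- chebyshev_basis_apply(sp, x, 4)
  for (kk in 0:3) {
    Tk <- cos(kk * acos(pmin(1, pmax(-1, eg$values))))
    ref <- eg$vectors %*% (Tk * t(eg$vectors)) %*% x
    expect_equal(B[[kk + 1]], ref, tolerance = 1e-8)
  }
})

test_that("chebnet forward equals its assembled dense operator in linear mode", {
  # 1 layer, K = 1, k = 1, theta_0 = 1, no bias: identity (predict last value)
  sp <- scaled_laplacian(random_connectome(5, 0.3, seed = 4))
  cfg1 <- model_config("chebnet", k = 1, cheb_order = 1, nonlinear = FALSE,
                       bias = FALSE, seed = 1)
  m1 <- build_model(cfg1, 5, sp)
  m1$params[[1]]$theta[1, 1, 1] <- 1
  win1 <- array(rnorm(4 * 1 * 5), c(4, 1, 5))
  expect_equal(chebnet_forward(m1, win1), win1[, 1, ])

  # multi-layer linear chebnet == dense operator built from theta and powers of L~
  P <- 6; k <- 2; K <- 3
  sp <- scaled_laplacian(random_connectome(P, 0.4, seed = 2))
  cfg <- model_config("chebnet", k = k, hidden_sizes = 4, cheb_order = K,
                      nonlinear = FALSE, seed = 5)
  m <- build_model(cfg, P, sp)
  S <- sp$scaled_laplacian
  Tk <- list(diag(P), S, 2 * S %*% S - diag(P))
  apply_layer <- function(X, theta, b) { # X: P x C_in
    out <- matrix(0, P, dim(theta)[3])
    for (co in seq_len(dim(theta)[3])) for (ci in seq_len(dim(theta)[2]))
      for (kk in seq_len(K))
        out[, co] <- out[, co] + theta[kk, ci, co] * (Tk[[kk]] %*% X[, ci])
    if (!is.null(b)) out <- sweep(out, 2, b, "+")
    out
  }
  win <- array(rnorm(5 * k * P), c(5, k, P))
  ref <- t(sapply(seq_len(5), function(n) {
    X <- t(win[n, , ])
    for (l in seq_along(m$params)) X <- apply_layer(X, m$params[[l]]$theta,
                                                    m$params[[l]]$b)
    X[, 1]
  }))
  expect_equal(chebnet_forward(m, win), ref, tolerance = 1e-6)

  # edgeless graph: no inter-node leakage even at K >= 2
  expect_warning(sp0 <- scaled_laplacian(support_connectome(matrix(0, 4, 4))),
                 "edgeless")
  cfg0 <- model_config("chebnet", k = 2, cheb_order = 3, nonlinear = TRUE, seed = 2)
  m0 <- build_model(cfg0, 4, sp0)
  w1 <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  w2 <- w1
  w2[, , 1] <- w2[, , 1] + 5
  expect_equal(chebnet_forward(m0, w1)[, -1], chebnet_forward(m0, w2)[, -1])
})

test_that("parameter counts match the closed-form formulas", {
  # benchmark-scale configurations: 197 parcels, printed input lengths
  lin_uni <- build_model(model_config("linear_uni", k = 256, seed = 1), 197)
  expect_identical(count_parameters(lin_uni), 197L * (256L + 1L))
  expect_identical(count_parameters(lin_uni), 50629L)

  lin_multi <- build_model(model_config("linear_multi", k = 3, seed = 1), 197)
  expect_identical(count_parameters(lin_multi), 197L * (3L * 197L + 1L))
  expect_identical(count_parameters(lin_multi), 116624L)

  expect_identical(count_parameters(
    build_model(model_config("linear_uni", k = 1, seed = 1), 1)), 2L)

  # chebnet: per layer K * C_in * C_out + C_out
  ch <- build_model(model_config("chebnet", k = 4, hidden_sizes = 8,
                                 cheb_order = 3, seed = 1), 10,
                    scaled_laplacian(random_connectome(10, 0.2, seed = 1)))
  expect_identical(count_parameters(ch), (3L * 4L * 8L + 8L) + (3L * 8L * 1L + 1L))
})

test_that("training is deterministic, convergent, and flags divergence", {
  ts <- simulate_run(matrix(0.5), NULL, noise_sd = 1, T_len = 20000,
                     burn_in = 200, seed = 4)
  ws <- make_windows(ts, k = 1, l = 1)
  cfg <- model_config("linear_uni", k = 1, seed = 1)
  m1 <- fit_model(build_model(cfg, 1), ws, epochs = 40, batch_size = 512,
                  learning_rate = 0.02, seed = 7)
  m2 <- fit_model(build_model(cfg, 1), ws, epochs = 40, batch_size = 512,
                  learning_rate = 0.02, seed = 7)
  expect_identical(m1$params, m2$params)

  # gradient training reaches the OLS optimum, which is consistent for a = 0.5
  x <- ws$inputs[, 1, 1]; y <- ws$targets[, 1]
  w_ols <- stats::coef(stats::lm(y ~ x))[2]
  expect_equal(unname(m1$params$W[1, 1]), unname(w_ols), tolerance = 0.01)
  expect_equal(unname(m1$params$W[1, 1]), 0.5, tolerance = 0.01)

  # full-batch training on a convex problem: loss non-increasing
  ws_small <- make_windows(simulate_run(matrix(0.5), NULL, 1, 500, 50, seed = 2),
                           k = 1, l = 1)
  m3 <- fit_model(build_model(model_config("linear_uni", k = 1, seed = 3), 1),
                  ws_small, epochs = 30, batch_size = nrow(ws_small$targets),
                  learning_rate = 0.002, seed = 1)
  expect_true(all(diff(m3$training_history$train_loss) <= 1e-6))

  expect_error(
    fit_model(build_model(model_config("linear_uni", k = 1, seed = 1), 1),
              ws_small, epochs = 3, batch_size = 64, learning_rate = 1e200,
              seed = 1),
    class = "neuroar_divergence")
})

test_that("validation checkpointing returns the best-epoch parameters", {
  ts <- simulate_run(matrix(0.6), NULL, 1, 800, 50, seed = 5)
  ws <- make_windows(ts, k = 1, l = 1)
  val_ts <- simulate_run(matrix(0.6), NULL, 1, 300, 50, seed = 6)
  val <- make_windows(val_ts, k = 1, l = 1)
  m <- fit_model(build_model(model_config("linear_uni", k = 1, seed = 2), 1),
                 ws, val = val, epochs = 20, batch_size = 256,
                 learning_rate = 0.05, seed = 3)
  # returned parameters reproduce the minimum recorded validation loss
  best <- min(m$training_history$val_loss)
  got <- mean((model_forward(m, val$inputs) - val$targets)^2)
  expect_equal(got, best, tolerance = 1e-12)
})

test_that("iterated prediction composes the model like matrix powers", {
  # scalar model yhat_{t+1} = 0.5 x_t on constant input 1: lag 3 gives 0.125
  m <- build_model(model_config("linear_uni", k = 1, bias = FALSE, seed = 1), 1)
  m$params$W <- matrix(0.5, 1, 1)
  ts <- parcel_ts(matrix(1, 10, 1), "s", "r", "c", 1.49)
  it <- predict_iterated(m, ts, l_max = 3)
  expect_equal(it$pred[[3]][10, 1], 0.125)

  # lag-1 output equals a plain forward pass on the same windows (bitwise)
  cp <- make_coupling(5, 0.4, 1, 0.8, seed = 2)
  ts2 <- simulate_run(cp$couplings, NULL, 1, 60, 20, seed = 3)
  mm <- build_model(model_config("linear_multi", k = 2, seed = 4), 5)
  it2 <- predict_iterated(mm, ts2, l_max = 2)
  ws <- make_windows(ts2, k = 2, l = 1)
  expect_identical(it2$pred[[1]][3:60, ], model_forward(mm, ws$inputs))

  # linear k=1 model with matrix A: lag-l prediction = A^l x_t
  A <- cp$couplings[1, , ]
  mA <- build_model(model_config("linear_multi", k = 1, bias = FALSE, seed = 1), 5)
  mA$params$W <- A
  it3 <- predict_iterated(mA, ts2, l_max = 4)
  s <- 30
  for (l in 1:4) {
    ref <- ts2$data[s - l, ]
    for (i in seq_len(l)) ref <- A %*% ref
    expect_equal(it3$pred[[l]][s, ], as.vector(ref), tolerance = 1e-8)
  }

  expect_error(predict_iterated(mA, parcel_ts(matrix(1, 3, 5), "s", "r", "c", 1.49),
                                l_max = 4),
               class = "neuroar_contract")
})

test_that("grid search scores by mean validation R2 and breaks ties first-wins", {
  coh <- make_test_cohort(n_subjects = 1, n_parcels = 10, n_runs = 5,
                          run_length = 200, seed = 31, n_train = 3)
  sdat <- list("sub-01" = list(
    train_windows = make_windows(coh$train, k = 1, l = 1),
    val_runs = coh$test))
  cfg <- model_config("linear_multi", k = 1, seed = 1)
  gs1 <- grid_search(list(cfg), sdat, epochs = 10, seed = 2)
  expect_identical(gs1$best, cfg)
  expect_identical(gs1$best_index, 1L)

  gs2 <- grid_search(list(cfg, cfg), sdat, epochs = 10, seed = 2)
  expect_identical(gs2$best_index, 1L) # exact tie -> first in grid order
})

test_that("grid search prefers the generating model family on synthetic data", {
  hits <- vapply(1:10, function(sd) {
    coh <- make_test_cohort(n_subjects = 1, n_parcels = 15, n_runs = 8,
                            run_length = 240, seed = 300 + sd, n_train = 5)
    sdat <- list("sub-01" = list(
      train_windows = make_windows(coh$train, k = 1, l = 1),
      val_runs = coh$test))
    grid <- list(model_config("linear_uni", k = 1, seed = 1),
                 model_config("linear_multi", k = 1, seed = 1))
    gs <- grid_search(grid, sdat, epochs = 25, batch_size = 256,
                      learning_rate = 0.02, seed = 42 + sd)
    gs$best$family == "linear_multi"
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("direct multi-lag training reduces to fit at L = 1 and is competitive", {
  coh <- make_test_cohort(n_subjects = 1, n_parcels = 8, n_runs = 5,
                          run_length = 200, seed = 41, n_train = 3)
  cfg <- model_config("linear_multi", k = 1, seed = 1)
  ws1 <- make_windows(coh$train, k = 1, l = 1)
  direct <- fit_direct_multilag(cfg, list(ws1), P = 8, epochs = 10, seed = 9)
  ref <- fit_model(build_model(cfg, 8), ws1, epochs = 10,
                   seed = substream_seed(9, "lag", 1))
  expect_identical(direct[[1]]$params, ref$params)

  # per-lag models are independent of training order
  ws2 <- make_windows(coh$train, k = 1, l = 2)
  ab <- fit_direct_multilag(cfg, list(ws1, ws2), P = 8, epochs = 10, seed = 9)
  ba <- fit_direct_multilag(cfg, list(ws2, ws1), P = 8, epochs = 10, seed = 9)
  expect_identical(ab[[1]]$params, ba[[2]]$params)
  expect_identical(ab[[2]]$params, ba[[1]]$params)
})

test_that("direct lag-2 models match iterated lag-2 accuracy on linear systems", {
  gaps <- vapply(1:20, function(sd) {
    coh <- make_test_cohort(n_subjects = 1, n_parcels = 8, n_runs = 6,
                            run_length = 200, seed = 600 + sd, n_train = 4)
    cfg <- model_config("linear_multi", k = 1, seed = 1)
    m1 <- quick_fit(cfg, coh$train, epochs = 25, seed = 3)
    ev_it <- evaluate_model(m1, coh$test, lags = 2)
    ws2 <- make_windows(coh$train, k = 1, l = 2)
    m2 <- fit_model(build_model(cfg, 8), ws2, epochs = 25, batch_size = 256,
                    learning_rate = 0.02, seed = 3)
    r2_direct <- mean(vapply(coh$test, function(ts) {
      te <- make_windows(ts, k = 1, l = 2)
      mean(r2_score(te$targets, model_forward(m2, te$inputs)))
    }, numeric(1)))
    r2_direct - mean(ev_it$r2_mean)
  }, numeric(1))
  expect_gte(stats::median(gaps), -0.05)
})
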