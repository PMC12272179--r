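test_that("coupling draws are seeded, exactly rescaled, and respect a base stack", {
  # seeded determinism
  a <- make_coupling(2, density = 1, order = 1, radius = 0.5, seed = 7)
  b <- make_coupling(2, density = 1, order = 1, radius = 0.5, seed = 7)
  expect_identical(a, b)

  # companion radius hits the target exactly (checked via eigendecomposition
  # of the 2P x 2P companion matrix)
  cp <- make_coupling(10, density = 0.3, order = 2, radius = 0.9, seed = 3)
  expect_equal(companion_spectral_radius(cp$couplings), 0.9, tolerance = 1e-6)

  # divergence = 0 with a base returns the base (already at target radius),
  # support unchanged
  mix <- make_coupling(10, density = 0.3, order = 2, radius = 0.9,
                       base = cp$couplings, divergence = 0, seed = 99)
  expect_equal(mix$couplings, cp$couplings, tolerance = 1e-12)
  expect_identical(mix$support, cp$support)

  # support is symmetric, zero-diagonal, at the requested edge count
  m <- sum(cp$support) / 2
  expect_equal(m, round(0.3 * 10 * 9 / 2))
  expect_identical(cp$support, t(cp$support))
  expect_true(all(diag(cp$support) == 0))
})

test_that("shared response is low-pass, standardized, and zero at amplitude 0", {
  expect_identical(make_shared_response(64, 3, amplitude = 0, cutoff_hz = 0.05,
                                        tr = 1.49, seed = 1),
                   matrix(0, 64, 3))
  s1 <- make_shared_response(256, 4, 1.5, 0.05, 1.49, seed = 5)
  s2 <- make_shared_response(256, 4, 1.5, 0.05, 1.49, seed = 5)
  expect_identical(s1, s2)
  expect_equal(colMeans(s1), rep(0, 4), tolerance = 1e-10)
  expect_equal(apply(s1, 2, function(x) sqrt(mean(x^2))), rep(1.5, 4),
               tolerance = 1e-10)

  # spectral content: almost no power above the cutoff
  s <- make_shared_response(4096, 1, 1, cutoff_hz = 0.05, tr = 1.49, seed = 2)
  hf <- high_frequency_fraction(power_spectrum(s, tr = 1.49), 0.05)
  expect_lt(hf, 0.05)

  expect_error(make_shared_response(64, 2, 1, cutoff_hz = 0.4, tr = 1.49),
               class = "neuroar_invalid_config")
})

test_that("simulate_run realizes the VAR recursion deterministically", {
  # homogeneous recursion from zero state stays at zero
  z <- simulate_run(matrix(0.5), shared = matrix(0, 50, 1), noise_sd = 0,
                    T_len = 50, burn_in = 5, seed = 1)
  expect_identical(z$data, matrix(0, 50, 1, dimnames = list(NULL, "p001")))

  # AR(1) stationary variance sigma^2 / (1 - a^2) = 4/3
  ts <- simulate_run(matrix(0.5), NULL, noise_sd = 1, T_len = 20000,
                     burn_in = 200, seed = 4)
  expect_equal(stats::var(as.vector(ts$data)), 1 / (1 - 0.25), tolerance = 0.1)

  expect_identical(simulate_run(matrix(0.5), NULL, 1, 100, 10, seed = 3)$data,
                   simulate_run(matrix(0.5), NULL, 1, 100, 10, seed = 3)$data)

  # unstable coupling explodes with an informative error
  expect_error(simulate_run(matrix(2), NULL, 1, 1200, 10, seed = 1),
               class = "neuroar_explosion")
})

test_that("generate_cohort lays out runs, shared responses, and couplings", {
  cc <- cohort_config(n_subjects = 3, n_parcels = 5,
                      n_runs_per_condition = c(train = 4, test = 2),
                      run_length = 60, rest_conditions = character(),
                      subject_divergence = 0, seed = 2)
  coh <- generate_cohort(cc)
  expect_length(coh$runs, 3 * 6)

  # divergence 0: all subjects share identical couplings
  expect_identical(coh$truth$couplings[["sub-01"]], coh$truth$couplings[["sub-03"]])

  # shared component is identical across subjects within a (condition, run):
  # differencing two subjects' runs removes it exactly
  r1 <- Filter(function(r) r$subject == "sub-01" & r$run == "run-01" &
                 r$condition == "train", coh$runs)[[1]]
  r2 <- Filter(function(r) r$subject == "sub-02" & r$run == "run-01" &
                 r$condition == "train", coh$runs)[[1]]
  sh <- coh$truth$shared_responses[["train/run-01"]]
  # subjects share couplings here, so (X1 - sh) and (X2 - sh) are two
  # independent realizations of the same VAR; both must stay finite and
  # differ (noise is subject-specific), while sh itself is stored truth
  expect_false(isTRUE(all.equal(r1$data, r2$data)))
  expect_equal(dim(sh), c(60, 5))

  # rest-like conditions carry an all-zero shared component
  cc_rest <- cohort_config(n_subjects = 2, n_parcels = 4,
                           n_runs_per_condition = c(friends = 3, rest = 2),
                           run_length = 50, seed = 3)
  coh_rest <- generate_cohort(cc_rest)
  expect_identical(coh_rest$truth$shared_responses[["rest/run-01"]],
                   matrix(0, 50, 4))
  expect_gt(max(abs(coh_rest$truth$shared_responses[["friends/run-01"]])), 0)
})

test_that("cohort generation is a pure function of the config and stable", {
  cc <- cohort_config(n_subjects = 2, n_parcels = 8,
                      n_runs_per_condition = c(friends = 3),
                      run_length = 80, subject_divergence = 0.7, seed = 9)
  c1 <- generate_cohort(cc)
  c2 <- generate_cohort(cc)
  expect_identical(c1$runs[[3]]$data, c2$runs[[3]]$data)
  expect_identical(c1$truth, c2$truth)

  # stability invariant across subjects
  for (s in names(c1$truth$couplings))
    expect_lte(companion_spectral_radius(c1$truth$couplings[[s]]),
               cc$spectral_radius + 1e-9)
})

test_that("fully divergent subjects share no signal beyond the shared response", {
  cc <- cohort_config(n_subjects = 2, n_parcels = 6,
                      n_runs_per_condition = c(friends = 1),
                      run_length = 2500, subject_divergence = 1, seed = 12)
  coh <- generate_cohort(cc)
  sh <- coh$truth$shared_responses[["friends/run-01"]]
  x1 <- coh$runs[[1]]$data - sh
  x2 <- coh$runs[[2]]$data - sh
  r <- vapply(seq_len(6), function(p) stats::cor(x1[, p], x2[, p]), numeric(1))
  expect_lt(abs(mean(r)), 0.1)
})

test_that("OLS VAR fit on a long run recovers the generating couplings", {
  cp <- make_coupling(10, density = 0.2, order = 1, radius = 0.85, seed = 6)
  ts <- simulate_run(cp$couplings, NULL, noise_sd = 1, T_len = 10000,
                     burn_in = 200, seed = 7)
  X <- ts$data[-nrow(ts$data), ]
  Y <- ts$data[-1, ]
  A_hat <- t(qr.solve(X, Y)) # per-target-row OLS, the independent oracle
  expect_lt(max(abs(A_hat - cp$couplings[1, , ])), 0.05)
})

test_that("parcel coordinates are seeded and pairwise distinct", {
  expect_identical(parcel_coordinates(50, seed = 4), parcel_coordinates(50, seed = 4))
  d <- stats::dist(parcel_coordinates(50, seed = 4))
  expect_true(all(d > 0))
  expect_length(as.vector(stats::dist(parcel_coordinates(2, seed = 1))), 1)
})
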