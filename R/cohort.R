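#' Configuration of a synthetic multi-subject cohort
#'
#' Describes the shape and dynamics of a simulated cohort of parcel-level
#' BOLD-like recordings: a stable vector auto-regression (VAR) on a sparse
#' symmetric coupling graph per subject, plus a low-frequency stimulus-evoked
#' component shared across subjects within each (condition, run), plus
#' Gaussian innovation noise. Conditions listed in `rest_conditions` carry no
#' shared component, emulating resting-state acquisitions.
#'
#' Defaults give a desk-scale cohort: 6 subjects, 30 parcels, 68 movie-like
#' runs (split downstream into 44 train / 12 validation / 12 test) plus 5
#' rest-like runs, each 480 time points at TR = 1.49 s (about 12 min per run).
#'
#' @param n_subjects number of subjects.
#' @param n_parcels number of parcels `P`.
#' @param n_runs_per_condition named integer vector, runs per condition label.
#' @param run_length time points per run `T`.
#' @param tr sampling interval, seconds.
#' @param coupling_density fraction of off-diagonal parcel pairs coupled.
#' @param coupling_order VAR order `p` of the generator.
#' @param spectral_radius target spectral radius of the VAR companion matrix,
#'   in (0, 1); controls how slowly the intrinsic dynamics decay.
#' @param shared_amplitude standard deviation of the shared evoked component
#'   (0 gives a purely intrinsic, rest-like cohort).
#' @param shared_cutoff_hz low-pass cutoff of the shared component, Hz.
#' @param subject_divergence in `[0, 1]`: 0 gives all subjects identical
#'   couplings, 1 fully subject-specific couplings (same support graph).
#' @param noise_sd innovation standard deviation.
#' @param burn_in initial samples discarded to erase the zero initial state.
#' @param rest_conditions condition labels treated as rest (no shared signal).
#' @param seed integer base seed; the cohort is a pure function of the config.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 6,
                          n_parcels = 30,
                          n_runs_per_condition = c(friends = 68, rest = 5),
                          run_length = 480,
                          tr = 1.49,
                          coupling_density = 0.10,
                          coupling_order = 1,
                          spectral_radius = 0.9,
                          shared_amplitude = 0.5,
                          shared_cutoff_hz = 0.05,
                          subject_divergence = 0.5,
                          noise_sd = 1,
                          burn_in = 200,
                          rest_conditions = "rest",
                          seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_parcels = as.integer(n_parcels),
              n_runs_per_condition = n_runs_per_condition,
              run_length = as.integer(run_length), tr = tr,
              coupling_density = coupling_density,
              coupling_order = as.integer(coupling_order),
              spectral_radius = spectral_radius,
              shared_amplitude = shared_amplitude,
              shared_cutoff_hz = shared_cutoff_hz,
              subject_divergence = subject_divergence,
              noise_sd = noise_sd, burn_in = as.integer(burn_in),
              rest_conditions = rest_conditions, seed = as.integer(seed))
  check_that(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  check_that(cfg$n_parcels >= 2, "n_parcels must be >= 2")
  check_that(length(cfg$n_runs_per_condition) >= 1 &&
               !is.null(names(cfg$n_runs_per_condition)) &&
               all(nzchar(names(cfg$n_runs_per_condition))),
             "n_runs_per_condition must be a named vector of counts")
  check_that(cfg$run_length > cfg$coupling_order, "run_length must exceed coupling_order")
  check_that(cfg$spectral_radius > 0 && cfg$spectral_radius < 1,
             "spectral_radius must lie in (0, 1)")
  check_that(cfg$coupling_density > 0 && cfg$coupling_density <= 1,
             "coupling_density must lie in (0, 1]")
  check_that(cfg$shared_amplitude >= 0, "shared_amplitude must be >= 0")
  check_that(cfg$subject_divergence >= 0 && cfg$subject_divergence <= 1,
             "subject_divergence must lie in [0, 1]")
  check_that(cfg$burn_in >= cfg$coupling_order, "burn_in must be >= coupling_order")
  structure(cfg, class = "cohort_config")
}

# companion matrix of a VAR(p) coefficient stack (p, P, P)
var_companion <- function(couplings) {
  p <- dim(couplings)[1]; P <- dim(couplings)[2]
  comp <- matrix(0, p * P, p * P)
  for (j in seq_len(p)) comp[seq_len(P), (j - 1) * P + seq_len(P)] <- couplings[j, , ]
  if (p > 1)
    comp[P + seq_len((p - 1) * P), seq_len((p - 1) * P)] <- diag((p - 1) * P)
  comp
}

#' Spectral radius of a VAR coefficient stack's companion matrix
#'
#' @param couplings array `(p, P, P)` of VAR coefficients (or a `P x P` matrix
#'   for order 1).
#' @return largest eigenvalue modulus of the companion matrix.
#' @export
companion_spectral_radius <- function(couplings) {
  couplings <- as_coupling_stack(couplings)
  max(Mod(eigen(var_companion(couplings), only.values = TRUE)$values))
}

as_coupling_stack <- function(couplings) {
  if (is.matrix(couplings)) {
    a <- array(0, c(1, nrow(couplings), ncol(couplings)))
    a[1, , ] <- couplings
    couplings <- a
  }
  check_that(length(dim(couplings)) == 3 && dim(couplings)[2] == dim(couplings)[3],
             "couplings must be a (order, P, P) array or a P x P matrix")
  couplings
}

# rescale a stack so the companion radius equals `radius` exactly:
# scaling A_j -> c^j A_j scales every companion eigenvalue by c
rescale_to_radius <- function(couplings, radius) {
  rho <- companion_spectral_radius(couplings)
  if (!is.finite(rho) || rho <= 0) return(NULL)
  cc <- radius / rho
  p <- dim(couplings)[1]
  for (j in seq_len(p)) couplings[j, , ] <- cc^j * couplings[j, , ]
  couplings
}

#' Draw a stable sparse VAR coupling stack on a symmetric support graph
#'
#' Off-diagonal coupling support is sampled symmetrically at the requested
#' density; diagonal self-couplings are always present (and drawn positive,
#' giving BOLD-like positive autocorrelation). Coefficients are rescaled so the
#' VAR companion-matrix spectral radius equals `radius` exactly. When a `base`
#' stack is supplied, the result is `(1 - divergence) * base + divergence *
#' fresh` with the fresh draw on the *same* support, rescaled to `radius`;
#' `divergence = 0` returns the base (rescaled), and the support graph is
#' shared by construction.
#'
#' @param P number of parcels (>= 2).
#' @param density fraction of off-diagonal pairs coupled, in (0, 1].
#' @param order VAR order `p`.
#' @param radius target companion spectral radius in (0, 1).
#' @param base optional `(order, P, P)` stack to perturb.
#' @param divergence mixing fraction in `[0, 1]` used when `base` is given.
#' @param seed integer seed; the draw is deterministic given all arguments.
#' @return list with `couplings` (`(order, P, P)` array) and `support`
#'   (`P x P` binary symmetric adjacency, zero diagonal).
#' @export
make_coupling <- function(P, density, order = 1, radius = 0.9,
                          base = NULL, divergence = 0, seed = 1) {
  check_that(P >= 2, "P must be >= 2")
  check_that(radius > 0 && radius < 1, "radius must lie in (0, 1)")
  check_that(density > 0 && density <= 1, "density must lie in (0, 1]")
  if (!is.null(base)) {
    base <- as_coupling_stack(base)
    check_that(all(dim(base) == c(order, P, P)),
               "base shape must match (order, P, P)")
  }

  draw_stack <- function(support, sub_seed) {
    deg <- pmax(1, rowSums(support))
    with_seed(sub_seed, {
      st <- array(0, c(order, P, P))
      for (j in seq_len(order)) {
        A <- matrix(0, P, P)
        # positive off-diagonal couplings: connectome edges emulate positive
        # co-fluctuation, the structure a functional-connectivity prior carries
        A[support == 1] <- abs(stats::rnorm(sum(support), sd = 0.6)) / sqrt(deg[row(support)[support == 1]])
        diag(A) <- stats::runif(P, 0.4, 0.8) * 0.6^(j - 1)
        st[j, , ] <- A
      }
      st
    })
  }

  if (is.null(base)) {
    m <- max(1L, round(density * P * (P - 1) / 2))
    support <- with_seed(substream_seed(seed, "support"), {
      pairs <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
      sel <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
      A <- matrix(0L, P, P)
      A[sel] <- 1L
      A + t(A)
    })
  } else {
    support <- support_of(base)
  }

  for (attempt in 0:100) {
    if (attempt == 100)
      stop(rlang::error_cnd(class = "neuroar_degenerate_draw",
                            message = "coupling rescaling degenerate after 100 attempts"))
    fresh <- draw_stack(support, substream_seed(seed, "coeffs", attempt))
    mixed <- if (is.null(base)) fresh else (1 - divergence) * base + divergence * fresh
    out <- rescale_to_radius(mixed, radius)
    if (!is.null(out) && all(is.finite(out))) break
  }
  list(couplings = out, support = support)
}

support_of <- function(couplings) {
  couplings <- as_coupling_stack(couplings)
  P <- dim(couplings)[2]
  A <- matrix(0L, P, P)
  for (j in seq_len(dim(couplings)[1])) A <- A | (couplings[j, , ] != 0)
  A <- A | t(A)
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  A
}

#' Generate a low-frequency shared (stimulus-evoked) component
#'
#' Each column is white Gaussian noise low-pass filtered in the Fourier domain
#' (all power above `cutoff_hz` removed), standardized to mean 0 and unit
#' population standard deviation, then scaled to `amplitude`.
#'
#' @param T_len number of time points (>= 2).
#' @param P number of parcels.
#' @param amplitude standard deviation of each column; 0 returns zeros.
#' @param cutoff_hz low-pass cutoff, must be below Nyquist `1 / (2 tr)`.
#' @param tr sampling interval, seconds.
#' @param seed integer seed.
#' @return `T_len x P` numeric matrix.
#' @export
make_shared_response <- function(T_len, P, amplitude, cutoff_hz, tr, seed = 1) {
  check_that(T_len >= 2, "T_len must be >= 2")
  check_that(amplitude >= 0, "amplitude must be >= 0")
  check_that(cutoff_hz < 1 / (2 * tr),
             sprintf("cutoff_hz (%.4f) must be below Nyquist (%.4f Hz)",
                     cutoff_hz, 1 / (2 * tr)), class = "neuroar_invalid_config")
  if (amplitude == 0) return(matrix(0, T_len, P))
  freqs <- (seq_len(T_len) - 1) / (T_len * tr)
  freqs <- pmin(freqs, 1 / tr - freqs) # fold to [0, Nyquist]
  keep <- freqs <= cutoff_hz
  check_that(sum(keep & freqs > 0) >= 1,
             "cutoff_hz leaves no nonzero basis frequency; lengthen the run",
             class = "neuroar_invalid_config")
  noise <- with_seed(seed, matrix(stats::rnorm(T_len * P), T_len, P))
  out <- apply(noise, 2, function(x) {
    xf <- stats::fft(x)
    xf[!keep] <- 0
    Re(stats::fft(xf, inverse = TRUE)) / T_len
  })
  out <- apply(out, 2, function(x) {
    s <- pop_sd(x)
    if (s < 1e-12) stop(rlang::error_cnd(class = "neuroar_invalid_config",
                                         message = "degenerate shared component"))
    (x - mean(x)) / s * amplitude
  })
  out
}

#' Simulate one run of a stable VAR with an additive shared component
#'
#' The intrinsic state follows `V_t = sum_j A_j V_{t-j} + eps_t` with i.i.d.
#' Gaussian innovations from a zero initial state; `burn_in` initial samples
#' are discarded and the returned signal is `X_t = V_t + shared_t`. Keeping
#' the shared (stimulus-evoked) component additive on the output — outside
#' the recursion — makes it exactly removable by subtraction, mirroring how
#' an evoked response is conceived: a common signal superimposed on
#' subject-specific intrinsic dynamics.
#'
#' @param couplings `(order, P, P)` coefficient stack (or `P x P` matrix).
#' @param shared `T_len x P` matrix, or `NULL` for no shared component.
#' @param noise_sd innovation standard deviation.
#' @param T_len retained run length.
#' @param burn_in discarded initial samples (>= VAR order).
#' @param seed integer seed.
#' @param subject,run,condition,tr labels and TR for the returned series.
#' @return a [parcel_ts()].
#' @export
simulate_run <- function(couplings, shared = NULL, noise_sd = 1, T_len = 480,
                         burn_in = 200, seed = 1,
                         subject = "sub-01", run = "run-01",
                         condition = "task", tr = 1.49) {
  couplings <- as_coupling_stack(couplings)
  p <- dim(couplings)[1]; P <- dim(couplings)[2]
  check_that(burn_in >= p, "burn_in must be >= coupling order")
  if (!is.null(shared)) {
    shared <- as.matrix(shared)
    check_that(all(dim(shared) == c(T_len, P)), "shared must be T_len x P")
  }
  total <- burn_in + T_len
  eps <- with_seed(seed, matrix(stats::rnorm(total * P, sd = noise_sd), total, P))
  A <- lapply(seq_len(p), function(j) couplings[j, , ])
  X <- matrix(0, total, P)
  for (t in seq_len(total)) {
    x <- eps[t, ]
    for (j in seq_len(p)) if (t - j >= 1) x <- x + A[[j]] %*% X[t - j, ]
    if (any(!is.finite(x)))
      stop(rlang::error_cnd(class = "neuroar_explosion",
                            message = sprintf("non-finite sample at time index %d (unstable coupling?)", t)))
    X[t, ] <- x
  }
  out <- X[burn_in + seq_len(T_len), , drop = FALSE]
  if (!is.null(shared)) out <- out + shared
  parcel_ts(out,
            subject = subject, run = run, condition = condition, tr = tr)
}

#' Draw synthetic parcel centroid coordinates in the unit cube
#'
#' @param P number of parcels (>= 2).
#' @param seed integer seed.
#' @return `P x 3` matrix of pairwise-distinct coordinates.
#' @export
parcel_coordinates <- function(P, seed = 1) {
  check_that(P >= 2, "P must be >= 2")
  with_seed(seed, {
    coords <- matrix(stats::runif(P * 3), P, 3)
    while (anyDuplicated(coords)) coords <- matrix(stats::runif(P * 3), P, 3)
    coords
  })
}

#' Generate a full synthetic cohort with ground truth
#'
#' Produces one run per (subject, condition, run index). Within a (condition,
#' run) cell the shared evoked component is identical across subjects;
#' rest-like conditions carry none. Each subject keeps fixed VAR couplings
#' across all runs, mixing a common base with a subject-specific perturbation
#' according to `subject_divergence`. The full cohort is a pure function of
#' the config (including its seed).
#'
#' @param config a [cohort_config()].
#' @return list with `runs` (list of [parcel_ts()]) and `truth` (list:
#'   per-subject `couplings`, common `support_graph`, `shared_responses` keyed
#'   `"condition/run"`, `parcel_coords`), plus the `config`.
#' @export
generate_cohort <- function(config) {
  check_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  P <- config$n_parcels; T_len <- config$run_length; seed <- config$seed

  base <- make_coupling(P, config$coupling_density, config$coupling_order,
                        config$spectral_radius, seed = substream_seed(seed, "base"))
  subjects <- sprintf("sub-%02d", seq_len(config$n_subjects))
  couplings <- lapply(seq_along(subjects), function(i) {
    if (config$subject_divergence == 0) base$couplings
    else make_coupling(P, config$coupling_density, config$coupling_order,
                       config$spectral_radius, base = base$couplings,
                       divergence = config$subject_divergence,
                       seed = substream_seed(seed, "subject", i))$couplings
  })
  names(couplings) <- subjects

  shared_responses <- list()
  runs <- list()
  for (cond in names(config$n_runs_per_condition)) {
    n_runs <- config$n_runs_per_condition[[cond]]
    amp <- if (cond %in% config$rest_conditions) 0 else config$shared_amplitude
    for (r in seq_len(n_runs)) {
      run_lab <- sprintf("run-%02d", r)
      sh <- make_shared_response(T_len, P, amp, config$shared_cutoff_hz, config$tr,
                                 seed = substream_seed(seed, "shared", cond, r))
      shared_responses[[paste(cond, run_lab, sep = "/")]] <- sh
      for (i in seq_along(subjects)) {
        runs[[length(runs) + 1]] <- simulate_run(
          couplings[[i]], shared = sh, noise_sd = config$noise_sd,
          T_len = T_len, burn_in = config$burn_in,
          seed = substream_seed(seed, "run", subjects[i], cond, r),
          subject = subjects[i], run = run_lab, condition = cond, tr = config$tr)
      }
    }
  }

  truth <- list(couplings = couplings, support_graph = base$support,
                shared_responses = shared_responses,
                parcel_coords = parcel_coordinates(P, substream_seed(seed, "coords")))
  list(runs = runs, truth = truth, config = config)
}
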