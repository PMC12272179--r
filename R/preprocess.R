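#' Z-score each parcel column of a run
#'
#' Per-run normalization to zero mean and unit *population* standard
#' deviation (the convention is fixed so the pipeline is bit-reproducible).
#'
#' @param series a [parcel_ts()] with at least 2 time points.
#' @return the normalized [parcel_ts()].
#' @export
zscore_per_run <- function(series) {
  check_that(inherits(series, "parcel_ts"), "series must be a parcel_ts")
  X <- series$data
  check_that(nrow(X) >= 2, "need at least 2 time points")
  sds <- apply(X, 2, pop_sd)
  if (any(sds < 1e-12)) {
    bad <- colnames(X)[sds < 1e-12]
    stop(rlang::error_cnd(class = "neuroar_degenerate_input",
                          message = sprintf("constant parcel column(s): %s",
                                            paste(bad, collapse = ", "))))
  }
  series$data <- scale(X, center = TRUE, scale = FALSE)[, , drop = FALSE]
  series$data <- sweep(series$data, 2, sds, "/")
  attr(series$data, "scaled:center") <- NULL
  series
}

#' Discrete-cosine high-pass filter
#'
#' Removes, per parcel, the least-squares projection onto the constant term
#' and all discrete cosine regressors with frequency below `cutoff_hz`
#' (DCT-II basis, frequency of regressor `n` being `n / (2 T tr)`), returning
#' the residual. This is the standard drift-removal step for BOLD
#' time-series.
#'
#' @param series a [parcel_ts()].
#' @param cutoff_hz high-pass cutoff in Hz (default 0.01); must be below
#'   Nyquist.
#' @return the filtered [parcel_ts()].
#' @export
dct_highpass <- function(series, cutoff_hz = 0.01) {
  check_that(inherits(series, "parcel_ts"), "series must be a parcel_ts")
  T_len <- nrow(series$data); tr <- series$tr
  check_that(cutoff_hz < 1 / (2 * tr), "cutoff_hz must be below Nyquist")
  n_max <- ceiling(2 * T_len * tr * cutoff_hz - 1e-9) - 1 # largest n with n/(2 T tr) < cutoff
  if (n_max < 1) {
    warning("run too short to form any DCT regressor below cutoff; mean-centering only")
    series$data <- scale(series$data, center = TRUE, scale = FALSE)[, , drop = FALSE]
    attr(series$data, "scaled:center") <- NULL
    return(series)
  }
  t_idx <- seq_len(T_len) - 0.5
  basis <- cbind(1, sapply(seq_len(n_max), function(n) cos(pi * n * t_idx / T_len)))
  fit <- qr(basis)
  series$data <- series$data - basis %*% qr.coef(fit, series$data)
  series
}

#' Split runs into train / validation / test sets
#'
#' The first `ceil(train_fraction * n)` runs (in acquisition order) form the
#' training set; the remaining runs alternate between validation (even
#' 0-based positions within the remainder) and test (odd positions),
#' mirroring an even/odd episode split.
#'
#' @param runs character vector of run labels in acquisition order (>= 3).
#' @param train_fraction fraction of runs used for training.
#' @return list of class `run_split` with `train`, `val`, `test` label sets.
#' @export
split_runs <- function(runs, train_fraction) {
  check_that(length(runs) >= 3, "need at least 3 runs to split",
             class = "neuroar_invalid_split")
  n_train <- ceiling(train_fraction * length(runs))
  rest <- runs[seq_along(runs) > n_train]
  check_that(length(rest) >= 2, "train_fraction leaves no validation/test runs",
             class = "neuroar_invalid_split")
  pos <- seq_along(rest) - 1
  structure(list(train = runs[seq_len(n_train)],
                 val = rest[pos %% 2 == 0],
                 test = rest[pos %% 2 == 1]),
            class = "run_split")
}

#' Extract supervised windows from runs
#'
#' Builds all (k-step input window, target at lag `l`) pairs from each run;
#' windows never span run boundaries. Sample `i`'s target is the time point
#' `l` steps after the last point of its window, so each run of length `T`
#' contributes `T - k - l + 1` samples.
#'
#' @param series_list list of [parcel_ts()] runs.
#' @param k input window length (>= 1).
#' @param l prediction lag in TR units (>= 1).
#' @return list of class `window_set`: `inputs` (`N x k x P` array),
#'   `targets` (`N x P`), `k`, `l`, and `provenance` (tibble of subject/run
#'   per sample).
#' @export
make_windows <- function(series_list, k, l = 1) {
  check_that(k >= 1 && l >= 1, "k and l must be >= 1")
  if (inherits(series_list, "parcel_ts")) series_list <- list(series_list)
  inputs <- list(); targets <- list(); prov <- list()
  for (ts in series_list) {
    T_len <- nrow(ts$data)
    if (T_len < k + l) {
      warning(sprintf("run %s/%s too short (T=%d < k+l=%d); skipped",
                      ts$subject, ts$run, T_len, k + l))
      next
    }
    n <- T_len - k - l + 1
    win <- array(0, c(n, k, ncol(ts$data)))
    for (j in seq_len(k)) win[, j, ] <- ts$data[(j - 1) + seq_len(n), , drop = FALSE]
    inputs[[length(inputs) + 1]] <- win
    targets[[length(targets) + 1]] <- ts$data[(k + l - 1) + seq_len(n), , drop = FALSE]
    prov[[length(prov) + 1]] <- tibble::tibble(subject = ts$subject, run = ts$run,
                                               condition = ts$condition,
                                               t_target = (k + l - 1) + seq_len(n))
  }
  if (length(inputs) == 0)
    stop(rlang::error_cnd(class = "neuroar_empty_windowset",
                          message = "no run long enough for the requested k and l"))
  P <- dim(inputs[[1]])[3]
  N <- sum(vapply(inputs, function(x) dim(x)[1], integer(1)))
  all_in <- array(0, c(N, k, P))
  ofs <- 0
  for (w in inputs) {
    all_in[ofs + seq_len(dim(w)[1]), , ] <- w
    ofs <- ofs + dim(w)[1]
  }
  structure(list(inputs = all_in, targets = do.call(rbind, targets),
                 k = as.integer(k), l = as.integer(l),
                 provenance = do.call(rbind, prov)),
            class = "window_set")
}

#' Leave-one-subject-out shared-response estimation
#'
#' For every (condition, run) cell, averages the (normalized) series of all
#' subjects except `held_out_subject`; the average is the estimate of the
#' stimulus-evoked signal shared across subjects.
#'
#' @param runs list of [parcel_ts()] covering multiple subjects.
#' @param held_out_subject subject label to exclude.
#' @return named list (key `"condition/run"`) of `T x P` matrices.
#' @export
estimate_shared_response <- function(runs, held_out_subject) {
  others <- Filter(function(r) r$subject != held_out_subject, runs)
  keys <- unique(vapply(others, run_key, character(1)))
  out <- list()
  for (key in keys) {
    grp <- Filter(function(r) run_key(r) == key, others)
    check_that(length(grp) >= 2,
               sprintf("need >= 2 other subjects for %s (got %d)", key, length(grp)),
               class = "neuroar_insufficient_subjects")
    out[[key]] <- Reduce(`+`, lapply(grp, function(r) r$data)) / length(grp)
  }
  out
}

#' Regress the shared response out of a run
#'
#' Per parcel, ordinary least squares of the subject's column on an intercept
#' plus the matching shared-response column; the residuals estimate the
#' subject's intrinsic activity.
#'
#' @param series a [parcel_ts()].
#' @param shared `T x P` matrix matching `series`.
#' @return the residual [parcel_ts()].
#' @export
regress_out_shared <- function(series, shared) {
  X <- series$data
  shared <- as.matrix(shared)
  check_that(all(dim(X) == dim(shared)), "series and shared shapes must match")
  res <- X
  for (p in seq_len(ncol(X))) {
    s <- shared[, p]
    if (pop_sd(s) < 1e-12) {
      warning(sprintf("constant shared column for parcel %d; removing intercept only", p))
      res[, p] <- X[, p] - mean(X[, p])
    } else {
      fit <- stats::lm.fit(cbind(1, s), X[, p])
      res[, p] <- fit$residuals
    }
  }
  series$data <- res
  series
}
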