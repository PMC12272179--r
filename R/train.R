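# ---- parameter-tree helpers (params are nested lists of numeric arrays) ----

params_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a))
      out[[i]] <- if (is.null(a[[i]])) NULL else params_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

params_zero <- function(a) {
  if (is.list(a)) lapply(a, function(x) if (is.null(x)) NULL else params_zero(x))
  else a * 0
}

params_finite <- function(a) {
  if (is.list(a)) all(vapply(a, function(x) is.null(x) || params_finite(x), logical(1)))
  else all(is.finite(a))
}

# ---- gradients ----

# dPred: N x P gradient of the loss w.r.t. predictions
model_backward <- function(model, windows, cache, dPred) {
  switch(model$config$family,
         linear_uni = backward_linear_uni(model, windows, dPred),
         linear_multi = backward_linear_multi(model, cache, dPred),
         mlp_uni = backward_mlp_uni(model, cache, dPred),
         mlp_multi = backward_mlp_multi(model, cache, dPred),
         chebnet = backward_chebnet(model, cache, dPred))
}

backward_linear_uni <- function(model, windows, dPred) {
  N <- nrow(dPred); P <- ncol(dPred); k <- model$config$k
  dW <- matrix(0, P, k)
  for (t in seq_len(k))
    dW[, t] <- colSums(dPred * matrix(windows[, t, ], N, P))
  list(W = dW, b = if (is.null(model$params$b)) NULL else colSums(dPred))
}

backward_linear_multi <- function(model, cache, dPred) {
  list(W = t(dPred) %*% cache$X,
       b = if (is.null(model$params$b)) NULL else colSums(dPred))
}

backward_mlp_multi <- function(model, cache, dPred) {
  L <- length(model$params)
  grads <- vector("list", L)
  delta <- dPred
  for (l in L:1) {
    if (model$config$nonlinear && l < L) delta <- delta * cache$masks[[l]]
    W <- model$params[[l]]$W
    grads[[l]] <- list(W = t(delta) %*% cache$acts[[l]],
                       b = if (is.null(model$params[[l]]$b)) NULL else colSums(delta))
    if (l > 1) delta <- delta %*% W
  }
  grads
}

backward_mlp_uni <- function(model, cache, dPred) {
  L <- length(model$params)
  N <- nrow(dPred); P <- ncol(dPred)
  grads <- vector("list", L)
  delta <- array(dPred, c(N, 1, P))
  for (l in L:1) {
    if (model$config$nonlinear && l < L) delta <- delta * cache$masks[[l]]
    W <- model$params[[l]]$W # P x C_out x C_in
    C_out <- dim(W)[2]; C_in <- dim(W)[3]
    dW <- array(0, dim(W))
    db <- if (is.null(model$params[[l]]$b)) NULL else matrix(0, P, C_out)
    new_delta <- array(0, c(N, C_in, P))
    for (p in seq_len(P)) {
      D <- matrix(delta[, , p], N, C_out)
      A <- matrix(cache$acts[[l]][, , p], N, C_in)
      dW[p, , ] <- t(D) %*% A
      if (!is.null(db)) db[p, ] <- colSums(D)
      if (l > 1) new_delta[, , p] <- D %*% matrix(W[p, , ], C_out, C_in)
    }
    grads[[l]] <- list(W = dW, b = db)
    if (l > 1) delta <- new_delta
  }
  grads
}

backward_chebnet <- function(model, cache, dPred) {
  S <- model$spectral_op$scaled_laplacian
  K <- model$config$cheb_order
  N <- nrow(dPred); P <- ncol(dPred)
  L <- length(model$params)
  grads <- vector("list", L)
  dY <- matrix(as.vector(t(dPred)), N * P, 1) # rows (n, p), p fastest
  for (l in L:1) {
    if (model$config$nonlinear && l < L) dY <- dY * cache$masks[[l]]
    theta <- model$params[[l]]$theta
    C_in <- dim(theta)[2]; C_out <- dim(theta)[3]
    G <- cache$G[[l]]
    dTheta2 <- t(G) %*% dY # (K C_in) x C_out, rows c fastest within k
    dTheta <- aperm(array(dTheta2, c(C_in, K, C_out)), c(2, 1, 3))
    grads[[l]] <- list(theta = dTheta,
                       b = if (is.null(model$params[[l]]$b)) NULL else colSums(dY))
    if (l > 1) {
      Theta2 <- matrix(aperm(theta, c(2, 1, 3)), K * C_in, C_out)
      dG <- dY %*% t(Theta2) # (N P) x (K C_in)
      blocks <- vector("list", K)
      for (kk in seq_len(K)) {
        blk <- dG[, (kk - 1) * C_in + seq_len(C_in), drop = FALSE]
        dim(blk) <- c(P, N, C_in)
        blocks[[kk]] <- matrix(aperm(blk, c(1, 3, 2)), P, C_in * N)
      }
      dM <- cheb_recurrence_adjoint(S, blocks) # P x (C_in N), c fastest
      dim(dM) <- c(P, C_in, N)
      dY <- matrix(aperm(dM, c(1, 3, 2)), N * P, C_in) # rows p fastest within n
    }
  }
  grads
}

# ---- Adam ----

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  state$m <- params_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- params_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  upd <- params_map2(state$m, state$v,
                     function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  state$params <- params_map2(params, upd, `-`)
  state
}

mse_loss <- function(pred, target) mean((pred - target)^2)

#' Train a model by Adam on mean squared error
#'
#' Minimizes the mean squared prediction error with the Adam optimizer
#' (conventional moment parameters, no weight decay / L2 penalty). Training
#' is deterministic given the seed (weight initialization comes from the
#' model config seed; minibatch shuffling from `seed`). When a validation
#' window set is supplied, the returned parameters are those of the epoch
#' with the lowest validation loss (best-epoch checkpointing).
#'
#' @param model an `ar_model` from [build_model()].
#' @param train a `window_set` of training pairs (non-empty).
#' @param val optional `window_set` for validation.
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer seed for minibatch shuffling.
#' @return the trained `ar_model`, with `training_history` (tibble of
#'   per-epoch train/val loss).
#' @export
fit_model <- function(model, train, val = NULL, epochs = 40, batch_size = 128,
                      learning_rate = 0.01, seed = 1) {
  check_that(inherits(train, "window_set") && dim(train$inputs)[1] >= 1,
             "train window set must be non-empty")
  N <- dim(train$inputs)[1]
  state <- list(params = model$params, m = params_zero(model$params),
                v = params_zero(model$params), t = 0)
  history <- vector("list", epochs)
  best_loss <- Inf; best_params <- model$params
  for (epoch in seq_len(epochs)) {
    ord <- with_seed(substream_seed(seed, "shuffle", epoch), sample.int(N))
    tot <- 0
    for (start in seq(1, N, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, N)]
      xb <- train$inputs[idx, , , drop = FALSE]
      yb <- train$targets[idx, , drop = FALSE]
      model$params <- state$params
      fw <- forward_with_cache(model, xb)
      loss <- mse_loss(fw$pred, yb)
      if (!is.finite(loss))
        stop(rlang::error_cnd(class = "neuroar_divergence",
                              message = sprintf("non-finite loss at epoch %d (learning_rate=%g)",
                                                epoch, learning_rate)))
      dPred <- 2 * (fw$pred - yb) / length(yb)
      grads <- model_backward(model, xb, fw$cache, dPred)
      state <- adam_step(state$params, grads, state, learning_rate)
      tot <- tot + loss * length(idx)
    }
    model$params <- state$params
    train_loss <- tot / N
    val_loss <- if (is.null(val)) NA_real_ else
      mse_loss(model_forward(model, val$inputs), val$targets)
    sel_loss <- if (is.null(val)) train_loss else val_loss
    if (is.finite(sel_loss) && sel_loss < best_loss) {
      best_loss <- sel_loss
      best_params <- state$params
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                       val_loss = val_loss)
  }
  model$params <- best_params
  model$training_history <- do.call(rbind, history)
  model
}

#' Iterated multi-lag prediction over a full run
#'
#' Applies a lag-1 model recursively: the lag-1 prediction for each target
#' time uses the true history; the lag-`j` prediction slides the window
#' forward, substituting the `j - 1` previously predicted values for the
#' time points where no true value is available yet. Predictions at all lags
#' are aligned to the target time index (row of the returned matrices).
#'
#' @param model a trained `ar_model` (lag-1).
#' @param series a [parcel_ts()] with at least `k + l_max` time points.
#' @param l_max maximum lag (TR units).
#' @return list of class `iterated_prediction`: `pred` (list over lags of
#'   `T x P` matrices, rows before `k + lag` are `NA`), `k`, `lags`.
#' @export
predict_iterated <- function(model, series, l_max = 6) {
  X <- series$data
  T_len <- nrow(X); P <- ncol(X); k <- model$config$k
  check_that(T_len >= k + l_max,
             sprintf("series length %d < k + l_max = %d", T_len, k + l_max),
             class = "neuroar_contract")
  preds <- lapply(seq_len(l_max), function(j) matrix(NA_real_, T_len, P))
  for (j in seq_len(l_max)) {
    s <- (k + j):T_len # target times
    win <- array(0, c(length(s), k, P))
    for (tw in seq_len(k)) {
      u <- s - k + tw - 1 # absolute time of window position tw
      lag_of_entry <- tw - 1 - k + j # >= 1 means a predicted value
      win[, tw, ] <- if (lag_of_entry >= 1) preds[[lag_of_entry]][u, , drop = FALSE]
        else X[u, , drop = FALSE]
    }
    preds[[j]][s, ] <- model_forward(model, win)
  }
  structure(list(pred = preds, k = k, lags = seq_len(l_max)), class = "iterated_prediction")
}

#' Hyper-parameter grid search by mean validation R-squared
#'
#' Trains every candidate configuration independently per subject and scores
#' it by the mean validation R-squared over subjects, parcels, and the listed
#' lags (validation predictions at lag > 1 are obtained by iterated
#' single-step prediction). Ties return the first configuration in grid
#' order.
#'
#' @param grid list of [model_config()] candidates (non-empty).
#' @param subjects_data named list per subject, each with `train_windows` (a
#'   `window_set` at lag 1), `val_runs` (list of [parcel_ts()]), and
#'   optionally `spectral_op` (required for chebnet configs).
#' @param lags lags entering the score (default 1).
#' @param epochs,batch_size,learning_rate,seed passed to [fit_model()].
#' @return list with `best` (the winning config), `scores` (tibble per
#'   config x subject), and `models` (fitted models for the best config).
#' @export
grid_search <- function(grid, subjects_data, lags = 1, epochs = 40,
                        batch_size = 128, learning_rate = 0.01, seed = 1) {
  check_that(length(grid) >= 1, "grid must be non-empty")
  rows <- list()
  fits <- vector("list", length(grid))
  any_ok <- FALSE
  for (g in seq_along(grid)) {
    cfg <- grid[[g]]
    fits[[g]] <- list()
    for (subj in names(subjects_data)) {
      sd <- subjects_data[[subj]]
      P <- dim(sd$train_windows$inputs)[3]
      score <- tryCatch({
        mdl <- build_model(cfg, P, spectral_op = sd$spectral_op)
        mdl <- fit_model(mdl, sd$train_windows, epochs = epochs,
                         batch_size = batch_size, learning_rate = learning_rate,
                         seed = substream_seed(seed, "gs", subj))
        fits[[g]][[subj]] <- mdl
        ev <- evaluate_model(mdl, sd$val_runs, lags = lags)
        mean(ev$r2_mean)
      }, neuroar_divergence = function(e) NA_real_)
      rows[[length(rows) + 1]] <- tibble::tibble(config = g, family = cfg$family,
                                                 k = cfg$k, subject = subj,
                                                 score = score)
      if (is.finite(score)) any_ok <- TRUE
    }
  }
  check_that(any_ok, "all configurations diverged",
             class = "neuroar_no_viable_config")
  scores <- do.call(rbind, rows)
  per_cfg <- vapply(seq_along(grid), function(g)
    mean(scores$score[scores$config == g]), numeric(1))
  per_cfg[is.na(per_cfg)] <- -Inf
  best <- which.max(per_cfg) # ties -> first in grid order
  list(best = grid[[best]], best_index = best, scores = scores,
       models = fits[[best]])
}

#' Train one independent model per prediction lag (direct multi-lag mode)
#'
#' The alternative to iterated single-step prediction: for each lag `l` a
#' separate model is trained on windows whose targets sit `l` steps ahead.
#' With a single lag of 1 this reduces exactly to [fit_model()].
#'
#' @param config a [model_config()].
#' @param train_by_lag named/indexed list of `window_set`s, one per lag.
#' @param P number of parcels.
#' @param spectral_op optional `spectral_operator` (chebnet).
#' @param epochs,batch_size,learning_rate,seed passed to [fit_model()]; each
#'   lag uses an independent seed substream.
#' @return list of trained `ar_model`s, one per lag.
#' @export
fit_direct_multilag <- function(config, train_by_lag, P, spectral_op = NULL,
                                epochs = 40, batch_size = 128,
                                learning_rate = 0.01, seed = 1) {
  lapply(seq_along(train_by_lag), function(i) {
    ws <- train_by_lag[[i]]
    mdl <- build_model(config, P, spectral_op = spectral_op)
    fit_model(mdl, ws, epochs = epochs, batch_size = batch_size,
              learning_rate = learning_rate,
              seed = substream_seed(seed, "lag", ws$l))
  })
}
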