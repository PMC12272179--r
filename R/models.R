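#' Model configuration for the auto-regressive model zoo
#'
#' Families:
#' * `linear_uni` — per-parcel linear AR: each parcel predicted from its own
#'   `k` past values (independent weights per parcel).
#' * `linear_multi` — classical VAR: every parcel predicted from the full
#'   `k x P` window.
#' * `mlp_uni` / `mlp_multi` — the same input wiring with hidden layers and
#'   ReLU activations (per-parcel independent MLPs for the univariate case).
#' * `chebnet` — graph convolutional network; the `k` window time-steps enter
#'   as `k` input channels per node and each layer applies Chebyshev
#'   polynomial filters of the scaled graph Laplacian.
#'
#' @param family one of `"linear_uni"`, `"linear_multi"`, `"mlp_uni"`,
#'   `"mlp_multi"`, `"chebnet"`.
#' @param k input window length in time points (>= 1).
#' @param hidden_sizes integer vector of hidden layer widths (MLP) or hidden
#'   channel counts (Chebnet); must be empty for linear families.
#' @param cheb_order Chebyshev polynomial order `K` (chebnet only, >= 1).
#' @param nonlinear apply ReLU between layers (ignored by linear families).
#' @param bias include bias terms.
#' @param seed integer seed for weight initialization.
#' @return a validated list of class `model_config`.
#' @export
model_config <- function(family, k = 1, hidden_sizes = integer(),
                         cheb_order = 3, nonlinear = TRUE, bias = TRUE,
                         seed = 1) {
  family <- match.arg(family, c("linear_uni", "linear_multi", "mlp_uni",
                                "mlp_multi", "chebnet"))
  check_that(k >= 1, "k must be >= 1")
  if (family %in% c("linear_uni", "linear_multi")) {
    check_that(length(hidden_sizes) == 0, "hidden_sizes must be empty for linear families")
    nonlinear <- FALSE
  }
  if (family == "chebnet") check_that(cheb_order >= 1, "cheb_order must be >= 1")
  structure(list(family = family, k = as.integer(k),
                 hidden_sizes = as.integer(hidden_sizes),
                 cheb_order = as.integer(cheb_order),
                 n_layers = length(hidden_sizes) + 1L,
                 nonlinear = isTRUE(nonlinear), bias = isTRUE(bias),
                 seed = as.integer(seed)),
            class = "model_config")
}

# seeded uniform fan-in initialization
init_mat <- function(nr, nc, fan_in) {
  b <- 1 / sqrt(max(1, fan_in))
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

#' Build an untrained model for `P` parcels
#'
#' Initializes all parameters deterministically from the config seed
#' (uniform fan-in scaling). Chebnet models additionally require a
#' [scaled_laplacian()] spectral operator.
#'
#' @param config a [model_config()].
#' @param P number of parcels.
#' @param spectral_op a `spectral_operator` (chebnet only).
#' @return an object of class `ar_model`.
#' @export
build_model <- function(config, P, spectral_op = NULL) {
  check_that(inherits(config, "model_config"), "config must be a model_config")
  if (config$family == "chebnet")
    check_that(inherits(spectral_op, "spectral_operator"),
               "chebnet requires a spectral_op", class = "neuroar_contract")
  k <- config$k; h <- config$hidden_sizes; K <- config$cheb_order
  params <- with_seed(config$seed, switch(
    config$family,
    linear_uni = list(W = init_mat(P, k, k),
                      b = if (config$bias) stats::runif(P, -1, 1) / sqrt(k) else NULL),
    linear_multi = list(W = init_mat(P, k * P, k * P),
                        b = if (config$bias) stats::runif(P, -1, 1) / sqrt(k * P) else NULL),
    mlp_uni = {
      sizes <- c(k, h, 1L)
      lapply(seq_len(length(sizes) - 1), function(l) {
        W <- array(stats::runif(P * sizes[l + 1] * sizes[l], -1, 1) / sqrt(sizes[l]),
                   c(P, sizes[l + 1], sizes[l]))
        list(W = W,
             b = if (config$bias) matrix(stats::runif(P * sizes[l + 1], -1, 1) / sqrt(sizes[l]),
                                         P, sizes[l + 1]) else NULL)
      })
    },
    mlp_multi = {
      sizes <- c(k * P, h, P)
      lapply(seq_len(length(sizes) - 1), function(l) {
        list(W = init_mat(sizes[l + 1], sizes[l], sizes[l]),
             b = if (config$bias) stats::runif(sizes[l + 1], -1, 1) / sqrt(sizes[l]) else NULL)
      })
    },
    chebnet = {
      ch <- c(k, h, 1L)
      lapply(seq_len(length(ch) - 1), function(l) {
        fan_in <- K * ch[l]
        theta <- array(stats::runif(K * ch[l] * ch[l + 1], -1, 1) / sqrt(fan_in),
                       c(K, ch[l], ch[l + 1]))
        list(theta = theta,
             b = if (config$bias) stats::runif(ch[l + 1], -1, 1) / sqrt(fan_in) else NULL)
      })
    }))
  structure(list(config = config, P = as.integer(P), params = params,
                 spectral_op = spectral_op, training_history = NULL),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> family=%s k=%d P=%d parameters=%d%s\n",
              x$config$family, x$config$k, x$P, count_parameters(x),
              if (is.null(x$training_history)) " (untrained)" else ""))
  invisible(x)
}

#' Count trainable parameters of a model
#'
#' Total number of trainable scalars, biases included. For the linear
#' families this is `P (k + 1)` (univariate) and `P (k P + 1)` (multivariate)
#' when biases are on.
#'
#' @param model an `ar_model`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) n <<- n + length(x)
    invisible(NULL)
  }
  walk(model$params)
  n
}

#' Apply the Chebyshev polynomial basis of the scaled Laplacian to a signal
#'
#' Computes `[T_0(L~) x, ..., T_{K-1}(L~) x]` by the three-term recurrence
#' `T_0 x = x`, `T_1 x = L~ x`, `T_j x = 2 L~ T_{j-1} x - T_{j-2} x` — no
#' eigendecomposition is ever formed.
#'
#' @param spectral_op a `spectral_operator`.
#' @param x `P x C` signal matrix (nodes x channels).
#' @param K number of basis terms (>= 1).
#' @return list of `K` matrices `P x C`.
#' @export
chebyshev_basis_apply <- function(spectral_op, x, K) {
  check_that(K >= 1, "K must be >= 1")
  cheb_recurrence(spectral_op$scaled_laplacian, as.matrix(x), K)
}

# three-term Chebyshev recurrence on a batch matrix M (P x cols)
cheb_recurrence <- function(S, M, K) {
  B <- vector("list", K)
  B[[1]] <- M
  if (K >= 2) B[[2]] <- S %*% M
  if (K >= 3) for (j in 3:K) B[[j]] <- 2 * (S %*% B[[j - 1]]) - B[[j - 2]]
  B
}

# Adjoint of the recurrence (Clenshaw): given gradients G_j flowing into each
# basis term B_j = T_j(S) M, return dM = sum_j T_j(S) G_j (S symmetric).
cheb_recurrence_adjoint <- function(S, G_list) {
  K <- length(G_list)
  if (K == 1) return(G_list[[1]])
  b1 <- G_list[[K]]; b2 <- NULL
  if (K >= 3) for (j in (K - 1):2) {
    b_new <- G_list[[j]] + 2 * (S %*% b1) - (if (is.null(b2)) 0 else b2)
    b2 <- b1; b1 <- b_new
  }
  out <- G_list[[1]] + S %*% b1
  if (!is.null(b2)) out <- out - b2
  out
}

# window array (N, k, P) -> flat design matrix N x (k P); column index
# (p - 1) * k + t (time-major within parcel) — the fixed vectorization
# convention for multivariate families
flatten_windows <- function(windows) {
  d <- dim(windows)
  matrix(windows, d[1], d[2] * d[3])
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

check_window_shape <- function(model, windows) {
  d <- dim(windows)
  check_that(length(d) == 3 && d[2] == model$config$k && d[3] == model$P,
             sprintf("window shape (%s) does not match model (k=%d, P=%d)",
                     paste(d, collapse = "x"), model$config$k, model$P),
             class = "neuroar_contract")
  d
}

#' Forward pass of a model on a window batch
#'
#' Maps an `N x k x P` array of input windows to `N x P` one-step
#' predictions, per the model family's wiring (see [model_config()]).
#'
#' @param model an `ar_model`.
#' @param windows `N x k x P` numeric array.
#' @return `N x P` prediction matrix.
#' @export
model_forward <- function(model, windows) {
  forward_with_cache(model, windows, keep_cache = FALSE)$pred
}

forward_with_cache <- function(model, windows, keep_cache = TRUE) {
  d <- check_window_shape(model, windows)
  switch(model$config$family,
         linear_uni = forward_linear_uni(model, windows, d),
         linear_multi = forward_linear_multi(model, windows, keep_cache),
         mlp_uni = forward_mlp_uni(model, windows, d, keep_cache),
         mlp_multi = forward_mlp_multi(model, windows, keep_cache),
         chebnet = forward_chebnet(model, windows, d, keep_cache))
}

forward_linear_uni <- function(model, windows, d) {
  N <- d[1]; k <- d[2]; P <- d[3]
  out <- matrix(0, N, P)
  for (t in seq_len(k))
    out <- out + matrix(windows[, t, ], N, P) *
      matrix(model$params$W[, t], N, P, byrow = TRUE)
  if (!is.null(model$params$b)) out <- sweep(out, 2, model$params$b, "+")
  list(pred = out, cache = NULL)
}

forward_linear_multi <- function(model, windows, keep_cache) {
  X <- flatten_windows(windows)
  out <- X %*% t(model$params$W)
  if (!is.null(model$params$b)) out <- sweep(out, 2, model$params$b, "+")
  list(pred = out, cache = if (keep_cache) list(X = X) else NULL)
}

forward_mlp_multi <- function(model, windows, keep_cache) {
  acts <- list(flatten_windows(windows))
  masks <- list()
  L <- length(model$params)
  for (l in seq_len(L)) {
    W <- model$params[[l]]$W; b <- model$params[[l]]$b
    z <- acts[[l]] %*% t(W)
    if (!is.null(b)) z <- sweep(z, 2, b, "+")
    if (model$config$nonlinear && l < L) {
      masks[[l]] <- z > 0
      z <- relu(z)
    }
    acts[[l + 1]] <- z
  }
  list(pred = acts[[L + 1]],
       cache = if (keep_cache) list(acts = acts, masks = masks) else NULL)
}

# Per-parcel MLPs with independent parameters; activations carried as
# N x C x P arrays.
forward_mlp_uni <- function(model, windows, d, keep_cache) {
  N <- d[1]; P <- d[3]
  acts <- list(windows) # N x k x P
  masks <- list()
  L <- length(model$params)
  for (l in seq_len(L)) {
    W <- model$params[[l]]$W # P x C_out x C_in
    b <- model$params[[l]]$b # P x C_out or NULL
    C_out <- dim(W)[2]; C_in <- dim(W)[3]
    z <- array(0, c(N, C_out, P))
    for (p in seq_len(P)) {
      A <- matrix(acts[[l]][, , p], N, C_in)
      zp <- A %*% t(matrix(W[p, , ], C_out, C_in))
      if (!is.null(b)) zp <- sweep(zp, 2, b[p, ], "+")
      z[, , p] <- zp
    }
    if (model$config$nonlinear && l < L) {
      masks[[l]] <- z > 0
      z <- relu(z)
    }
    acts[[l + 1]] <- z
  }
  list(pred = matrix(acts[[L + 1]][, 1, ], N, P),
       cache = if (keep_cache) list(acts = acts, masks = masks) else NULL)
}

# Chebnet layers. Node-channel activations are carried as P x (C * N)
# matrices with column index (n - 1) * C + c (channel fastest), so every
# Chebyshev basis term is one P x P matmul over the whole batch. For the
# theta contraction the basis stack is reshaped to G: rows (n, p) with p
# fastest, columns (k, c) with c fastest, giving Y = G %*% Theta.
forward_chebnet <- function(model, windows, d, keep_cache) {
  check_that(inherits(model$spectral_op, "spectral_operator"),
             "missing spectral_op", class = "neuroar_contract")
  S <- model$spectral_op$scaled_laplacian
  K <- model$config$cheb_order
  N <- d[1]; k <- d[2]; P <- d[3]
  M <- t(matrix(aperm(windows, c(2, 1, 3)), k * N, P)) # P x (k N), c fastest
  L <- length(model$params)
  cache <- list(G = vector("list", L), masks = vector("list", L))
  C_in <- k
  for (l in seq_len(L)) {
    theta <- model$params[[l]]$theta # K x C_in x C_out
    b <- model$params[[l]]$b
    C_out <- dim(theta)[3]
    B <- cheb_recurrence(S, M, K)
    G <- matrix(0, N * P, K * C_in)
    for (kk in seq_len(K)) {
      Bk <- B[[kk]]
      dim(Bk) <- c(P, C_in, N)
      G[, (kk - 1) * C_in + seq_len(C_in)] <- matrix(aperm(Bk, c(1, 3, 2)), N * P, C_in)
    }
    Theta2 <- matrix(aperm(theta, c(2, 1, 3)), K * C_in, C_out) # rows: c fastest within k
    Y <- G %*% Theta2 # (N P) x C_out, rows: p fastest within n
    if (!is.null(b)) Y <- sweep(Y, 2, b, "+")
    if (model$config$nonlinear && l < L) {
      cache$masks[[l]] <- Y > 0
      Y <- relu(Y)
    }
    if (keep_cache) cache$G[[l]] <- G
    dim(Y) <- c(P, N, C_out)
    M <- matrix(aperm(Y, c(1, 3, 2)), P, C_out * N)
    C_in <- C_out
  }
  pred <- t(matrix(M, P, N)) # final C_out = 1
  list(pred = pred, cache = if (keep_cache) cache else NULL)
}

#' Chebnet forward pass
#'
#' The `k` window time-steps enter as `k` input channels per node; each layer
#' maps `C_in` to `C_out` channels through theta-weighted sums of the `K`
#' Chebyshev basis terms of the scaled Laplacian (plus bias), with ReLU
#' between layers iff `nonlinear = TRUE`; the final layer outputs one channel
#' per node — the prediction.
#'
#' @param model an `ar_model` of family `"chebnet"` (with `spectral_op`).
#' @param windows `N x k x P` array.
#' @return `N x P` prediction matrix.
#' @export
chebnet_forward <- function(model, windows) {
  check_that(model$config$family == "chebnet", "model family must be chebnet",
             class = "neuroar_contract")
  model_forward(model, windows)
}
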