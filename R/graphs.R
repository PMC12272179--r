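#' Functional connectome from training runs
#'
#' Pearson correlation between parcels, computed on the time-concatenation of
#' all supplied (normalized) training runs.
#'
#' @param train_runs list of [parcel_ts()] runs (or a single run).
#' @return `P x P` symmetric correlation matrix with unit diagonal.
#' @export
functional_connectome <- function(train_runs) {
  if (inherits(train_runs, "parcel_ts")) train_runs <- list(train_runs)
  X <- do.call(rbind, lapply(train_runs, function(r) r$data))
  check_that(nrow(X) >= 2, "need at least 2 total time points")
  sds <- apply(X, 2, pop_sd)
  if (any(sds < 1e-12))
    stop(rlang::error_cnd(class = "neuroar_degenerate_input",
                          message = "constant parcel in training data"))
  C <- stats::cor(X)
  (C + t(C)) / 2
}

new_connectome <- function(adjacency, kind) {
  P <- nrow(adjacency)
  diag(adjacency) <- 0L
  storage.mode(adjacency) <- "integer"
  structure(list(adjacency = adjacency,
                 density = sum(adjacency) / (P * (P - 1)),
                 kind = kind),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> kind=%s  P=%d  density=%.4f (%d edges)\n",
              x$kind, nrow(x$adjacency), x$density, sum(x$adjacency) / 2))
  invisible(x)
}

# off-diagonal upper-triangle pairs ordered lexicographically by (row, col)
upper_pairs <- function(P) {
  idx <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

edges_to_adjacency <- function(pairs, P) {
  A <- matrix(0L, P, P)
  A[pairs] <- 1L
  A + t(A)
}

n_edges_for_density <- function(P, density) {
  check_that(density > 0 && density <= 1, "density must lie in (0, 1]")
  max(1L, round(density * P * (P - 1) / 2))
}

#' Binarize a weight matrix by keeping its strongest pairs
#'
#' Keeps the `m = round(density * P(P-1)/2)` off-diagonal pairs with the
#' highest (signed) weight. Ties crossing the m-th rank are broken by
#' (row, col) lexicographic order of the pair (a warning is emitted), so the
#' result is deterministic.
#'
#' @param weights `P x P` symmetric numeric matrix.
#' @param density fraction of off-diagonal pairs to connect, in (0, 1].
#' @param kind label stored on the result (default `"functional"`).
#' @return a `connectome` (binary symmetric adjacency, zero diagonal).
#' @export
binarize_top_density <- function(weights, density, kind = "functional") {
  check_that(isTRUE(all.equal(weights, t(weights), tolerance = 1e-8)),
             "weights must be symmetric")
  P <- nrow(weights)
  m <- n_edges_for_density(P, density)
  pairs <- upper_pairs(P)
  w <- weights[pairs]
  ord <- order(-w) # stable: lexicographic (row, col) among ties
  if (m < length(w) && w[ord[m]] == w[ord[m + 1]])
    warning("ties cross the density threshold; broken by (row, col) order")
  new_connectome(edges_to_adjacency(pairs[ord[seq_len(m)], , drop = FALSE], P), kind)
}

#' Spatial connectome from parcel coordinates
#'
#' Connects the `m` closest parcel pairs by Euclidean distance.
#'
#' @param coords `P x 3` matrix of pairwise-distinct centroid coordinates.
#' @param density fraction of off-diagonal pairs to connect.
#' @return a `connectome` of kind `"spatial"`.
#' @export
spatial_connectome <- function(coords, density) {
  coords <- as.matrix(coords)
  check_that(anyDuplicated(coords) == 0, "duplicate coordinates",
             class = "neuroar_invalid_input")
  D <- as.matrix(stats::dist(coords))
  binarize_top_density(-D, density, kind = "spatial")
}

#' Random connectome at fixed density
#'
#' Samples exactly `m` edges uniformly without replacement among off-diagonal
#' pairs; deterministic under `seed`.
#'
#' @param P number of parcels.
#' @param density fraction of off-diagonal pairs to connect.
#' @param seed integer seed.
#' @return a `connectome` of kind `"random"`.
#' @export
random_connectome <- function(P, density, seed = 1) {
  m <- n_edges_for_density(P, density)
  pairs <- upper_pairs(P)
  sel <- with_seed(seed, sample.int(nrow(pairs), m))
  new_connectome(edges_to_adjacency(pairs[sel, , drop = FALSE], P), "random")
}

#' Connectome from a known support graph
#'
#' Wraps a ground-truth binary adjacency (e.g. the generator's coupling
#' support) as a `connectome` usable as a graph prior.
#'
#' @param adjacency `P x P` binary symmetric matrix, zero diagonal.
#' @param kind label (default `"functional"`).
#' @return a `connectome`.
#' @export
support_connectome <- function(adjacency, kind = "functional") {
  check_that(all(adjacency == t(adjacency)) && all(diag(adjacency) == 0),
             "adjacency must be symmetric with zero diagonal")
  new_connectome(adjacency, kind)
}

#' Scaled graph Laplacian for Chebyshev filtering
#'
#' Computes the symmetric normalized Laplacian `L = I - D^{-1/2} A D^{-1/2}`
#' (isolated nodes get `D^{-1/2} = 0`, leaving an identity row), its largest
#' eigenvalue `lambda_max` by dense symmetric eigendecomposition, and the
#' rescaled operator `L_tilde = (2 / lambda_max) L - I`, whose spectrum lies
#' in `[-1, 1]` — the domain of Chebyshev polynomials. An edgeless graph uses
#' the convention `lambda_max = 2` (with a warning).
#'
#' @param connectome a `connectome`.
#' @return list of class `spectral_operator` with `scaled_laplacian` and
#'   `lambda_max`.
#' @export
scaled_laplacian <- function(connectome) {
  check_that(inherits(connectome, "connectome"), "need a connectome")
  A <- connectome$adjacency
  P <- nrow(A)
  deg <- rowSums(A)
  d_inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(P) - outer(d_inv_sqrt, d_inv_sqrt) * A
  if (sum(A) == 0) {
    warning("edgeless graph; using lambda_max = 2 convention")
    lambda_max <- 2
  } else {
    lambda_max <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  }
  Lt <- (2 / lambda_max) * L - diag(P)
  structure(list(scaled_laplacian = (Lt + t(Lt)) / 2, lambda_max = lambda_max),
            class = "spectral_operator")
}
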