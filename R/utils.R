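#' Derive a deterministic sub-seed from a base seed and a stream label
#'
#' All randomness in the package flows from a single base seed through named
#' substreams, so that independent stages (coupling draw, per-run innovations,
#' weight initialization, run subsampling, ...) are reproducible in isolation
#' and do not perturb each other when one stage is re-run.
#'
#' @param seed integer base seed.
#' @param ... labels (coerced to character) naming the substream.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  lab <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "_"),
                      character(1)), collapse = "/")
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- (abs(seed) %% m)
  h <- (h * 48271) %% m
  if (nzchar(lab)) {
    codes <- utf8ToInt(lab)
    for (cc in codes) h <- (h * 69621 + cc) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a local, seeded RNG state
#'
#' Saves and restores `.Random.seed`, so package internals never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# single check helper used across the package
check_that <- function(ok, msg, class = "neuroar_error") {
  if (!isTRUE(ok)) stop(rlang::error_cnd(class = class, message = msg))
  invisible(TRUE)
}

# population (not sample) standard deviation; convention fixed for
# bit-reproducible z-scoring
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
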