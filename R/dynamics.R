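#' Periodogram power spectrum of parcel signals
#'
#' Plain per-column periodogram `|DFT|^2` on the one-sided frequency grid,
#' without detrending or tapering.
#'
#' @param series `T x P` matrix or a [parcel_ts()].
#' @param tr sampling interval in seconds (taken from the series if a
#'   [parcel_ts()] is given).
#' @return list of class `bold_spectrum`: `freqs` (Hz, from 0 to Nyquist) and
#'   `power` (`length(freqs) x P` matrix).
#' @export
power_spectrum <- function(series, tr = NULL) {
  if (inherits(series, "parcel_ts")) {
    tr <- series$tr
    series <- series$data
  }
  X <- as.matrix(series)
  check_that(nrow(X) >= 8, "need at least 8 time points")
  check_that(!is.null(tr) && tr > 0, "tr required")
  T_len <- nrow(X)
  n_keep <- floor(T_len / 2) + 1
  power <- apply(X, 2, function(x) Mod(stats::fft(x))[seq_len(n_keep)]^2)
  structure(list(freqs = (seq_len(n_keep) - 1) / (T_len * tr),
                 power = matrix(power, n_keep),
                 tr = tr, T_len = T_len),
            class = "bold_spectrum")
}

#' Fraction of spectral power above a cutoff frequency
#'
#' Sums (two-sided-equivalent) periodogram power above the cutoff and
#' divides by total power; the DC bin counts toward total power. Columns are
#' pooled.
#'
#' @param spectrum a `bold_spectrum`.
#' @param cutoff_hz cutoff within the frequency grid.
#' @return fraction in `[0, 1]`.
#' @export
high_frequency_fraction <- function(spectrum, cutoff_hz) {
  check_that(inherits(spectrum, "bold_spectrum"), "need a bold_spectrum")
  check_that(cutoff_hz >= 0 && cutoff_hz <= max(spectrum$freqs),
             "cutoff outside frequency grid")
  # double interior bins to account for the folded negative frequencies
  w <- rep(2, length(spectrum$freqs))
  w[1] <- 1
  if (spectrum$T_len %% 2 == 0) w[length(w)] <- 1
  pw <- spectrum$power * w
  tot <- sum(pw)
  if (tot < 1e-300)
    stop(rlang::error_cnd(class = "neuroar_undefined_fraction",
                          message = "zero total power"))
  sum(pw[spectrum$freqs > cutoff_hz, , drop = FALSE]) / tot
}

#' Seed-based connectivity of a (possibly predicted) seed signal
#'
#' Pearson correlation of one seed signal against every parcel column of the
#' original series. Constant seed or parcel columns yield `NA` entries and a
#' warning rather than silent zeros.
#'
#' @param seed_signal length-`T` numeric vector (original or predicted
#'   parcel signal).
#' @param reference `T x P` matrix (or [parcel_ts()]) of original signals.
#' @return length-`P` correlation vector (named if the reference has parcel
#'   names).
#' @export
seed_connectivity <- function(seed_signal, reference) {
  if (inherits(reference, "parcel_ts")) reference <- reference$data
  reference <- as.matrix(reference)
  check_that(length(seed_signal) == nrow(reference), "lengths must align")
  out <- rep(NA_real_, ncol(reference))
  names(out) <- colnames(reference)
  if (pop_sd(seed_signal) < 1e-12) {
    warning("constant seed signal; all correlations undefined (NA)")
    return(out)
  }
  sds <- apply(reference, 2, pop_sd)
  ok <- sds >= 1e-12
  if (any(!ok)) warning("constant parcel column(s); correlations flagged NA")
  out[ok] <- as.vector(stats::cor(seed_signal, reference[, ok, drop = FALSE]))
  out
}

#' Mark the top fraction of a parcel-level map
#'
#' Marks exactly `ceiling(fraction * P)` highest values; ties are broken by
#' parcel index (lower index wins), so the mask is deterministic.
#'
#' @param values length-`P` numeric vector.
#' @param fraction fraction in (0, 1].
#' @return logical mask of length `P`.
#' @export
threshold_top_fraction <- function(values, fraction) {
  check_that(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  P <- length(values)
  n <- ceiling(fraction * P)
  ord <- order(values, decreasing = TRUE) # stable: lower index wins ties
  mask <- rep(FALSE, P)
  mask[ord[seq_len(n)]] <- TRUE
  mask
}
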