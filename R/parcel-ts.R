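#' Parcel-level time-series for one acquisition run
#'
#' The basic data container of the package: a `T x P` numeric matrix of
#' parcel-averaged BOLD-like signals for a single run, together with its
#' subject / run / condition labels and the sampling interval (TR, seconds).
#'
#' @param data numeric `T x P` matrix (rows = time points, columns = parcels).
#' @param subject,run,condition character labels.
#' @param tr sampling interval in seconds.
#' @return an object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, subject, run, condition, tr) {
  data <- as.matrix(data)
  check_that(is.numeric(data) && all(is.finite(data)),
             "parcel_ts data must be a finite numeric matrix")
  check_that(is.numeric(tr) && length(tr) == 1 && tr > 0, "tr must be a positive scalar")
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("p%03d", seq_len(ncol(data)))
  structure(
    list(data = data, subject = as.character(subject), run = as.character(run),
         condition = as.character(condition), tr = as.numeric(tr)),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> subject=%s condition=%s run=%s  %d time points x %d parcels, TR=%.3fs\n",
              x$subject, x$condition, x$run, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$data)

run_key <- function(ts) paste(ts$condition, ts$run, sep = "/")

# filter a list of parcel_ts by label predicates
filter_runs <- function(runs, subject = NULL, condition = NULL, run = NULL) {
  keep <- vapply(runs, function(r) {
    (is.null(subject) || r$subject %in% subject) &&
      (is.null(condition) || r$condition %in% condition) &&
      (is.null(run) || r$run %in% run)
  }, logical(1))
  runs[keep]
}
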