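#' Write a cohort to disk as delimited tables plus a manifest
#'
#' One tab-separated table per run (rows = time points, columns = labelled
#' parcels), a JSON manifest (subjects, runs, conditions, TR, file paths),
#' and a JSON ground-truth archive (couplings, support adjacency, shared
#' responses, parcel coordinates).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (ts in cohort$runs) {
    fname <- sprintf("%s_%s_%s.tsv", ts$subject, ts$condition, ts$run)
    utils::write.table(ts$data, file.path(dir, fname), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    entries[[length(entries) + 1]] <- list(subject = ts$subject, run = ts$run,
                                           condition = ts$condition, file = fname)
  }
  manifest <- list(tr = cohort$config$tr,
                   n_parcels = cohort$config$n_parcels,
                   run_length = cohort$config$run_length,
                   seed = cohort$config$seed,
                   runs = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  truth <- cohort$truth
  jsonlite::write_json(
    list(couplings = truth$couplings, support_graph = truth$support_graph,
         shared_responses = truth$shared_responses,
         parcel_coords = truth$parcel_coords),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return list with `runs` (list of [parcel_ts()]), `truth` (if the
#'   ground-truth archive is present, with arrays restored), and `tr`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  runs <- lapply(seq_len(nrow(manifest$runs)), function(i) {
    e <- manifest$runs[i, ]
    X <- as.matrix(utils::read.table(file.path(dir, e$file), header = TRUE,
                                     sep = "\t", check.names = FALSE))
    parcel_ts(X, subject = e$subject, run = e$run, condition = e$condition,
              tr = manifest$tr)
  })
  truth <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    raw <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    truth <- list(
      couplings = lapply(raw$couplings, restore_array),
      support_graph = as.matrix(raw$support_graph),
      shared_responses = lapply(raw$shared_responses, as.matrix),
      parcel_coords = as.matrix(raw$parcel_coords))
  }
  list(runs = runs, truth = truth, tr = manifest$tr)
}

# jsonlite deserializes an (p, P, P) array written by write_json as nested
# row-major lists; rebuild the original array layout
restore_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  p <- length(x)
  mats <- lapply(x, function(m) do.call(rbind, lapply(m, unlist)))
  out <- array(0, c(p, nrow(mats[[1]]), ncol(mats[[1]])))
  for (j in seq_len(p)) out[j, , ] <- mats[[j]]
  out
}
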