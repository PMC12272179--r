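#!/usr/bin/env Rscript
# Preprocess the written cohort (0.01 Hz discrete-cosine high-pass, per-run
# z-scoring), split the movie-like runs into train / validation / test by
# the first-block-then-alternate rule, and record the split plus per-split
# window counts for the reference window length.

source(file.path("analysis", "00_setup.R"))

cohort <- read_cohort(COHORT_DIR)
runs <- lapply(cohort$runs, function(r) zscore_per_run(dct_highpass(r, 0.01)))
task_runs <- Filter(function(r) r$condition == "friends", runs)
labels <- sort(unique(vapply(task_runs, function(r) r$run, character(1))))
split <- split_runs(labels, 0.6)

k <- 3
counts <- vapply(list(split$train, split$val, split$test), function(lb) {
  ws <- make_windows(Filter(function(r) r$run %in% lb &&
                              r$subject == "sub-01", task_runs), k = k, l = 1)
  dim(ws$inputs)[1]
}, numeric(1))

jsonlite::write_json(
  list(train = split$train, val = split$val, test = split$test,
       window_length = k,
       windows_per_subject = list(train = counts[1], val = counts[2],
                                  test = counts[3])),
  file.path(RESULTS_DIR, "split.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("split: %d train / %d val / %d test runs\n",
            length(split$train), length(split$val), length(split$test)))
cat(sprintf("lag-1 windows per subject (k = %d): %d train, %d val, %d test\n",
            k, counts[1], counts[2], counts[3]))
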