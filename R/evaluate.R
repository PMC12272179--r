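#' Per-parcel coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)` per parcel, where
#' `ybar` is the mean of the evaluated targets themselves (the naive
#' predict-the-mean baseline of that run). Values can be negative when the
#' prediction is worse than that baseline.
#'
#' @param y_true,y_pred `N x P` matrices.
#' @return length-`P` numeric vector.
#' @export
r2_score <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  check_that(all(dim(y_true) == dim(y_pred)), "shapes must match")
  check_that(nrow(y_true) >= 2, "need at least 2 samples")
  mu <- colMeans(y_true)
  tss <- colSums(sweep(y_true, 2, mu)^2)
  if (any(tss < 1e-24))
    stop(rlang::error_cnd(class = "neuroar_undefined_score",
                          message = "zero-variance true column; R2 undefined"))
  1 - colSums((y_true - y_pred)^2) / tss
}

#' Evaluate a model on runs at multiple lags
#'
#' Predictions come from [predict_iterated()]; one record per (run, lag)
#' holds per-parcel R-squared and its mean over the evaluation parcel mask
#' (all parcels by default).
#'
#' @param model a trained `ar_model`.
#' @param runs list of [parcel_ts()] (or a single run).
#' @param lags integer lags to evaluate.
#' @param mask optional logical/integer parcel subset for `r2_mean`.
#' @param model_subject optional label recorded on the records.
#' @return tibble with columns model_subject, data_subject, run, condition,
#'   lag, r2_mean and list-column r2_parcels.
#' @export
evaluate_model <- function(model, runs, lags = 1, mask = NULL,
                           model_subject = NA_character_) {
  if (inherits(runs, "parcel_ts")) runs <- list(runs)
  rows <- list()
  for (ts in runs) {
    it <- predict_iterated(model, ts, l_max = max(lags))
    for (l in lags) {
      s <- (model$config$k + l):nrow(ts$data)
      r2 <- r2_score(ts$data[s, , drop = FALSE], it$pred[[l]][s, , drop = FALSE])
      m <- if (is.null(mask)) rep(TRUE, length(r2)) else mask
      rows[[length(rows) + 1]] <- tibble::tibble(
        model_subject = model_subject, data_subject = ts$subject,
        run = ts$run, condition = ts$condition, lag = l,
        r2_mean = mean(r2[m]), r2_parcels = list(r2))
    }
  }
  do.call(rbind, rows)
}

#' Subject specificity of individual models
#'
#' For every ordered subject pair (i, j != i) and matched test run r,
#' computes `d = R2(model_i on subject_i, run r) - R2(model_i on subject_j,
#' run r)` (means over parcels), then a two-sided Wilcoxon signed-rank test
#' over runs per pair, Benjamini-Hochberg corrected across pairs. A
#' significantly positive `d` means the model is specific to the subject it
#' was trained on.
#'
#' @param models named list of trained `ar_model`s, one per subject.
#' @param runs list of [parcel_ts()] test runs covering all subjects, with
#'   matching (condition, run) labels across subjects.
#' @param lag evaluation lag (default 1).
#' @param alpha FDR level for the corrected tests.
#' @param mask optional parcel mask.
#' @return list with `differences` (tibble per pair x run) and `tests`
#'   (tibble per pair: mean_d, p, p_adj, reject).
#' @export
subject_specificity <- function(models, runs, lag = 1, alpha = 0.05, mask = NULL) {
  subjects <- names(models)
  check_that(length(subjects) >= 2, "need >= 2 subjects",
             class = "neuroar_alignment")
  keys_by_subj <- lapply(subjects, function(s)
    sort(vapply(filter_runs(runs, subject = s), run_key, character(1))))
  common <- Reduce(intersect, keys_by_subj)
  check_that(length(common) >= 1, "no matched test runs across subjects",
             class = "neuroar_alignment")

  # R2 of model i on data of subject d, per matched run
  r2_tab <- list()
  for (i in subjects) for (d in subjects) {
    subj_runs <- Filter(function(r) run_key(r) %in% common,
                        filter_runs(runs, subject = d))
    ev <- evaluate_model(models[[i]], subj_runs, lags = lag, mask = mask,
                         model_subject = i)
    ev$key <- paste(ev$condition, ev$run, sep = "/")
    r2_tab[[paste(i, d)]] <- ev
  }

  diffs <- list(); tests <- list()
  for (i in subjects) for (j in setdiff(subjects, i)) {
    intra <- r2_tab[[paste(i, i)]]
    inter <- r2_tab[[paste(i, j)]]
    inter <- inter[match(intra$key, inter$key), ]
    d <- intra$r2_mean - inter$r2_mean
    diffs[[length(diffs) + 1]] <- tibble::tibble(
      model_subject = i, other_subject = j, run = intra$key, lag = lag, d = d)
    tests[[length(tests) + 1]] <- tibble::tibble(
      model_subject = i, other_subject = j, lag = lag, mean_d = mean(d),
      p = wilcoxon_paired(intra$r2_mean, inter$r2_mean))
  }
  tests <- do.call(rbind, tests)
  adj <- bh_fdr(tests$p, alpha = alpha)
  tests$p_adj <- adj$p_adj
  tests$reject <- adj$reject
  list(differences = do.call(rbind, diffs), tests = tests)
}

#' Group model versus individual models at matched training-set size
#'
#' Trains one pooled model on `total_train_runs` runs drawn balanced across
#' subjects, and one model per subject on `total_train_runs` of that
#' subject's own runs, then evaluates everything on each subject's test
#' runs. For chebnet configs the graph prior is the binarized functional
#' connectome of the respective training runs.
#'
#' @param train_runs list of training [parcel_ts()] across subjects.
#' @param test_runs list of test [parcel_ts()] across subjects.
#' @param config a [model_config()].
#' @param total_train_runs total runs in each training set.
#' @param lags lags to evaluate.
#' @param graph_density density of the functional graph prior (chebnet).
#' @param epochs,batch_size,learning_rate,seed training controls.
#' @return tibble per (subject, run, lag) with r2_individual and r2_group.
#' @export
group_vs_individual <- function(train_runs, test_runs, config, total_train_runs,
                                lags = 1, graph_density = 0.1, epochs = 40,
                                batch_size = 128, learning_rate = 0.01, seed = 1) {
  subjects <- sort(unique(vapply(train_runs, function(r) r$subject, character(1))))
  per_subj <- ceiling(total_train_runs / length(subjects))
  sel_ind <- list(); sel_grp <- list()
  for (s in subjects) {
    mine <- filter_runs(train_runs, subject = s)
    check_that(length(mine) >= total_train_runs,
               sprintf("subject %s has %d < %d train runs", s, length(mine),
                       total_train_runs), class = "neuroar_config_error")
    idx <- sort(with_seed(substream_seed(seed, "runsel", s),
                          sample.int(length(mine), total_train_runs)))
    sel_ind[[s]] <- mine[idx]
    sel_grp[[s]] <- mine[idx[seq_len(min(per_subj, total_train_runs))]]
  }
  pooled <- unlist(sel_grp, recursive = FALSE)[seq_len(min(total_train_runs,
                                                           per_subj * length(subjects)))]

  # the fit seed is derived from the training-set composition, so identical
  # training sets (e.g. group == individual for a single subject) yield
  # identical models
  train_one <- function(rs) {
    ws <- make_windows(rs, k = config$k, l = 1)
    sp <- if (config$family == "chebnet")
      scaled_laplacian(binarize_top_density(functional_connectome(rs), graph_density))
    else NULL
    lab <- paste(vapply(rs, function(r) paste(r$subject, run_key(r)), character(1)),
                 collapse = ",")
    fit_model(build_model(config, dim(ws$inputs)[3], spectral_op = sp), ws,
              epochs = epochs, batch_size = batch_size,
              learning_rate = learning_rate,
              seed = substream_seed(seed, "fit", lab))
  }

  group_model <- train_one(pooled)
  ind_models <- lapply(subjects, function(s) train_one(sel_ind[[s]]))
  names(ind_models) <- subjects

  rows <- list()
  for (s in subjects) {
    ts_runs <- filter_runs(test_runs, subject = s)
    ev_i <- evaluate_model(ind_models[[s]], ts_runs, lags = lags, model_subject = s)
    ev_g <- evaluate_model(group_model, ts_runs, lags = lags, model_subject = "group")
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject = s, run = ev_i$run, condition = ev_i$condition, lag = ev_i$lag,
      r2_individual = ev_i$r2_mean, r2_group = ev_g$r2_mean,
      d = ev_i$r2_mean - ev_g$r2_mean)
  }
  do.call(rbind, rows)
}

#' Learning curve: accuracy versus amount of training data
#'
#' For each training-set size and repetition, trains a model from scratch on
#' a seeded random subset (without replacement) of the training runs and
#' evaluates on the fixed validation runs.
#'
#' @param train_runs list of training [parcel_ts()] (one subject).
#' @param val_runs list of validation [parcel_ts()].
#' @param config a [model_config()].
#' @param run_counts training-set sizes to probe.
#' @param repetitions training repetitions per size (new subset each).
#' @param lags lags to evaluate.
#' @param graph_density density of the functional graph prior (chebnet).
#' @param epochs,batch_size,learning_rate,seed training controls.
#' @return tibble (n_runs, repetition, lag, r2_mean).
#' @export
data_scaling <- function(train_runs, val_runs, config, run_counts,
                         repetitions = 5, lags = 1, graph_density = 0.1,
                         epochs = 40, batch_size = 128, learning_rate = 0.01,
                         seed = 1) {
  check_that(max(run_counts) <= length(train_runs),
             "max(run_counts) exceeds available train runs",
             class = "neuroar_config_error")
  rows <- list()
  for (n in run_counts) for (rep in seq_len(repetitions)) {
    idx <- sort(with_seed(substream_seed(seed, "subset", n, rep),
                          sample.int(length(train_runs), n)))
    rs <- train_runs[idx]
    ws <- make_windows(rs, k = config$k, l = 1)
    sp <- if (config$family == "chebnet")
      scaled_laplacian(binarize_top_density(functional_connectome(rs), graph_density))
    else NULL
    mdl <- fit_model(build_model(config, dim(ws$inputs)[3], spectral_op = sp), ws,
                     epochs = epochs, batch_size = batch_size,
                     learning_rate = learning_rate,
                     seed = substream_seed(seed, "fit", n, rep))
    ev <- evaluate_model(mdl, val_runs, lags = lags)
    agg <- stats::aggregate(r2_mean ~ lag, data = ev, FUN = mean)
    rows[[length(rows) + 1]] <- tibble::tibble(n_runs = n, repetition = rep,
                                               lag = agg$lag, r2_mean = agg$r2_mean)
  }
  do.call(rbind, rows)
}
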