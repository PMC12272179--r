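#' Assemble an experiment-suite configuration
#'
#' Collects everything needed to run the benchmark end to end: the cohort
#' (config or a directory written by [write_cohort()]), preprocessing
#' controls, the graph prior, the model zoo, evaluation lags, the enabled
#' experiments, and training controls. See [validate_config()] for the
#' checks and defaults applied.
#'
#' @param cohort a [cohort_config()] or a path to a written cohort.
#' @param cutoff_hz high-pass cutoff (Hz) applied per run.
#' @param train_fraction fraction of the task condition's runs for training.
#' @param graph_kind `"functional"`, `"spatial"` or `"random"`.
#' @param graph_density edge density of the binarized graph prior.
#' @param model_grid list of [model_config()]s compared in
#'   `model_comparison` (first entry is the reference model reused by the
#'   other experiments).
#' @param lags lags (TR units) at which models are evaluated.
#' @param experiments character vector of enabled experiments, among
#'   `"model_comparison"`, `"graph_sensitivity"`, `"linearity_sensitivity"`,
#'   `"data_scaling"`, `"subject_specificity"`, `"group_model"`,
#'   `"shared_response_ablation"`, `"dynamics"`.
#' @param n_random_graphs random-graph draws averaged in graph sensitivity.
#' @param run_counts,scaling_repetitions data-scaling controls.
#' @param epochs,batch_size,learning_rate training controls.
#' @param seed base seed; every stage derives named substreams from it.
#' @param output_dir where summary tables are written.
#' @return list of class `experiment_config` (not yet validated).
#' @export
experiment_config <- function(cohort = cohort_config(),
                              cutoff_hz = 0.01,
                              train_fraction = 44 / 68,
                              graph_kind = "functional",
                              graph_density = NULL,
                              model_grid = NULL,
                              lags = 1:6,
                              experiments = c("model_comparison", "dynamics"),
                              n_random_graphs = 5,
                              run_counts = NULL,
                              scaling_repetitions = 5,
                              epochs = 30, batch_size = 128,
                              learning_rate = 0.01,
                              seed = 1,
                              output_dir = "neuroar-results") {
  structure(list(cohort = cohort, cutoff_hz = cutoff_hz,
                 train_fraction = train_fraction, graph_kind = graph_kind,
                 graph_density = graph_density, model_grid = model_grid,
                 lags = lags, experiments = experiments,
                 n_random_graphs = n_random_graphs, run_counts = run_counts,
                 scaling_repetitions = scaling_repetitions, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 seed = seed, output_dir = output_dir),
            class = "experiment_config")
}

known_experiments <- c("model_comparison", "graph_sensitivity",
                       "linearity_sensitivity", "data_scaling",
                       "subject_specificity", "group_model",
                       "shared_response_ablation", "dynamics")

#' Validate and normalize an experiment configuration
#'
#' Fills defaults (graph density 0.10; a compact default model grid),
#' checks units and cross-field constraints (cutoff below Nyquist,
#' `k + max(lag) <= run length`, enough runs for the split and scaling
#' counts), and reports *all* violations at once with their field names.
#'
#' @param config an [experiment_config()].
#' @return the normalized `experiment_config`.
#' @export
validate_config <- function(config) {
  check_that(inherits(config, "experiment_config"), "need an experiment_config")
  violations <- character()
  note <- function(msg) violations <<- c(violations, msg)

  if (is.null(config$graph_density)) config$graph_density <- 0.10
  if (is.null(config$model_grid))
    config$model_grid <- list(
      model_config("chebnet", k = 3, cheb_order = 3, nonlinear = FALSE),
      model_config("linear_multi", k = 3),
      model_config("linear_uni", k = 8))
  if (inherits(config$cohort, "cohort_config")) {
    co <- config$cohort
    task_conds <- setdiff(names(co$n_runs_per_condition), co$rest_conditions)
    if (length(task_conds) == 0)
      note("cohort: needs at least one non-rest condition")
    else if (co$n_runs_per_condition[[task_conds[1]]] < 3)
      note("cohort$n_runs_per_condition: first task condition needs >= 3 runs")
    if (config$cutoff_hz >= 1 / (2 * co$tr))
      note("cutoff_hz: must be below Nyquist 1/(2 tr)")
    kmax <- max(vapply(config$model_grid, function(m) m$k, numeric(1)))
    if (kmax + max(config$lags) > co$run_length)
      note(sprintf("model_grid$k + lags: k=%d + max lag %d exceeds run_length %d",
                   kmax, max(config$lags), co$run_length))
  } else if (!dir.exists(as.character(config$cohort))) {
    note("cohort: neither a cohort_config nor an existing directory")
  }
  bad <- setdiff(config$experiments, known_experiments)
  if (length(bad)) note(sprintf("experiments: unknown flag(s) %s",
                                paste(bad, collapse = ", ")))
  if (length(config$experiments) == 0) note("experiments: none enabled")
  if (config$train_fraction <= 0 || config$train_fraction >= 1)
    note("train_fraction: must lie in (0, 1)")
  if (config$graph_density <= 0 || config$graph_density > 1)
    note("graph_density: must lie in (0, 1]")
  if (length(violations))
    stop(rlang::error_cnd(class = "neuroar_config_error",
                          message = paste(c("invalid experiment config:",
                                            violations), collapse = "\n  - ")))
  config
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[neuroar] ", fmt), ...))

write_summary <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  df <- as.data.frame(df)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# preprocess one run: DCT high-pass then per-run z-scoring
preprocess_run <- function(ts, cutoff_hz) zscore_per_run(dct_highpass(ts, cutoff_hz))

# split the first task condition's runs per subject and collect lists
prepare_cohort_data <- function(config) {
  cohort <- if (inherits(config$cohort, "cohort_config"))
    generate_cohort(config$cohort) else read_cohort(as.character(config$cohort))
  runs <- lapply(cohort$runs, preprocess_run, cutoff_hz = config$cutoff_hz)
  conds <- unique(vapply(runs, function(r) r$condition, character(1)))
  rest <- if (inherits(config$cohort, "cohort_config"))
    config$cohort$rest_conditions else "rest"
  task_cond <- setdiff(conds, rest)[1]
  subjects <- sort(unique(vapply(runs, function(r) r$subject, character(1))))
  task_runs <- filter_runs(runs, condition = task_cond)
  run_labels <- sort(unique(vapply(task_runs, function(r) r$run, character(1))))
  split <- split_runs(run_labels, config$train_fraction)
  list(cohort = cohort, runs = runs, subjects = subjects,
       task_cond = task_cond, split = split,
       train = filter_runs(task_runs, run = split$train),
       val = filter_runs(task_runs, run = split$val),
       test = filter_runs(task_runs, run = split$test))
}

# graph prior for one subject per the configured kind
subject_spectral_op <- function(config, train_runs, coords, seed) {
  graph <- switch(config$graph_kind,
                  functional = binarize_top_density(functional_connectome(train_runs),
                                                    config$graph_density),
                  spatial = spatial_connectome(coords, config$graph_density),
                  random = random_connectome(ncol(train_runs[[1]]$data),
                                             config$graph_density, seed = seed))
  scaled_laplacian(graph)
}

train_subject_model <- function(cfg, train_runs, spectral_op, config, seed) {
  ws <- make_windows(train_runs, k = cfg$k, l = 1)
  mdl <- build_model(cfg, dim(ws$inputs)[3], spectral_op = spectral_op)
  fit_model(mdl, ws, epochs = config$epochs, batch_size = config$batch_size,
            learning_rate = config$learning_rate, seed = seed)
}

#' Run the full experiment suite
#'
#' Executes the enabled experiments in dependency order (simulate ->
#' preprocess -> graphs -> train -> evaluate -> analyze) and writes one
#' summary CSV per experiment plus a manifest (seed, config hash) to the
#' output directory. Reruns with an identical configuration produce
#' byte-identical summaries. Any stage failure aborts with the stage name;
#' summaries of completed stages remain on disk.
#'
#' @param config an [experiment_config()]; validated on entry.
#' @return named list of written file paths, invisibly.
#' @export
run_experiment_suite <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  outputs <- list()
  stage <- "prepare"
  run_stage <- function(name, fn) {
    stage <<- name
    log_stage("stage %s: start", name)
    out <- tryCatch(fn(), error = function(e)
      stop(rlang::error_cnd(class = "neuroar_stage_error",
                            message = sprintf("stage '%s' failed: %s", name,
                                              conditionMessage(e)))))
    log_stage("stage %s: done", name)
    out
  }

  dat <- run_stage("prepare", function() prepare_cohort_data(config))
  ref_cfg <- config$model_grid[[1]]
  lags <- config$lags

  # per-subject training runs + graph prior + reference model (lazy: only the
  # experiments that need the reference model trigger training)
  ref_models <- NULL
  get_ref_models <- function() {
    if (!is.null(ref_models)) return(ref_models)
    ref_models <<- run_stage("train", function() {
      ms <- lapply(dat$subjects, function(s) {
        tr <- filter_runs(dat$train, subject = s)
        sp <- if (ref_cfg$family == "chebnet")
          subject_spectral_op(config, tr, dat$cohort$truth$parcel_coords,
                              substream_seed(seed, "graph", s)) else NULL
        train_subject_model(ref_cfg, tr, sp, config, substream_seed(seed, "fit", s))
      })
      names(ms) <- dat$subjects
      ms
    })
    ref_models
  }

  if ("model_comparison" %in% config$experiments) {
    outputs$model_comparison <- run_stage("model_comparison", function() {
      rows <- list()
      for (ci in seq_along(config$model_grid)) {
        cfg <- config$model_grid[[ci]]
        for (s in dat$subjects) {
          tr <- filter_runs(dat$train, subject = s)
          sp <- if (cfg$family == "chebnet")
            subject_spectral_op(config, tr, dat$cohort$truth$parcel_coords,
                                substream_seed(seed, "graph", s)) else NULL
          mdl <- train_subject_model(cfg, tr, sp, config,
                                     substream_seed(seed, "mc", ci, s))
          ev <- evaluate_model(mdl, filter_runs(dat$test, subject = s),
                               lags = lags, model_subject = s)
          ev$model <- paste0(cfg$family, "_k", cfg$k,
                             if (cfg$family == "chebnet" && !cfg$nonlinear) "_linear" else "")
          rows[[length(rows) + 1]] <- ev
        }
      }
      tab <- do.call(rbind, rows)
      # adjacent-model Wilcoxon per lag over (subject, run) pairs, BH over lags x pairs
      models_u <- unique(tab$model)
      stats_rows <- list()
      if (length(models_u) >= 2) {
        for (l in lags) for (mi in 2:length(models_u)) {
          a <- tab[tab$model == models_u[mi - 1] & tab$lag == l, ]
          b <- tab[tab$model == models_u[mi] & tab$lag == l, ]
          key <- paste(a$data_subject, a$run)
          b <- b[match(key, paste(b$data_subject, b$run)), ]
          stats_rows[[length(stats_rows) + 1]] <- tibble::tibble(
            lag = l, model_a = models_u[mi - 1], model_b = models_u[mi],
            mean_a = mean(a$r2_mean), mean_b = mean(b$r2_mean),
            p = wilcoxon_paired(a$r2_mean, b$r2_mean))
        }
        st <- do.call(rbind, stats_rows)
        adj <- bh_fdr(st$p)
        st$p_adj <- adj$p_adj; st$reject <- adj$reject
        write_summary(st, config$output_dir, "model_comparison_tests")
      }
      write_summary(tab, config$output_dir, "model_comparison")
    })
  }

  if ("graph_sensitivity" %in% config$experiments) {
    outputs$graph_sensitivity <- run_stage("graph_sensitivity", function() {
      cfg <- ref_cfg
      check_that(cfg$family == "chebnet",
                 "graph_sensitivity requires a chebnet reference model")
      rows <- list()
      P <- dat$cohort$config$n_parcels
      for (s in dat$subjects) {
        tr <- filter_runs(dat$train, subject = s)
        te <- filter_runs(dat$test, subject = s)
        graphs <- list(
          functional = scaled_laplacian(binarize_top_density(
            functional_connectome(tr), config$graph_density)),
          spatial = scaled_laplacian(spatial_connectome(
            dat$cohort$truth$parcel_coords, config$graph_density)))
        for (g in names(graphs)) {
          mdl <- train_subject_model(cfg, tr, graphs[[g]], config,
                                     substream_seed(seed, "gsens", g, s))
          ev <- evaluate_model(mdl, te, lags = lags, model_subject = s)
          ev$graph <- g; ev$trial <- 1L
          rows[[length(rows) + 1]] <- ev
        }
        for (trial in seq_len(config$n_random_graphs)) {
          sp <- scaled_laplacian(random_connectome(P, config$graph_density,
                                                   seed = substream_seed(seed, "rg", s, trial)))
          mdl <- train_subject_model(cfg, tr, sp, config,
                                     substream_seed(seed, "gsens", "random", s, trial))
          ev <- evaluate_model(mdl, te, lags = lags, model_subject = s)
          ev$graph <- "random"; ev$trial <- trial
          rows[[length(rows) + 1]] <- ev
        }
      }
      write_summary(do.call(rbind, rows), config$output_dir, "graph_sensitivity")
    })
  }

  if ("linearity_sensitivity" %in% config$experiments) {
    outputs$linearity_sensitivity <- run_stage("linearity_sensitivity", function() {
      cfg <- ref_cfg
      check_that(cfg$family == "chebnet",
                 "linearity_sensitivity requires a chebnet reference model")
      rows <- list()
      for (s in dat$subjects) {
        tr <- filter_runs(dat$train, subject = s)
        te <- filter_runs(dat$test, subject = s)
        sp <- subject_spectral_op(config, tr, dat$cohort$truth$parcel_coords,
                                  substream_seed(seed, "graph", s))
        for (nl in c(FALSE, TRUE)) {
          cfg_nl <- cfg; cfg_nl$nonlinear <- nl
          mdl <- train_subject_model(cfg_nl, tr, sp, config,
                                     substream_seed(seed, "lin", nl, s))
          ev <- evaluate_model(mdl, te, lags = lags, model_subject = s)
          ev$variant <- if (nl) "nonlinear" else "linear"
          rows[[length(rows) + 1]] <- ev
        }
      }
      write_summary(do.call(rbind, rows), config$output_dir, "linearity_sensitivity")
    })
  }

  if ("data_scaling" %in% config$experiments) {
    outputs$data_scaling <- run_stage("data_scaling", function() {
      s <- dat$subjects[1]
      counts <- config$run_counts
      if (is.null(counts)) {
        n_tr <- length(dat$split$train)
        counts <- unique(pmax(1, seq(4, n_tr, by = 4)))
      }
      tab <- data_scaling(filter_runs(dat$train, subject = s),
                          filter_runs(dat$val, subject = s),
                          ref_cfg, run_counts = counts,
                          repetitions = config$scaling_repetitions,
                          lags = lags, graph_density = config$graph_density,
                          epochs = config$epochs, batch_size = config$batch_size,
                          learning_rate = config$learning_rate,
                          seed = substream_seed(seed, "scaling"))
      write_summary(tab, config$output_dir, "data_scaling")
    })
  }

  if ("subject_specificity" %in% config$experiments) {
    outputs$subject_specificity <- run_stage("subject_specificity", function() {
      res <- subject_specificity(get_ref_models(), dat$test, lag = min(lags))
      write_summary(res$differences, config$output_dir, "subject_specificity_diffs")
      write_summary(res$tests, config$output_dir, "subject_specificity_tests")
    })
  }

  if ("group_model" %in% config$experiments) {
    outputs$group_model <- run_stage("group_model", function() {
      n_train <- min(vapply(dat$subjects, function(s)
        length(filter_runs(dat$train, subject = s)), integer(1)))
      tab <- group_vs_individual(dat$train, dat$test, ref_cfg,
                                 total_train_runs = n_train, lags = lags,
                                 graph_density = config$graph_density,
                                 epochs = config$epochs,
                                 batch_size = config$batch_size,
                                 learning_rate = config$learning_rate,
                                 seed = substream_seed(seed, "group"))
      write_summary(tab, config$output_dir, "group_model")
    })
  }

  if ("shared_response_ablation" %in% config$experiments) {
    outputs$shared_response_ablation <- run_stage("shared_response_ablation", function() {
      rows <- list()
      task_runs <- c(dat$train, dat$val, dat$test)
      for (s in dat$subjects) {
        shared <- estimate_shared_response(task_runs, held_out_subject = s)
        strip <- function(rs) lapply(rs, function(r)
          regress_out_shared(r, shared[[run_key(r)]]))
        tr <- filter_runs(dat$train, subject = s)
        te <- filter_runs(dat$test, subject = s)
        tr_res <- strip(tr); te_res <- strip(te)
        sp <- if (ref_cfg$family == "chebnet")
          subject_spectral_op(config, tr, dat$cohort$truth$parcel_coords,
                              substream_seed(seed, "graph", s)) else NULL
        m_full <- train_subject_model(ref_cfg, tr, sp, config,
                                      substream_seed(seed, "sra", "full", s))
        m_res <- train_subject_model(ref_cfg, tr_res, sp, config,
                                     substream_seed(seed, "sra", "resid", s))
        ev_f <- evaluate_model(m_full, te, lags = lags, model_subject = s)
        ev_f$signal <- "original"
        ev_r <- evaluate_model(m_res, te_res, lags = lags, model_subject = s)
        ev_r$signal <- "shared_removed"
        rows[[length(rows) + 1]] <- ev_f
        rows[[length(rows) + 1]] <- ev_r
      }
      write_summary(do.call(rbind, rows), config$output_dir,
                    "shared_response_ablation")
    })
  }

  if ("dynamics" %in% config$experiments) {
    outputs$dynamics <- run_stage("dynamics", function() {
      models <- get_ref_models()
      s <- dat$subjects[1]
      te <- filter_runs(dat$test, subject = s)
      rows <- list(); jac <- list()
      for (ts in te) {
        it <- predict_iterated(models[[s]], ts, l_max = max(lags))
        sp_orig <- power_spectrum(ts)
        rows[[length(rows) + 1]] <- tibble::tibble(
          run = ts$run, source = "original", lag = NA_integer_,
          high_freq_fraction = high_frequency_fraction(sp_orig, 0.025))
        for (l in lags) {
          rng <- (models[[s]]$config$k + l):nrow(ts$data)
          sp_pred <- power_spectrum(it$pred[[l]][rng, , drop = FALSE], tr = ts$tr)
          rows[[length(rows) + 1]] <- tibble::tibble(
            run = ts$run, source = sprintf("predicted_lag%d", l), lag = l,
            high_freq_fraction = high_frequency_fraction(sp_pred, 0.025))
        }
        # seed map overlap at the first lag, seed = parcel 1
        rng1 <- (models[[s]]$config$k + 1):nrow(ts$data)
        sc_orig <- seed_connectivity(ts$data[rng1, 1], ts$data[rng1, , drop = FALSE])
        sc_pred <- seed_connectivity(it$pred[[1]][rng1, 1], ts$data[rng1, , drop = FALSE])
        m1 <- threshold_top_fraction(sc_orig, 0.1)
        m2 <- threshold_top_fraction(sc_pred, 0.1)
        jac[[length(jac) + 1]] <- tibble::tibble(
          run = ts$run, seed_parcel = 1L,
          jaccard = sum(m1 & m2) / sum(m1 | m2))
      }
      write_summary(do.call(rbind, rows), config$output_dir, "dynamics_spectra")
      write_summary(do.call(rbind, jac), config$output_dir, "dynamics_seedmaps")
    })
  }

  manifest <- list(seed = seed,
                   config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
                   experiments = config$experiments,
                   files = lapply(outputs, basename))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outputs)
}
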