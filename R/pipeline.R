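#' End-to-end pipeline: simulate/load, select, classify, tune, evaluate
#'
#' Orchestrates the full workflow over one feature table: optional wrapper
#' feature selection with binary BER, LSTM and MLP training on the selected
#' features, optional hyperparameter tuning, and a metric report on a held
#' out stratified test split. All artifacts are written under `out_dir` with
#' the seed and a config echo embedded.
#'
#' @param config list with elements:
#'   `table` (a `feature_table`) or `features_csv` (path);
#'   `seed` (global seed, default 1);
#'   `select` (logical, run feature selection, default TRUE);
#'   `tune` (logical, run hyperparameter tuning, default FALSE);
#'   `test_fraction` (stratified test holdout, default 0.25);
#'   `ber` (a [ber_settings()] for selection),
#'   `fs` (an [fs_config()]),
#'   `train` (a [train_config()]),
#'   `tune_budget` (as in [tune_lstm()]);
#'   `out_dir` (output directory, optional).
#' @return a `pipeline_report` list: `mask`, `models`, `metrics` (per-model
#'   `metric_report`), `metrics_table` (flat data frame: model, ACC, TPR,
#'   TNR, PPV, NPV, F1, seconds), `selected_ratio`, `seed`, `config_echo`.
#' @export
run_pipeline <- function(config) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  table <- config$table
  if (is.null(table)) {
    if (is.null(config$features_csv)) stop("pipeline needs a feature table")
    table <- read_feature_table(config$features_csv)
  }
  do_select <- !identical(config$select, FALSE)
  test_fraction <- if (is.null(config$test_fraction)) 0.25
                   else config$test_fraction

  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  test <- stratified_holdout(table$labels, test_fraction)
  train_tab <- feature_table(table$values[!test, , drop = FALSE],
                             table$labels[!test],
                             feature_ids = table$feature_ids)

  # stage: feature selection
  if (do_select) {
    ber <- if (is.null(config$ber))
      ber_settings(population_size = 10L, iterations = 10L, seed = seed)
    else config$ber
    fs <- if (is.null(config$fs)) fs_config(seed = seed) else config$fs
    sel <- tryCatch(select_features(train_tab, ber, fs),
                    error = function(e)
                      stop("feature-selection stage failed: ",
                           conditionMessage(e)))
    mask <- sel$mask
  } else {
    sel <- NULL
    mask <- rep(TRUE, ncol(table$values))
  }

  sub_train <- feature_table(train_tab$values[, mask, drop = FALSE],
                             train_tab$labels)
  sub_test_x <- table$values[test, mask, drop = FALSE]
  test_y <- table$labels[test]

  # stage: classification (and optional tuning of the LSTM)
  tc <- if (is.null(config$train)) train_config(seed = seed)
        else config$train
  models <- list()
  t0 <- proc.time()[["elapsed"]]
  if (isTRUE(config$tune)) {
    tune_set <- ber_settings(population_size = 5L, iterations = 3L,
                             seed = seed)
    budget <- if (is.null(config$tune_budget))
      list(search_epochs = 5L, final_epochs = tc$epochs)
    else config$tune_budget
    tuned <- tryCatch(tune_lstm(sub_train, settings = tune_set,
                                budget = budget),
                      error = function(e)
                        stop("tuning stage failed: ", conditionMessage(e)))
    models$lstm <- tuned$final_model
    models$tune <- tuned
  } else {
    models$lstm <- tryCatch(train_lstm(sub_train, config = tc),
                            error = function(e)
                              stop("training stage failed: ",
                                   conditionMessage(e)))
  }
  t_lstm <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  models$mlp <- train_mlp(sub_train, config = tc)
  t_mlp <- proc.time()[["elapsed"]] - t0

  # stage: evaluation on the held-out test split
  metrics <- list(
    lstm = compute_metrics(confusion_counts(
      test_y, as.integer(predict_lstm(models$lstm, sub_test_x) > 0.5)),
      n_for_ci = sum(test)),
    mlp = compute_metrics(confusion_counts(
      test_y, as.integer(predict_mlp(models$mlp, sub_test_x) > 0.5)),
      n_for_ci = sum(test)))
  secs <- c(lstm = t_lstm, mlp = t_mlp)
  metrics_table <- do.call(rbind, lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(model = nm, ACC = m$accuracy, TPR = m$sensitivity,
               TNR = m$specificity, PPV = m$ppv, NPV = m$npv, F1 = m$f1,
               seconds = unname(secs[nm]))
  }))

  report <- structure(list(mask = mask, selection = sel, models = models,
                           metrics = metrics, metrics_table = metrics_table,
                           selected_ratio = mean(mask), seed = seed,
                           config_echo = config[setdiff(names(config),
                                                        "table")]),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_outputs(report, config$out_dir)
  report
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(selected = which(report$mask), D = length(report$mask),
         fitness = if (is.null(report$selection)) NA
                   else report$selection$fitness,
         seed = report$seed),
    file.path(out_dir, "mask.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(report$metrics, function(m)
      m[c("accuracy", "sensitivity", "specificity", "ppv", "npv", "f1",
          "balanced_accuracy")]),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  mt <- report$metrics_table
  mt$seconds <- NULL  # wall-clock excluded from reproducible artifacts
  utils::write.csv(mt, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Render the multi-method comparison tables
#'
#' Given per-method vectors of replicate scores (equal run counts), emits
#' the order-statistics summary per method, the pairwise Wilcoxon
#' signed-rank table of the first method against each other, and the
#' one-way ANOVA table across methods.
#'
#' @param runs named list of equal-length numeric vectors, one per method;
#'   the first is the reference method.
#' @return list with data frames `summary`, `wilcoxon` and an `anova_table`.
#' @export
render_comparison <- function(runs) {
  if (length(runs) < 2L) stop("need at least two methods")
  lens <- vapply(runs, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("Wilcoxon pairing requires equal run counts per method")
  summaries <- lapply(runs, order_stats_summary)
  summary_df <- summaries[[1L]]["statistic"]
  for (nm in names(runs)) summary_df[[nm]] <- summaries[[nm]]$value
  ref <- names(runs)[1L]
  wil <- do.call(rbind, lapply(names(runs)[-1L], function(nm) {
    wr <- tryCatch(wilcoxon_signed_rank(runs[[ref]] - runs[[nm]]),
                   error = function(e)
                     list(W_plus = NA_real_, W_minus = NA_real_,
                          W = NA_real_, p_two_tailed = NA_real_,
                          method = "degenerate"))
    data.frame(comparison = paste(ref, "vs", nm),
               W_plus = wr$W_plus, W_minus = wr$W_minus, W = wr$W,
               p_two_tailed = wr$p_two_tailed, method = wr$method)
  }))
  anova <- tryCatch(one_way_anova(runs), error = function(e) NULL)
  list(summary = summary_df, wilcoxon = wil, anova = anova)
}
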