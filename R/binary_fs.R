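#' Threshold a continuous position into a feature mask
#'
#' The sigmoid transfer function maps each coordinate to a selection
#' probability; a coordinate is selected iff `sigmoid(x) > 0.5` (equivalently
#' `x > 0`). An all-off mask is repaired by forcing on the coordinate with
#' the largest sigmoid value (lowest index on ties), so masks are never
#' empty.
#'
#' @param position numeric position vector.
#' @return logical selection vector of the same length.
#' @examples
#' binarize(c(-2, 3))  # FALSE TRUE
#' @export
binarize <- function(position) {
  sel <- position > 0
  if (!any(sel)) sel[which.max(position)] <- TRUE
  sel
}

#' Configuration of the wrapper feature-selection fitness
#'
#' @param alpha weight of the classification-error term in `[0, 1]`; the
#'   remaining `1 - alpha` weighs the selected-size ratio.
#' @param wrapper `"knn"` (k-nearest-neighbour, the desk-scale default),
#'   `"lstm"` (gated sequence classifier, expensive), or a function
#'   `(values, labels, seed) -> error` for custom wrappers.
#' @param k neighbours for the knn wrapper.
#' @param folds stratified cross-validation folds.
#' @param lstm_config a [train_config()] used when `wrapper = "lstm"`
#'   (validated by holdout rather than folds).
#' @param seed integer seed for fold assignment and tie-breaking.
#' @return an object of class `fs_config`.
#' @export
fs_config <- function(alpha = 0.99, wrapper = "knn", k = 5L, folds = 5L,
                      lstm_config = NULL, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  structure(list(alpha = alpha, wrapper = wrapper, k = as.integer(k),
                 folds = as.integer(folds), lstm_config = lstm_config,
                 seed = as.integer(seed)),
            class = "fs_config")
}

## deterministic stratified fold ids (1..folds) given the current RNG stream
stratified_folds <- function(labels, folds) {
  ids <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds)
      stop("a class has fewer samples than folds")
    ids[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  ids
}

## cross-validated knn error on the selected columns
knn_cv_error <- function(values, labels, k, folds) {
  fold_id <- stratified_folds(labels, folds)
  wrong <- 0L
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (length(unique(labels[!test])) < 2L)
      stop("single-class training fold; cannot score the wrapper")
    pred <- class::knn(values[!test, , drop = FALSE],
                       values[test, , drop = FALSE],
                       factor(labels[!test]), k = k)
    wrong <- wrong + sum(pred != factor(labels[test]))
  }
  wrong / length(labels)
}

## wrapper error of a masked table; deterministic given config$seed
wrapper_error <- function(mask, table, config) {
  vals <- table$values[, mask, drop = FALSE]
  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)
  if (is.function(config$wrapper))
    return(config$wrapper(vals, table$labels, config$seed))
  if (identical(config$wrapper, "knn"))
    return(knn_cv_error(vals, table$labels, config$k, config$folds))
  if (identical(config$wrapper, "lstm")) {
    cfg <- config$lstm_config
    if (is.null(cfg)) cfg <- train_config(epochs = 20L, hidden_size = 8L,
                                          seed = config$seed)
    sub <- feature_table(vals, table$labels)
    model <- train_lstm(sub, config = cfg)
    return(1 - model$traces$validation_accuracy[cfg$epochs])
  }
  stop("unknown wrapper: ", config$wrapper)
}

#' Composite feature-selection fitness
#'
#' `alpha * error + (1 - alpha) * |selected| / D`, where the error is the
#' cross-validated classification error of the wrapper restricted to the
#' selected features. Lies in `[0, 1]` whenever the error does.
#'
#' @param mask logical selection vector.
#' @param table a `feature_table`.
#' @param config an [fs_config()].
#' @return scalar fitness (smaller is better).
#' @export
fs_fitness <- function(mask, table, config = fs_config()) {
  if (!any(mask)) stop("mask must select at least one feature")
  err <- wrapper_error(mask, table, config)
  config$alpha * err + (1 - config$alpha) * sum(mask) / length(mask)
}

#' Wrapper feature selection with binary BER
#'
#' Runs the continuous BER dynamics in dimension D with bounds \[-4, 4\]
#' (so the sigmoid transfer spans roughly \[0.018, 0.982\]), scoring each
#' agent through [binarize()] and [fs_fitness()]. Fitness values are cached
#' per mask so re-visited masks are not re-scored.
#'
#' @param table a `feature_table`.
#' @param settings a [ber_settings()]; its seed drives the whole search.
#' @param config an [fs_config()].
#' @return an object of class `fs_result`: `mask` (logical), `selected`
#'   (indices), `fitness`, `error` (wrapper error of the final mask),
#'   `select_ratio`, `trajectory`, `evaluations`.
#' @export
select_features <- function(table, settings = ber_settings(),
                            config = fs_config()) {
  D <- ncol(table$values)
  cache <- new.env(parent = emptyenv())
  fit_fn <- function(pos) {
    mask <- binarize(pos)
    key <- rawToChar(as.raw(as.integer(mask) + 48L))
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fs_fitness(mask, table, config)
    cache[[key]] <- f
    f
  }
  spec <- objective_spec("fs", D, -4, 4, fit_fn)
  res <- ber_run(spec, settings)
  finish_fs_result(res$best_position, res$best_fitness, res$trajectory,
                   res$evaluations, table, config)
}

finish_fs_result <- function(best_position, best_fitness, trajectory,
                             evaluations, table, config) {
  mask <- binarize(best_position)
  structure(list(mask = mask,
                 selected = which(mask),
                 fitness = best_fitness,
                 error = wrapper_error(mask, table, config),
                 select_ratio = mean(mask),
                 trajectory = trajectory,
                 evaluations = evaluations),
            class = "fs_result")
}

#' Wrapper feature selection with binary particle swarm (control)
#'
#' Global-best PSO over the same continuous space, transfer rule and fitness
#' as [select_features()], provided as a comparison control. Velocities are
#' clamped to the box half-width; inertia 0.7, cognitive and social
#' coefficients 1.5.
#'
#' @param table a `feature_table`.
#' @param settings a [ber_settings()] (population, iterations, seed reused).
#' @param config an [fs_config()].
#' @return an `fs_result`, as for [select_features()].
#' @export
select_features_bpso <- function(table, settings = ber_settings(),
                                 config = fs_config()) {
  D <- ncol(table$values)
  lo <- -4; hi <- 4
  w <- 0.7; c1 <- 1.5; c2 <- 1.5
  vmax <- (hi - lo) / 2
  cache <- new.env(parent = emptyenv())
  score <- function(pos) {
    mask <- binarize(pos)
    key <- rawToChar(as.raw(as.integer(mask) + 48L))
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fs_fitness(mask, table, config)
    cache[[key]] <- f
    f
  }
  set.seed(settings$seed)
  n <- settings$population_size
  X <- matrix(stats::runif(n * D, lo, hi), n, D)
  V <- matrix(stats::runif(n * D, -vmax, vmax), n, D)
  fits <- apply(X, 1, score)
  P <- X; pfit <- fits
  g <- which.min(pfit)
  gbest <- X[g, ]; gfit <- pfit[g]
  traj <- gfit
  evals <- n
  for (t in seq_len(settings$iterations)) {
    for (i in seq_len(n)) {
      u1 <- stats::runif(D); u2 <- stats::runif(D)
      V[i, ] <- w * V[i, ] + c1 * u1 * (P[i, ] - X[i, ]) +
        c2 * u2 * (gbest - X[i, ])
      V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
      X[i, ] <- pmin(pmax(X[i, ] + V[i, ], lo), hi)
      f <- score(X[i, ])
      evals <- evals + 1L
      if (f < pfit[i]) { pfit[i] <- f; P[i, ] <- X[i, ] }
      if (f < gfit) { gfit <- f; gbest <- X[i, ] }
    }
    traj <- c(traj, gfit)
  }
  finish_fs_result(gbest, gfit, traj, evals, table, config)
}

#' Summarize a battery of feature-selection runs
#'
#' Multi-run summary of wrapper error, selected-size ratio and fitness:
#' mean error, mean selected ratio, best/worst/mean fitness and the
#' sample standard deviation (M - 1 denominator, defined 0 at M = 1).
#'
#' @param runs list of `fs_result` objects (or lists with `fitness`,
#'   `error`, `select_ratio`).
#' @return an `fs_run_summary` list.
#' @export
summarize_fs_runs <- function(runs) {
  if (length(runs) == 0L) stop("no runs to summarize")
  fits <- vapply(runs, `[[`, numeric(1), "fitness")
  errs <- vapply(runs, `[[`, numeric(1), "error")
  sizes <- vapply(runs, `[[`, numeric(1), "select_ratio")
  M <- length(runs)
  structure(list(average_error = mean(errs),
                 average_select_size = mean(sizes),
                 best_fitness = min(fits),
                 worst_fitness = max(fits),
                 mean_fitness = mean(fits),
                 sd_fitness = if (M == 1L) 0 else stats::sd(fits),
                 M = M),
            class = "fs_run_summary")
}
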