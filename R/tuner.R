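#' Hyperparameter search space
#'
#' Each dimension has a range, a scale (`"linear"` or `"log"`) and a type
#' (`"real"` or `"integer"`); integer dimensions are rounded after the scale
#' transform and clipped to range. A dimension may instead carry an explicit
#' `choices` vector (e.g. the divisors of the feature dimension for the
#' sequence step width), indexed on a uniform grid.
#'
#' @param dimensions named list; each element a list with `lo`, `hi`,
#'   `scale`, `type`, or with `choices`.
#' @return a `hyper_space` object.
#' @export
hyper_space <- function(dimensions) {
  for (nm in names(dimensions)) {
    dm <- dimensions[[nm]]
    if (is.null(dm$choices)) {
      if (dm$lo >= dm$hi) stop("dimension '", nm, "': lo must be below hi")
      if (dm$scale == "log" && dm$lo <= 0)
        stop("dimension '", nm, "': log scale needs positive bounds")
    }
  }
  structure(list(dimensions = dimensions), class = "hyper_space")
}

#' Default tuning space for the sequence classifier
#'
#' Hidden size 8..256 (log-integer), learning rate 1e-4..1e-1 (log-real),
#' batch size 16..128 (log-integer), and the sequence step width over the
#' divisors of the feature dimension.
#'
#' @param n_features feature dimension of the table being tuned on.
#' @return a [hyper_space()].
#' @export
default_hyper_space <- function(n_features) {
  divs <- which(n_features %% seq_len(n_features) == 0L)
  hyper_space(list(
    hidden_size = list(lo = 8, hi = 256, scale = "log", type = "integer"),
    learning_rate = list(lo = 1e-4, hi = 1e-1, scale = "log", type = "real"),
    batch_size = list(lo = 16, hi = 128, scale = "log", type = "integer"),
    step_dim = list(choices = divs)))
}

#' Decode a unit-hypercube position into hyperparameters
#'
#' Coordinate u in `[0, 1]` maps to `lo + u * (hi - lo)` on a linear scale
#' and to `10^(log10(lo) + u * (log10(hi) - log10(lo)))` on a log scale;
#' integer dimensions are rounded, choice dimensions index their grid.
#' Out-of-range coordinates are clipped.
#'
#' @param position numeric vector in `[0, 1]^k`, one per space dimension.
#' @param space a [hyper_space()].
#' @return named list of decoded hyperparameter values.
#' @examples
#' sp <- default_hyper_space(20)
#' decode_position(rep(0.5, 4), sp)
#' @export
decode_position <- function(position, space) {
  dims <- space$dimensions
  if (length(position) != length(dims))
    stop("'position' length must match the number of space dimensions")
  position <- pmin(pmax(position, 0), 1)
  out <- vector("list", length(dims))
  names(out) <- names(dims)
  for (j in seq_along(dims)) {
    dm <- dims[[j]]
    u <- position[j]
    if (!is.null(dm$choices)) {
      idx <- min(length(dm$choices), 1L + floor(u * length(dm$choices)))
      out[[j]] <- dm$choices[idx]
    } else {
      v <- if (dm$scale == "log")
        10^(log10(dm$lo) + u * (log10(dm$hi) - log10(dm$lo)))
      else dm$lo + u * (dm$hi - dm$lo)
      if (dm$type == "integer") v <- min(dm$hi, max(dm$lo, round(v)))
      out[[j]] <- v
    }
  }
  out
}

## deterministic per-evaluation model seed below 2^31
derive_seed <- function(base, counter) {
  as.integer((as.numeric(base) * 7919 + counter * 104729) %% 2147483647)
}

## decoded config -> validation error of an LSTM trained at the search budget
tune_eval_error <- function(cfg, table, epochs, model_seed) {
  d <- ncol(table$values)
  enc <- sequence_encoding(d %/% cfg$step_dim, cfg$step_dim)
  tc <- train_config(epochs = epochs, learning_rate = cfg$learning_rate,
                     batch_size = cfg$batch_size,
                     hidden_size = cfg$hidden_size, seed = model_seed)
  model <- tryCatch(train_lstm(table, enc, tc), error = function(e) NULL)
  if (is.null(model)) return(Inf)
  1 - model$traces$validation_accuracy[epochs]
}

#' Tune the sequence classifier with the BER optimizer
#'
#' BER searches the unit hypercube of the hyperparameter space; each
#' evaluation decodes a position, trains the classifier at a reduced epoch
#' budget and scores its stratified-holdout validation error. Every trained
#' model's seed derives deterministically from the run seed and an
#' evaluation counter, so the whole search is reproducible. The winning
#' configuration is retrained at the full epoch budget.
#'
#' @param table a `feature_table`.
#' @param space a [hyper_space()]; defaults to [default_hyper_space()].
#' @param settings a [ber_settings()] controlling the search.
#' @param budget list with `search_epochs` (per-evaluation training budget)
#'   and `final_epochs` (retraining budget for the winner).
#' @return a `tune_result`: `best_config`, `best_validation_error`,
#'   `trajectory`, `final_model`, `evaluations`.
#' @export
tune_lstm <- function(table, space = NULL,
                      settings = ber_settings(population_size = 10L,
                                              iterations = 10L),
                      budget = list(search_epochs = 10L, final_epochs = 50L)) {
  if (is.null(space)) space <- default_hyper_space(ncol(table$values))
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  fit_fn <- function(pos) {
    counter$i <- counter$i + 1L
    cfg <- decode_position(pos, space)
    tune_eval_error(cfg, table, budget$search_epochs,
                    derive_seed(settings$seed, counter$i))
  }
  spec <- objective_spec("lstm-tuning", length(space$dimensions), 0, 1,
                         fit_fn)
  res <- ber_run(spec, settings)
  best_config <- decode_position(res$best_position, space)
  d <- ncol(table$values)
  enc <- sequence_encoding(d %/% best_config$step_dim, best_config$step_dim)
  final_cfg <- train_config(epochs = budget$final_epochs,
                            learning_rate = best_config$learning_rate,
                            batch_size = best_config$batch_size,
                            hidden_size = best_config$hidden_size,
                            seed = derive_seed(settings$seed, 0L))
  final_model <- train_lstm(table, enc, final_cfg)
  structure(list(best_config = best_config,
                 best_validation_error = res$best_fitness,
                 trajectory = res$trajectory,
                 final_model = final_model,
                 evaluations = res$evaluations),
            class = "tune_result")
}

#' Equal-budget random-configuration control
#'
#' Draws `n_configs` positions uniformly from the unit hypercube, scores
#' each exactly as [tune_lstm()] does, and returns the validation errors;
#' the null against which tuned configurations are benchmarked.
#'
#' @param table a `feature_table`.
#' @param n_configs number of random configurations.
#' @param space a [hyper_space()].
#' @param budget as in [tune_lstm()].
#' @param seed integer seed.
#' @return numeric vector of validation errors.
#' @export
random_configs_error <- function(table, n_configs, space = NULL,
                                 budget = list(search_epochs = 10L),
                                 seed = 1L) {
  if (is.null(space)) space <- default_hyper_space(ncol(table$values))
  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  k <- length(space$dimensions)
  U <- matrix(stats::runif(n_configs * k), n_configs, k)
  vapply(seq_len(n_configs), function(i) {
    cfg <- decode_position(U[i, ], space)
    tune_eval_error(cfg, table, budget$search_epochs, derive_seed(seed, i))
  }, numeric(1))
}

#' Replicated tuning runs with an order-statistics summary
#'
#' Runs `M` independently seeded tuning searches and summarizes the final
#' validation accuracies in the conventional multi-run layout: number of
#' values, minimum, quartiles (linear interpolation between closest ranks),
#' median, maximum, mean and standard deviation.
#'
#' @param table a `feature_table`.
#' @param settings base [ber_settings()]; run i uses `seed + i - 1`.
#' @param budget as in [tune_lstm()].
#' @param M number of replicate runs (>= 2).
#' @param space optional [hyper_space()].
#' @return list with `accuracies` (length M) and `summary` (a data frame
#'   with columns `statistic`, `value`).
#' @export
replicate_tuning <- function(table, settings = ber_settings(
                               population_size = 5L, iterations = 3L),
                             budget = list(search_epochs = 5L,
                                           final_epochs = 20L),
                             M = 10L, space = NULL) {
  if (M < 2L) stop("'M' must be >= 2")
  acc <- vapply(seq_len(M), function(i) {
    s <- settings
    s$seed <- settings$seed + i - 1L
    res <- tune_lstm(table, space, s, budget)
    max(res$final_model$traces$validation_accuracy)
  }, numeric(1))
  list(accuracies = acc, summary = order_stats_summary(acc))
}

#' Order-statistics summary in the multi-run comparison layout
#'
#' @param x numeric vector of per-run values.
#' @return data frame with `statistic` and `value` columns (number of
#'   values, minimum, 25% percentile, median, 75% percentile, maximum,
#'   mean, standard deviation). Quantiles use linear interpolation
#'   (type 7).
#' @export
order_stats_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(
    statistic = c("Number of values", "Minimum", "25% Percentile", "Median",
                  "75% Percentile", "Maximum", "Mean", "Std. Deviation"),
    value = c(length(x), min(x), q[1L], q[2L], q[3L], max(x), mean(x),
              if (length(x) > 1L) stats::sd(x) else 0))
}
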