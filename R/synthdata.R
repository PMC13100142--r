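#' Unimodal benchmark objectives
#'
#' Standard unimodal test functions used to probe optimizer convergence:
#' `sphere` (sum of squares, bounds \[-100, 100\]), `sum_squares`
#' (index-weighted squares, bounds \[-100, 100\]) and `schwefel_2_22`
#' (sum of absolute values plus their product, bounds \[-10, 10\]). All have
#' their optimum 0 at the origin.
#'
#' @param name one of `"sphere"`, `"sum_squares"`, `"schwefel_2_22"`.
#' @param dimension search-space dimension.
#' @return an [objective_spec()] with attributes `optimum_position` and
#'   `optimum_value`.
#' @examples
#' f <- make_benchmark("sphere", 2)
#' f$evaluate(c(1, 1))  # 2
#' @export
make_benchmark <- function(name = c("sphere", "sum_squares", "schwefel_2_22"),
                           dimension = 10L) {
  name <- match.arg(name)
  d <- as.integer(dimension)
  def <- switch(name,
    sphere = list(fn = function(x) sum(x^2), lo = -100, hi = 100),
    sum_squares = list(fn = function(x) sum(seq_along(x) * x^2),
                       lo = -100, hi = 100),
    schwefel_2_22 = list(fn = function(x) sum(abs(x)) + prod(abs(x)),
                         lo = -10, hi = 10))
  spec <- objective_spec(name, d, def$lo, def$hi, def$fn)
  attr(spec, "optimum_position") <- rep(0, d)
  attr(spec, "optimum_value") <- 0
  spec
}

#' Specification for a synthetic two-class feature table
#'
#' Describes a Gaussian class-conditional model that emulates a deep-feature
#' table: `k` informative features whose class means are separated by
#' `delta`, optionally one redundant correlated copy per informative feature
#' (correlation `rho`), and pure-noise nuisance features. Class sizes default
#' to a 1/10-scale echo of a 1589:2246 Normal:Osteoarthritis split.
#'
#' @param n_class0,n_class1 samples per class (label 0 / label 1).
#' @param d total number of features.
#' @param k number of informative features.
#' @param delta class-mean separation on informative features, in units of
#'   the noise standard deviation when `sigma = 1`.
#' @param rho correlation of each redundant copy with its informative source;
#'   `rho = 0` disables redundant copies.
#' @param sigma noise standard deviation.
#' @param seed integer seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_class0 = 159L, n_class1 = 225L, d = 100L, k = 10L,
                       delta = 3, rho = 0, sigma = 1, seed = 1L) {
  if (k > d) stop("'k' must not exceed 'd'")
  if (delta < 0) stop("'delta' must be nonnegative")
  if (abs(rho) >= 1) stop("'|rho|' must be below 1")
  if (sigma <= 0) stop("'sigma' must be positive")
  structure(list(n_class0 = as.integer(n_class0),
                 n_class1 = as.integer(n_class1),
                 d = as.integer(d), k = as.integer(k),
                 delta = delta, rho = rho, sigma = sigma,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic feature table with known informative features
#'
#' Class-0 samples have mean `-delta/2` and class-1 samples `+delta/2` on the
#' `k` informative features (columns 1..k); when `rho != 0`, columns
#' k+1..2k hold redundant copies `rho * informative + sqrt(1 - rho^2) * noise`;
#' remaining columns are pure noise. The ground-truth informative indices are
#' returned so feature-selection recall can be scored.
#'
#' @param spec a [synth_spec()].
#' @return a `feature_table`: list with `values` (samples x features matrix),
#'   `labels` (0/1 integer vector), `feature_ids`, `informative` (true
#'   informative column indices), `redundant`, and a `provenance` string.
#' @examples
#' tab <- generate_features(synth_spec(n_class0 = 20, n_class1 = 20,
#'                                     d = 10, k = 2, delta = 4, seed = 7))
#' dim(tab$values)
#' @export
generate_features <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_class0 + spec$n_class1
  labels <- rep(c(0L, 1L), c(spec$n_class0, spec$n_class1))
  X <- matrix(stats::rnorm(n * spec$d, sd = spec$sigma), n, spec$d)
  shift <- ifelse(labels == 1L, spec$delta / 2, -spec$delta / 2)
  if (spec$k > 0) {
    X[, seq_len(spec$k)] <- X[, seq_len(spec$k), drop = FALSE] + shift
  }
  redundant <- integer(0)
  if (spec$rho != 0 && spec$k > 0 && 2L * spec$k <= spec$d) {
    redundant <- spec$k + seq_len(spec$k)
    noise <- matrix(stats::rnorm(n * spec$k, sd = spec$sigma), n, spec$k)
    X[, redundant] <- spec$rho * X[, seq_len(spec$k), drop = FALSE] +
      sqrt(1 - spec$rho^2) * noise
  }
  structure(list(values = X,
                 labels = labels,
                 feature_ids = sprintf("f%03d", seq_len(spec$d)),
                 informative = seq_len(spec$k),
                 redundant = redundant,
                 provenance = sprintf(
                   "synthetic gaussian table (n0=%d, n1=%d, d=%d, k=%d, delta=%g, rho=%g, sigma=%g, seed=%d)",
                   spec$n_class0, spec$n_class1, spec$d, spec$k,
                   spec$delta, spec$rho, spec$sigma, spec$seed)),
            class = "feature_table")
}

#' Canned synthetic fixtures used across the test battery
#'
#' `tiny_easy` is a small separable table (equal classes, strong separation),
#' `tiny_hard` its weakly separated counterpart, and `imbalanced_koa_like`
#' a 1/10-scale echo of a 1589:2246 two-class imbalance with moderate
#' separation in 100 features.
#'
#' @param name fixture name.
#' @return a `feature_table`.
#' @export
make_fixture <- function(name = c("tiny_easy", "tiny_hard",
                                  "imbalanced_koa_like")) {
  name <- match.arg(name)
  spec <- switch(name,
    tiny_easy = synth_spec(n_class0 = 60L, n_class1 = 60L, d = 20L, k = 5L,
                           delta = 6, rho = 0, sigma = 1, seed = 101L),
    tiny_hard = synth_spec(n_class0 = 60L, n_class1 = 60L, d = 20L, k = 5L,
                           delta = 1, rho = 0, sigma = 1, seed = 102L),
    imbalanced_koa_like = synth_spec(n_class0 = 159L, n_class1 = 225L,
                                     d = 100L, k = 10L, delta = 3, rho = 0.6,
                                     sigma = 1, seed = 103L))
  generate_features(spec)
}

#' Build a feature table from a matrix and labels
#'
#' @param values numeric matrix, samples by features.
#' @param labels binary 0/1 labels, one per row.
#' @param feature_ids optional column identifiers.
#' @param provenance free-text origin note.
#' @return a `feature_table`.
#' @export
feature_table <- function(values, labels, feature_ids = NULL,
                          provenance = "user-supplied") {
  values <- as.matrix(values)
  labels <- as.integer(labels)
  if (nrow(values) != length(labels))
    stop("'labels' must have one entry per row of 'values'")
  if (anyNA(values) || anyNA(labels))
    stop("feature tables must not contain missing values")
  if (!all(labels %in% c(0L, 1L)))
    stop("'labels' must be binary 0/1")
  if (is.null(feature_ids)) feature_ids <- sprintf("f%03d", seq_len(ncol(values)))
  structure(list(values = values, labels = labels,
                 feature_ids = feature_ids, informative = integer(0),
                 redundant = integer(0), provenance = provenance),
            class = "feature_table")
}

#' Read / write feature tables as CSV
#'
#' Column layout: `sample_id`, `label` (0/1), then one column per feature.
#'
#' @param path file path.
#' @return for `read_feature_table`, a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3L || names(df)[1L] != "sample_id" || names(df)[2L] != "label")
    stop("expected columns: sample_id, label, then features")
  feature_table(as.matrix(df[, -(1:2), drop = FALSE]), df$label,
                feature_ids = names(df)[-(1:2)],
                provenance = paste("read from", path))
}

#' @rdname read_feature_table
#' @param table a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = sprintf("s%04d", seq_along(table$labels)),
                   label = table$labels, check.names = FALSE)
  vals <- as.data.frame(table$values)
  names(vals) <- table$feature_ids
  utils::write.csv(cbind(df, vals), path, row.names = FALSE)
  invisible(path)
}

## Save and restore the global RNG stream so that internally seeded helpers
## do not disturb a caller's reproducibility.
preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
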