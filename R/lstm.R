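## Gated sequence classifier built directly from the cell equations
## (forget/input/output gates, candidate cell state, tanh-squashed output),
## trained by full backpropagation through time with Adam. The candidate
## activation defaults to the logistic sigmoid, with tanh available.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Sequence encoding of a flat feature vector
#'
#' Fixes the convention mapping a flat d-dimensional feature vector to an
#' ordered sequence of `timesteps` vectors of length `step_dim`
#' (`timesteps * step_dim = d`), in row-major order: timestep t covers
#' features `(t-1)*step_dim + 1` to `t*step_dim`.
#'
#' @param timesteps number of sequence steps L.
#' @param step_dim features per step m.
#' @return a `sequence_encoding` object.
#' @export
sequence_encoding <- function(timesteps, step_dim) {
  timesteps <- as.integer(timesteps)
  step_dim <- as.integer(step_dim)
  if (timesteps < 1L || step_dim < 1L)
    stop("'timesteps' and 'step_dim' must be positive")
  structure(list(timesteps = timesteps, step_dim = step_dim),
            class = "sequence_encoding")
}

## default: narrowest step width whose sequence has at most 32 steps, so
## small tables keep scalar steps (d = 20 -> m = 1) and wide deep-feature
## vectors use wide steps (d = 1024 -> m = 32) without unlearnably long
## sequences in between
default_sequence_encoding <- function(d) {
  divisors <- which(d %% seq_len(d) == 0L)
  m <- divisors[match(TRUE, d / divisors <= 32L)]
  sequence_encoding(d %/% m, m)
}

#' Reshape a flat feature vector into an ordered sequence
#'
#' @param features numeric vector of length `timesteps * step_dim`.
#' @param enc a [sequence_encoding()].
#' @return a `timesteps` x `step_dim` matrix; row t is the step-t input.
#'   `as.vector(t(result))` reproduces the input exactly.
#' @examples
#' reshape_to_sequence(1:6, sequence_encoding(3, 2))
#' @export
reshape_to_sequence <- function(features, enc) {
  if (length(features) != enc$timesteps * enc$step_dim)
    stop("feature length must equal timesteps * step_dim")
  matrix(features, nrow = enc$timesteps, ncol = enc$step_dim, byrow = TRUE)
}

#' Initialize gate parameters
#'
#' Gate weight matrices map the concatenation `[y_(t-1), x_t]` to the hidden
#' size; entries are drawn uniformly and scaled by `1/sqrt(fan-in)`. The
#' forget-gate bias starts at 1 so early-sequence information survives long
#' enough to be learned from, the usual remedy for vanishing signal over
#' long sequences.
#'
#' @param step_dim input width m per timestep.
#' @param hidden_size hidden width H.
#' @param seed integer seed.
#' @param candidate_activation `"sigmoid"` (default, as in the gate table) or
#'   `"tanh"` (the conventional cell).
#' @return an `lstm_params` list with `W_f`, `W_i`, `W_o`, `W_c`
#'   (H x (H+m)), biases `b_f`, `b_i`, `b_o`, `b_c`, readout `w_out`,
#'   `b_out`.
#' @export
lstm_params <- function(step_dim, hidden_size, seed = 1L,
                        candidate_activation = c("sigmoid", "tanh")) {
  candidate_activation <- match.arg(candidate_activation)
  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  H <- as.integer(hidden_size)
  m <- as.integer(step_dim)
  fan <- H + m
  rmat <- function(nr, nc, s) matrix(stats::runif(nr * nc, -1, 1) / sqrt(s),
                                     nr, nc)
  structure(list(W_f = rmat(H, fan, fan), b_f = rep(1, H),
                 W_i = rmat(H, fan, fan), b_i = numeric(H),
                 W_o = rmat(H, fan, fan), b_o = numeric(H),
                 W_c = rmat(H, fan, fan), b_c = numeric(H),
                 w_out = stats::runif(H, -1, 1) / sqrt(H), b_out = 0,
                 hidden_size = H, step_dim = m,
                 candidate_activation = candidate_activation),
            class = "lstm_params")
}

#' One step of the gated cell
#'
#' Applies the gate equations to a single input vector:
#' `f = sigma(W_f [y, x] + b_f)`, `i = sigma(W_i [y, x] + b_i)`,
#' `o = sigma(W_o [y, x] + b_o)`, candidate `c* = act(W_c [y, x] + b_c)`,
#' `C = C_prev * f + c* * i`, `y = o * tanh(C)`.
#'
#' @param x_t input vector of length `step_dim`.
#' @param prev list with `cell` and `output` vectors of length
#'   `hidden_size` (zero vectors at t = 0).
#' @param params an [lstm_params()].
#' @return list with `cell`, `output`, and a `gates` list (`f`, `i`, `o`,
#'   `candidate`), all gates strictly inside (0, 1).
#' @export
lstm_cell <- function(x_t, prev, params) {
  if (length(x_t) != params$step_dim) stop("'x_t' has the wrong length")
  z <- c(prev$output, x_t)
  f <- sigmoid(drop(params$W_f %*% z) + params$b_f)
  i <- sigmoid(drop(params$W_i %*% z) + params$b_i)
  o <- sigmoid(drop(params$W_o %*% z) + params$b_o)
  pre_c <- drop(params$W_c %*% z) + params$b_c
  cc <- if (params$candidate_activation == "sigmoid") sigmoid(pre_c)
        else tanh(pre_c)
  C <- prev$cell * f + cc * i
  list(cell = C, output = o * tanh(C),
       gates = list(f = f, i = i, o = o, candidate = cc))
}

#' Forward pass over a sequence
#'
#' Iterates [lstm_cell()] from a zero initial state and applies the single
#' logistic readout unit to the final output vector.
#'
#' @param sequence matrix from [reshape_to_sequence()] (timesteps rows).
#' @param params an [lstm_params()].
#' @return class probability in (0, 1).
#' @export
lstm_forward <- function(sequence, params) {
  sequence <- as.matrix(sequence)
  if (nrow(sequence) < 1L) stop("'sequence' must be nonempty")
  H <- params$hidden_size
  state <- list(cell = numeric(H), output = numeric(H))
  for (t in seq_len(nrow(sequence))) {
    state <- lstm_cell(sequence[t, ], state, params)
  }
  sigmoid(sum(params$w_out * state$output) + params$b_out)
}

#' Training configuration for the classifiers
#'
#' @param epochs training epochs (>= 1).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param hidden_size hidden width H.
#' @param seed integer seed (initialization, splits, shuffles).
#' @param candidate_activation candidate-cell activation for the LSTM.
#' @param validation_fraction stratified holdout fraction for the accuracy
#'   traces.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50L, learning_rate = 0.02,
                         batch_size = 32L, hidden_size = 16L, seed = 1L,
                         candidate_activation = c("sigmoid", "tanh"),
                         validation_fraction = 0.2) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("'epochs' must be >= 1")
  if (learning_rate <= 0) stop("'learning_rate' must be positive")
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 hidden_size = as.integer(hidden_size),
                 seed = as.integer(seed),
                 candidate_activation = match.arg(candidate_activation),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

## stratified holdout: returns logical vector, TRUE = validation
stratified_holdout <- function(labels, fraction) {
  val <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(fraction * length(idx)))
    val[sample(idx, n_val)] <- TRUE
  }
  val
}

## ---- batched forward/backward over all samples ----

lstm_batch_forward <- function(X, params) {
  n <- nrow(X)
  H <- params$hidden_size
  m <- params$step_dim
  L <- ncol(X) %/% m
  Y <- matrix(0, n, H)
  C <- matrix(0, n, H)
  cache <- vector("list", L)
  for (t in seq_len(L)) {
    Xt <- X[, ((t - 1L) * m + 1L):(t * m), drop = FALSE]
    Z <- cbind(Y, Xt)
    f <- sigmoid(Z %*% t(params$W_f) + rep(params$b_f, each = n))
    i <- sigmoid(Z %*% t(params$W_i) + rep(params$b_i, each = n))
    o <- sigmoid(Z %*% t(params$W_o) + rep(params$b_o, each = n))
    pre_c <- Z %*% t(params$W_c) + rep(params$b_c, each = n)
    cc <- if (params$candidate_activation == "sigmoid") sigmoid(pre_c)
          else tanh(pre_c)
    C_prev <- C
    C <- C_prev * f + cc * i
    tC <- tanh(C)
    Y <- o * tC
    cache[[t]] <- list(Z = Z, f = f, i = i, o = o, cc = cc,
                       C_prev = C_prev, C = C, tC = tC)
  }
  logits <- drop(Y %*% params$w_out) + params$b_out
  list(prob = sigmoid(logits), Y = Y, cache = cache, L = L)
}

lstm_batch_backward <- function(X, y, fwd, params) {
  n <- nrow(X)
  H <- params$hidden_size
  m <- params$step_dim
  L <- fwd$L
  dlogit <- (fwd$prob - y) / n
  g <- list(W_f = 0 * params$W_f, b_f = numeric(H),
            W_i = 0 * params$W_i, b_i = numeric(H),
            W_o = 0 * params$W_o, b_o = numeric(H),
            W_c = 0 * params$W_c, b_c = numeric(H),
            w_out = drop(crossprod(fwd$Y, dlogit)),
            b_out = sum(dlogit))
  dY <- outer(dlogit, params$w_out)
  dC <- matrix(0, n, H)
  for (t in rev(seq_len(L))) {
    cc_ <- fwd$cache[[t]]
    dO <- dY * cc_$tC
    dC <- dC + dY * cc_$o * (1 - cc_$tC^2)
    dCc <- dC * cc_$i
    dI <- dC * cc_$cc
    dF <- dC * cc_$C_prev
    dC_prev <- dC * cc_$f
    df_pre <- dF * cc_$f * (1 - cc_$f)
    di_pre <- dI * cc_$i * (1 - cc_$i)
    do_pre <- dO * cc_$o * (1 - cc_$o)
    dcc_pre <- if (params$candidate_activation == "sigmoid")
      dCc * cc_$cc * (1 - cc_$cc) else dCc * (1 - cc_$cc^2)
    Z <- cc_$Z
    g$W_f <- g$W_f + crossprod(df_pre, Z)
    g$W_i <- g$W_i + crossprod(di_pre, Z)
    g$W_o <- g$W_o + crossprod(do_pre, Z)
    g$W_c <- g$W_c + crossprod(dcc_pre, Z)
    g$b_f <- g$b_f + colSums(df_pre)
    g$b_i <- g$b_i + colSums(di_pre)
    g$b_o <- g$b_o + colSums(do_pre)
    g$b_c <- g$b_c + colSums(dcc_pre)
    dZ <- df_pre %*% params$W_f + di_pre %*% params$W_i +
      do_pre %*% params$W_o + dcc_pre %*% params$W_c
    dY <- dZ[, seq_len(H), drop = FALSE]
    dC <- dC_prev
  }
  g
}

## ---- Adam optimizer over a named list of arrays ----

adam_init <- function(params, names) {
  list(m = lapply(params[names], function(p) 0 * p),
       v = lapply(params[names], function(p) 0 * p),
       t = 0L)
}

adam_update <- function(params, grads, opt, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(opt$m)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the gated sequence classifier
#'
#' Minimizes binary cross-entropy of the logistic readout by full
#' backpropagation through time with Adam, on a stratified training split,
#' recording per-epoch train/validation accuracy. Fully deterministic for a
#' fixed seed.
#'
#' @param table a `feature_table` with both classes present.
#' @param enc a [sequence_encoding()]; by default scalar steps for narrow
#'   tables and 32-wide steps for wide tables that divide evenly.
#' @param config a [train_config()].
#' @return an `lstm_model`: `params`, `enc`, `config`, `traces` (data frame
#'   with epoch, loss, train_accuracy, validation_accuracy).
#' @export
train_lstm <- function(table, enc = NULL, config = train_config()) {
  X <- table$values
  y <- table$labels
  if (length(unique(y)) < 2L) stop("both classes must be present")
  d <- ncol(X)
  if (is.null(enc)) enc <- default_sequence_encoding(d)
  if (enc$timesteps * enc$step_dim != d)
    stop("sequence encoding does not match the feature dimension")
  params <- lstm_params(enc$step_dim, config$hidden_size, seed = config$seed,
                        candidate_activation = config$candidate_activation)
  trained <- fit_by_bptt(X, y, params, config,
    forward = lstm_batch_forward, backward = lstm_batch_backward,
    par_names = c("W_f", "b_f", "W_i", "b_i", "W_o", "b_o", "W_c", "b_c",
                  "w_out", "b_out"))
  structure(list(params = trained$params, enc = enc, config = config,
                 traces = trained$traces),
            class = "lstm_model")
}

## shared seeded minibatch training loop for both classifiers
fit_by_bptt <- function(X, y, params, config, forward, backward, par_names) {
  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed + 1L)
  val <- stratified_holdout(y, config$validation_fraction)
  Xtr <- X[!val, , drop = FALSE]; ytr <- y[!val]
  Xva <- X[val, , drop = FALSE]; yva <- y[val]
  opt <- adam_init(params, par_names)
  ntr <- nrow(Xtr)
  traces <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                       train_accuracy = NA_real_,
                       validation_accuracy = NA_real_)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1L, ntr, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, ntr)]
      fwd <- forward(Xtr[idx, , drop = FALSE], params)
      grads <- backward(Xtr[idx, , drop = FALSE], ytr[idx], fwd, params)
      upd <- adam_update(params, grads, opt, config$learning_rate)
      params <- upd$params
      opt <- upd$opt
    }
    ptr <- forward(Xtr, params)$prob
    loss <- bce_loss(ptr, ytr)
    if (!is.finite(loss)) stop("training diverged: non-finite loss at epoch ",
                               ep)
    traces$loss[ep] <- loss
    traces$train_accuracy[ep] <- mean((ptr > 0.5) == ytr)
    traces$validation_accuracy[ep] <-
      mean((forward(Xva, params)$prob > 0.5) == yva)
  }
  list(params = params, traces = traces)
}

#' Predict class probabilities
#'
#' @param model an `lstm_model` or `mlp_model`.
#' @param newdata a `feature_table` or a samples x features matrix.
#' @return vector of probabilities of class 1.
#' @export
predict_lstm <- function(model, newdata) {
  X <- if (inherits(newdata, "feature_table")) newdata$values
       else as.matrix(newdata)
  lstm_batch_forward(X, model$params)$prob
}

## ---- multilayer perceptron baseline ----

mlp_batch_forward <- function(X, params) {
  Apre <- X %*% t(params$W1) + rep(params$b1, each = nrow(X))
  A <- tanh(Apre)
  logits <- drop(A %*% params$w_out) + params$b_out
  list(prob = sigmoid(logits), A = A)
}

mlp_batch_backward <- function(X, y, fwd, params) {
  n <- nrow(X)
  dlogit <- (fwd$prob - y) / n
  dA <- outer(dlogit, params$w_out) * (1 - fwd$A^2)
  list(W1 = crossprod(dA, X), b1 = colSums(dA),
       w_out = drop(crossprod(fwd$A, dlogit)), b_out = sum(dlogit))
}

#' Train the multilayer perceptron baseline
#'
#' One tanh hidden layer and a logistic output unit, trained with the same
#' objective, optimizer, splits and traces as [train_lstm()]; consumes the
#' raw (unsequenced) feature table.
#'
#' @param table a `feature_table`.
#' @param config a [train_config()]; `hidden_size` defaults to 64 here.
#' @return an `mlp_model` with `params`, `config`, `traces`.
#' @export
train_mlp <- function(table, config = train_config(hidden_size = 64L)) {
  X <- table$values
  y <- table$labels
  if (length(unique(y)) < 2L) stop("both classes must be present")
  d <- ncol(X)
  H <- config$hidden_size
  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)
  params <- list(W1 = matrix(stats::runif(H * d, -1, 1) / sqrt(d), H, d),
                 b1 = numeric(H),
                 w_out = stats::runif(H, -1, 1) / sqrt(H),
                 b_out = 0)
  trained <- fit_by_bptt(X, y, params, config,
    forward = mlp_batch_forward, backward = mlp_batch_backward,
    par_names = c("W1", "b1", "w_out", "b_out"))
  structure(list(params = trained$params, config = config,
                 traces = trained$traces),
            class = "mlp_model")
}

#' @rdname predict_lstm
#' @export
predict_mlp <- function(model, newdata) {
  X <- if (inherits(newdata, "feature_table")) newdata$values
       else as.matrix(newdata)
  mlp_batch_forward(X, model$params)$prob
}
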