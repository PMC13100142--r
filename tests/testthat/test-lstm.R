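zero_params <- function(m, H, act = "sigmoid") {
  p <- lstm_params(m, H, seed = 1L, candidate_activation = act)
  for (nm in c("W_f", "W_i", "W_o", "W_c")) p[[nm]][] <- 0
  for (nm in c("b_f", "b_i", "b_o", "b_c", "w_out")) p[[nm]][] <- 0
  p$b_out <- 0
  p
}

test_that("sequence reshaping is row-major and invertible", {
  expect_equal(reshape_to_sequence(1:4, sequence_encoding(4, 1)),
               matrix(1:4, 4, 1))
  expect_equal(reshape_to_sequence(1:6, sequence_encoding(3, 2)),
               rbind(c(1, 2), c(3, 4), c(5, 6)))
  v <- rnorm(24)
  for (m in c(1, 2, 4, 6)) {
    seqm <- reshape_to_sequence(v, sequence_encoding(24 / m, m))
    expect_equal(as.vector(t(seqm)), v)
  }
  expect_error(reshape_to_sequence(1:5, sequence_encoding(2, 3)), "length")
})

test_that("zero-parameter cell reproduces its closed form", {
  p <- zero_params(3, 4)
  st <- lstm_cell(rnorm(3), list(cell = numeric(4), output = numeric(4)), p)
  expect_equal(st$gates$f, rep(0.5, 4))
  expect_equal(st$gates$i, rep(0.5, 4))
  expect_equal(st$gates$o, rep(0.5, 4))
  expect_equal(st$gates$candidate, rep(0.5, 4))
  expect_equal(st$cell, rep(0.25, 4))
  expect_equal(st$output, rep(0.5 * tanh(0.25), 4), tolerance = 1e-9)
})

test_that("one-input-unit cell matches a straight-line transcription", {
  p <- zero_params(1, 1)
  for (nm in c("W_f", "W_i", "W_o", "W_c")) p[[nm]][] <- 1
  st <- lstm_cell(1, list(cell = 0, output = 0), p)
  s1 <- 1 / (1 + exp(-1))
  expect_equal(st$gates$f, s1, tolerance = 1e-9)
  expect_equal(st$cell, s1 * s1, tolerance = 1e-9)
  expect_equal(st$output, s1 * tanh(s1 * s1), tolerance = 1e-9)
  # frozen value of the transcription above
  expect_equal(st$output, 0.357321538745, tolerance = 1e-9)
})

test_that("a large negative forget bias erases the previous cell state", {
  p <- zero_params(2, 3)
  p$b_f[] <- -50
  prev <- list(cell = c(5, -5, 2), output = numeric(3))
  st <- lstm_cell(rnorm(2), prev, p)
  expect_equal(st$cell, st$gates$candidate * st$gates$i, tolerance = 1e-12)
})

test_that("gates stay in (0,1) and the cell state is bounded by t", {
  set.seed(31)
  p <- lstm_params(2, 5, seed = 31L)  # sigmoid candidate
  st <- list(cell = numeric(5), output = numeric(5))
  for (t in 1:12) {
    st <- lstm_cell(rnorm(2, sd = 3), st, p)
    for (g in st$gates) {
      expect_true(all(g > 0 & g < 1))
    }
    expect_true(all(st$cell >= 0 & st$cell <= t))
  }
})

test_that("forward pass: symmetric logit, link range, composition", {
  p0 <- zero_params(2, 3)
  expect_equal(lstm_forward(matrix(rnorm(8), 4, 2), p0), 0.5)
  p <- lstm_params(2, 3, seed = 5L)
  pr <- lstm_forward(matrix(rnorm(8, sd = 10), 4, 2), p)
  expect_true(pr > 0 && pr < 1)
  # single-step forward equals cell + readout transcription
  x <- rnorm(2)
  st <- lstm_cell(x, list(cell = numeric(3), output = numeric(3)), p)
  expect_equal(lstm_forward(matrix(x, 1, 2), p),
               1 / (1 + exp(-(sum(p$w_out * st$output) + p$b_out))))
  expect_error(lstm_forward(matrix(nrow = 0, ncol = 2), p), "nonempty")
})

test_that("training is seeded-deterministic and validates its inputs", {
  tab <- generate_features(synth_spec(n_class0 = 30L, n_class1 = 30L,
                                      d = 10L, k = 3L, delta = 5, seed = 8L))
  cfg <- train_config(epochs = 10L, hidden_size = 8L, seed = 3L)
  m1 <- train_lstm(tab, config = cfg)
  m2 <- train_lstm(tab, config = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$traces, m2$traces)
  expect_error(train_config(epochs = 0L), "epochs")
  one_class <- feature_table(matrix(rnorm(20), 10, 2), rep(1L, 10))
  expect_error(train_lstm(one_class), "both classes")
  expect_error(train_mlp(one_class), "both classes")
})

test_that("both classifiers learn a separable table", {
  tab <- make_fixture("tiny_easy")
  ml <- train_lstm(tab, config = train_config(epochs = 40L,
                                              hidden_size = 16L, seed = 2L))
  mm <- train_mlp(tab, config = train_config(epochs = 40L,
                                             hidden_size = 64L, seed = 2L))
  expect_gte(max(ml$traces$train_accuracy), 0.95)
  expect_gte(max(mm$traces$train_accuracy), 0.95)
  # both consume the same table; prediction interfaces are parallel
  pl <- predict_lstm(ml, tab)
  pm <- predict_mlp(mm, tab)
  expect_length(pl, length(tab$labels))
  expect_length(pm, length(tab$labels))
  expect_true(all(pl > 0 & pl < 1))
})

test_that("tanh candidate variant trains and differs from the default", {
  tab <- generate_features(synth_spec(n_class0 = 25L, n_class1 = 25L,
                                      d = 8L, k = 2L, delta = 5, seed = 12L))
  m_sig <- train_lstm(tab, config = train_config(epochs = 5L,
                                                 hidden_size = 4L, seed = 1L))
  m_tanh <- train_lstm(tab, config = train_config(
    epochs = 5L, hidden_size = 4L, seed = 1L,
    candidate_activation = "tanh"))
  expect_false(identical(m_sig$params$W_c, m_tanh$params$W_c))
})
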