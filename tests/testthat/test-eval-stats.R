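test_that("metrics from counts match hand arithmetic and clipping", {
  perfect <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0),
                             n_for_ci = 100)
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv",
               "f1", "balanced_accuracy"))
    expect_equal(perfect[[nm]], 1)
  expect_true(all(perfect$ci$upper <= 1))
  expect_true(all(perfect$ci$lower >= 0))

  m <- compute_metrics(list(TP = 30, FN = 10, TN = 50, FP = 10))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 50 / 60)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 50 / 60)
  expect_equal(m$f1, 0.75)
  expect_equal(m$balanced_accuracy, (0.75 + 50 / 60) / 2)

  # zero denominator: that metric is undefined, the others are reported
  none_pos <- compute_metrics(list(TP = 0, FN = 0, TN = 10, FP = 5))
  expect_true(is.na(none_pos$sensitivity))
  expect_equal(none_pos$specificity, 10 / 15)
})

test_that("counts-based metrics equal an independent counting pass", {
  set.seed(14)
  for (i in 1:5) {
    truth <- rbinom(80, 1, 0.4)
    pred <- ifelse(runif(80) < 0.25, 1 - truth, truth)
    m <- compute_metrics(confusion_counts(truth, pred))
    o <- manual_metrics(truth, pred)
    for (nm in names(o)) expect_equal(m[[nm]], o[[nm]])
  }
})

test_that("harmonic-mean F1 reproduces the published worked example", {
  expect_equal(f1_score(0.938679245, 0.952153110), 0.945368171,
               tolerance = 1e-9)
})

test_that("balanced accuracy reproduces the published pairs", {
  expect_equal(balanced_accuracy(0.5, 0.5), 0.5)
  x <- runif(1)
  expect_equal(balanced_accuracy(x, x), x)
  expect_equal(round(balanced_accuracy(0.99707887, 0.993119266), 6),
               0.995099)
  expect_equal(round(balanced_accuracy(0.95215311, 0.962427746), 5),
               0.95729)
  expect_error(balanced_accuracy(1.2, 0.5), "\\[0, 1\\]")
})

test_that("signed-rank test: all-positive cases and conventions", {
  w <- wilcoxon_signed_rank((1:10) / 10)
  expect_equal(w$W_plus, 55)
  expect_equal(w$W_minus, 0)
  expect_equal(w$p_two_tailed, 2 / 1024)
  expect_equal(round(w$p_two_tailed, 3), 0.002)
  expect_equal(w$method, "exact")

  w3 <- wilcoxon_signed_rank(c(0.3, 0.1, 0.2))
  expect_equal(w3$W_plus, 6)
  expect_equal(w3$p_two_tailed, 0.25)

  # zeros are dropped before ranking
  wz <- wilcoxon_signed_rank(c(0, 0, 1, 2, -3))
  expect_equal(wz$n, 3L)
  expect_equal(wz$W_plus + wz$W_minus, 3 * 4 / 2)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
})

test_that("exact p agrees with wilcox.test on tie-free data", {
  set.seed(5)
  for (i in 1:8) {
    d <- round(rnorm(9), 6)
    d <- d[d != 0]
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    mine <- wilcoxon_signed_rank(d)
    expect_equal(mine$p_two_tailed, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact null matches full sign enumeration for every pattern", {
  # tie-free ranks 1..n: every sign pattern at n = 10
  n <- 10
  r <- 1:n
  sums <- enumerate_signrank_sums(r)
  for (pat in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(pat, 2^(0:(n - 1))) > 0, 1, -1)
    d <- signs * r
    w <- wilcoxon_signed_rank(d)
    w_obs <- sum(r[signs > 0])
    p_oracle <- min(1, 2 * min(mean(sums >= w_obs), mean(sums <= w_obs)))
    expect_equal(w$p_two_tailed, p_oracle, tolerance = 1e-12)
  }
  # midrank ties: random sign patterns over a tied magnitude set at n = 12
  mags <- c(1, 1, 2, 2, 2, 3, 4, 4, 5, 6, 6, 7)
  r_t <- rank(mags)
  sums_t <- enumerate_signrank_sums(r_t)
  set.seed(77)
  for (i in 1:40) {
    signs <- sample(c(-1, 1), 12, replace = TRUE)
    d <- signs * mags
    if (all(signs == 0)) next
    w <- wilcoxon_signed_rank(d)
    w_obs <- sum(r_t[signs > 0])
    p_oracle <- min(1, 2 * min(mean(sums_t >= w_obs - 1e-9),
                               mean(sums_t <= w_obs + 1e-9)))
    expect_equal(w$p_two_tailed, p_oracle, tolerance = 1e-12)
  }
})

test_that("large-sample path falls back to the normal approximation", {
  set.seed(3)
  d <- rnorm(40, mean = 0.4)
  w <- wilcoxon_signed_rank(d)
  expect_equal(w$method, "normal")
  expect_true(w$p_two_tailed > 0 && w$p_two_tailed < 1)
})

test_that("one-way ANOVA matches the hand decomposition", {
  a <- one_way_anova(list(c(0, 1), c(1, 2)))
  expect_equal(a$ss_between, 1)
  expect_equal(a$df_between, 1L)
  expect_equal(a$ss_within, 1)
  expect_equal(a$df_within, 2L)
  expect_equal(a$f_stat, 2)

  # degenerate: identical constant groups
  flat <- one_way_anova(list(rep(2, 3), rep(2, 4)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$f_stat))

  # sum-of-squares identity and oracle agreement on random inputs
  set.seed(9)
  for (i in 1:5) {
    groups <- lapply(1:4, function(g) rnorm(sample(3:8, 1), mean = g / 2))
    a <- one_way_anova(groups)
    o <- manual_anova(groups)
    expect_equal(a$ss_between, o$ss_between, tolerance = 1e-10)
    expect_equal(a$ss_within, o$ss_within, tolerance = 1e-10)
    expect_equal(a$ss_total, a$ss_between + a$ss_within, tolerance = 1e-10)
    expect_equal(a$f_stat, (o$ss_between / o$df_between) /
                   (o$ss_within / o$df_within), tolerance = 1e-10)
  }
})

test_that("F from a printed sum-of-squares decomposition", {
  a <- anova_from_ss(0.006464, 4, 0.000605, 45)
  expect_equal(round(a$f_stat, 1), 120.2)
  expect_lt(a$p_value, 1e-4)
  expect_equal(a$ss_total, 0.007069)
})

test_that("cosine similarity: self, orthogonal, arithmetic", {
  v <- rnorm(6)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
})

test_that("complexity product reports raw work units", {
  expect_equal(complexity_product(0, 5, 7), 0)
  expect_equal(complexity_product(15, 1024, 50), 768000)
  expect_equal(complexity_product(25, 1024, 50), 1280000)
})
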