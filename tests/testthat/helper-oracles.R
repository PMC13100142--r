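# Independent oracles used across the suite.

# Exact two-tailed signed-rank p by literal enumeration of all 2^n sign
# assignments (independent of the package's convolution implementation).
enumerate_signrank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  sums <- as.matrix(subsets) %*% r
  p_ge <- mean(sums >= w_obs - 1e-9)
  p_le <- mean(sums <= w_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# Null distribution of W+ for a rank multiset, by the same literal
# enumeration; returns the vector of subset sums.
enumerate_signrank_sums <- function(r) {
  n <- length(r)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  drop(as.matrix(subsets) %*% r)
}

# Hand sum-of-squares decomposition for one-way ANOVA.
manual_anova <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  list(ss_between = ss_b, ss_within = ss_w,
       df_between = length(groups) - 1L,
       df_within = length(all_v) - length(groups))
}

# Type-7 quantile by explicit linear interpolation between closest ranks.
manual_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# Metrics recomputed by an independent counting pass over raw vectors.
manual_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  list(accuracy = (tp + tn) / length(truth), sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp), ppv = tp / (tp + fp),
       npv = tn / (tn + fn), f1 = 2 * tp / (2 * tp + fp + fn))
}
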