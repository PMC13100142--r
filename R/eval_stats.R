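#' Confusion counts from label and prediction vectors
#'
#' @param truth true 0/1 labels.
#' @param predicted predicted 0/1 labels (or probabilities, thresholded at
#'   0.5).
#' @param positive which label is the positive class (default 1, the
#'   disease class).
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive = 1L) {
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have the same length")
  if (is.double(predicted) && any(predicted %% 1 != 0))
    predicted <- as.integer(predicted > 0.5)
  pos_t <- truth == positive
  pos_p <- predicted == positive
  structure(list(TP = sum(pos_t & pos_p), TN = sum(!pos_t & !pos_p),
                 FP = sum(!pos_t & pos_p), FN = sum(pos_t & !pos_p)),
            class = "confusion_counts")
}

#' Classification metrics with Wald confidence intervals
#'
#' Computes accuracy, sensitivity (TPR), specificity (TNR), positive and
#' negative predictive values, F1 and balanced accuracy from confusion
#' counts. Specificity uses the standard `TN / (TN + FP)`. When `n_for_ci`
#' is given, each metric gets a normal-approximation 95% interval
#' `p +/- 1.96 * sqrt(p (1 - p) / n)`, clipped to `[0, 1]`. A metric whose
#' denominator is zero is reported as `NA` while the others are computed.
#'
#' @param counts a [confusion_counts()] object or a list with TP/TN/FP/FN.
#' @param n_for_ci sample size for the intervals (e.g. the test-set size);
#'   `NULL` suppresses them.
#' @param z normal quantile for the interval (1.96 for 95%).
#' @return a `metric_report` list: `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `f1`, `balanced_accuracy`, counts echo, and `ci` (a data
#'   frame) when requested.
#' @examples
#' compute_metrics(list(TP = 30, FN = 10, TN = 50, FP = 10))
#' @export
compute_metrics <- function(counts, n_for_ci = NULL, z = 1.96) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- ratio(TP + TN, TP + TN + FP + FN)
  tpr <- ratio(TP, TP + FN)
  tnr <- ratio(TN, TN + FP)
  ppv <- ratio(TP, TP + FP)
  npv <- ratio(TN, TN + FN)
  f1 <- ratio(2 * TP, 2 * TP + FP + FN)
  bal <- if (is.na(tpr) || is.na(tnr)) NA_real_ else (tpr + tnr) / 2
  rep_ <- list(accuracy = acc, sensitivity = tpr, specificity = tnr,
               ppv = ppv, npv = npv, f1 = f1, balanced_accuracy = bal,
               counts = counts)
  if (!is.null(n_for_ci)) {
    vals <- c(accuracy = acc, sensitivity = tpr, specificity = tnr,
              ppv = ppv, npv = npv, f1 = f1, balanced_accuracy = bal)
    half <- z * sqrt(vals * (1 - vals) / n_for_ci)
    rep_$ci <- data.frame(metric = names(vals), estimate = unname(vals),
                          lower = pmax(0, unname(vals - half)),
                          upper = pmin(1, unname(vals + half)))
  }
  structure(rep_, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  nm <- c("accuracy", "sensitivity", "specificity", "ppv", "npv", "f1",
          "balanced_accuracy")
  for (n in nm) cat(sprintf("  %-18s %s\n", n, format(x[[n]], digits = 7)))
  invisible(x)
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean `2 * ppv * tpr / (ppv + tpr)`, used to reconstruct F1 from
#' published precision/sensitivity pairs.
#'
#' @param ppv positive predictive value in `[0, 1]`.
#' @param tpr sensitivity in `[0, 1]`.
#' @return the F1 score.
#' @examples
#' f1_score(0.938679245, 0.952153110)
#' @export
f1_score <- function(ppv, tpr) {
  if (ppv + tpr == 0) return(NA_real_)
  2 * ppv * tpr / (ppv + tpr)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity; insensitive to class imbalance.
#'
#' @param tpr sensitivity in `[0, 1]`.
#' @param tnr specificity in `[0, 1]`.
#' @return `(tpr + tnr) / 2`.
#' @examples
#' balanced_accuracy(0.99707887, 0.993119266)
#' @export
balanced_accuracy <- function(tpr, tnr) {
  if (any(tpr < 0 | tpr > 1) || any(tnr < 0 | tnr > 1))
    stop("rates must lie in [0, 1]")
  (tpr + tnr) / 2
}

#' Wilcoxon signed-rank test with an exact small-sample null
#'
#' Zero differences are dropped; absolute differences are ranked with
#' midranks for ties. For n <= 20 the two-tailed p-value is exact, computed
#' from the full null distribution of the positive-rank sum over all 2^n
#' equiprobable sign assignments (evaluated by convolution over ranks, which
#' enumerates the same distribution). Beyond n = 20 a normal approximation
#' with continuity and tie correction is used.
#'
#' @param differences numeric vector of paired differences, at least one
#'   nonzero.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return a `wilcoxon_result` list: `W_plus`, `W_minus`, `W` (signed-rank
#'   sum `W_plus - W_minus`), `n` (after zero removal), `p_two_tailed`,
#'   `method`.
#' @examples
#' wilcoxon_signed_rank(rep(0.01, 10) + (1:10) / 1000)
#' @export
wilcoxon_signed_rank <- function(differences,
                                 method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  r <- rank(abs(d))
  W_plus <- sum(r[d > 0])
  W_minus <- sum(r[d < 0])
  use_exact <- method == "exact" || (method == "auto" && n <= 20L)
  if (use_exact) {
    # distribution of 2*W+ over all sign assignments; midranks double to ints
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with sum s
    counts[1L] <- 1
    for (v in r2) {
      shifted <- c(numeric(v), counts[seq_len(total + 1L - v)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    s_obs <- as.integer(round(2 * W_plus))
    p_ge <- sum(probs[(s_obs + 1L):(total + 1L)])
    p_le <- sum(probs[1L:(s_obs + 1L)])
    p <- min(1, 2 * min(p_ge, p_le))
    used <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W_plus - mu - sign(W_plus - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    used <- "normal"
  }
  structure(list(W_plus = W_plus, W_minus = W_minus, W = W_plus - W_minus,
                 n = n, p_two_tailed = p, method = used),
            class = "wilcoxon_result")
}

#' One-way ANOVA
#'
#' Standard between/within sum-of-squares decomposition with the F test,
#' fitted through [stats::aov()]. When the within-group mean square is zero
#' the F statistic is undefined and flagged degenerate.
#'
#' @param groups list of numeric vectors, each a group with >= 2 values.
#' @return an `anova_table` list: `ss_between`, `df_between`, `ms_between`,
#'   `ss_within`, `df_within`, `ms_within`, `f_stat`, `p_value`, `ss_total`,
#'   `df_total`, `degenerate`.
#' @examples
#' one_way_anova(list(c(0, 1), c(1, 2)))
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least two values")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  # perfect fits raise an advisory warning; degeneracy is flagged explicitly
  tab <- suppressWarnings(stats::anova(stats::aov(value ~ grp)))
  ss_b <- tab$`Sum Sq`[1L]; df_b <- tab$Df[1L]
  ss_w <- tab$`Sum Sq`[2L]; df_w <- tab$Df[2L]
  # zero within-group variance (all groups constant) leaves F undefined
  degen <- all(vapply(groups, stats::var, numeric(1)) == 0) ||
    !is.finite(tab$`F value`[1L])
  structure(list(ss_between = ss_b, df_between = df_b,
                 ms_between = ss_b / df_b,
                 ss_within = ss_w, df_within = df_w,
                 ms_within = ss_w / df_w,
                 f_stat = if (degen) NA_real_ else tab$`F value`[1L],
                 p_value = if (degen) NA_real_ else tab$`Pr(>F)`[1L],
                 ss_total = ss_b + ss_w, df_total = df_b + df_w,
                 degenerate = degen),
            class = "anova_table")
}

#' ANOVA F statistic and p-value from printed sums of squares
#'
#' Reconstructs the F test from a published between/within decomposition.
#'
#' @param ss_between,df_between between-group sum of squares and df.
#' @param ss_within,df_within within-group sum of squares and df.
#' @return an `anova_table` (without raw data).
#' @examples
#' anova_from_ss(0.006464, 4, 0.000605, 45)$f_stat
#' @export
anova_from_ss <- function(ss_between, df_between, ss_within, df_within) {
  ms_b <- ss_between / df_between
  ms_w <- ss_within / df_within
  degen <- ms_w <= 0
  f <- if (degen) NA_real_ else ms_b / ms_w
  structure(list(ss_between = ss_between, df_between = df_between,
                 ms_between = ms_b,
                 ss_within = ss_within, df_within = df_within,
                 ms_within = ms_w,
                 f_stat = f,
                 p_value = if (degen) NA_real_ else
                   stats::pf(f, df_between, df_within, lower.tail = FALSE),
                 ss_total = ss_between + ss_within,
                 df_total = df_between + df_within,
                 degenerate = degen),
            class = "anova_table")
}

#' Cosine similarity between two vectors
#'
#' Used as the robustness statistic comparing original and perturbed
#' feature vectors.
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return `dot(a, b) / (|a| |b|)` in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vectors have no direction")
  sum(a * b) / (na * nb)
}

#' Abstract work units of a population-search configuration
#'
#' The optimizer's time complexity is O(n * d * iter); this reports the raw
#' product as the per-configuration work unit.
#'
#' @param n population size.
#' @param d feature/search dimension.
#' @param iters iterations.
#' @return `n * d * iters`.
#' @examples
#' complexity_product(15, 1024, 50)
#' @export
complexity_product <- function(n, d, iters) {
  if (any(c(n, d, iters) < 0)) stop("inputs must be nonnegative")
  n * d * iters
}
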