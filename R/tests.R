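#' Likelihood-ratio test of neutrality against a one-parameter mode
#'
#' `D = 2 (ll_s - ll_0)` referred to a chi-square distribution with one
#' degree of freedom; small negative values of `D` arising from numerical
#' noise in nested fits are clamped to zero.
#'
#' @param ll_s maximized log-likelihood under the alternative mode.
#' @param ll_0 maximized log-likelihood under neutrality.
#' @return named vector `c(D, p)`.
#' @export
lrt_pvalue <- function(ll_s, ll_0) {
  D <- max(0, 2 * (ll_s - ll_0))
  c(D = D, p = pchisq(D, df = 1, lower.tail = FALSE))
}

#' Multiple-alternative test statistic
#'
#' \eqn{\delta = -2 (ll_0 - \max(ll_{add}, ll_{dom}, ll_{rec}, ll_{het}))},
#' the largest of the four single-alternative likelihood-ratio statistics,
#' clamped to be nonnegative.
#'
#' @param ll0 neutral log-likelihood.
#' @param ll_modes numeric vector of mode log-likelihoods (additive,
#'   dominant, recessive, heterozygote difference).
#' @return scalar delta.
#' @export
delta_statistic <- function(ll0, ll_modes) {
  max(0, -2 * (ll0 - max(ll_modes)))
}

#' Classify the mode of selection at one locus
#'
#' Stepwise procedure over the one-parameter modes: compute the delta
#' statistic, obtain its p-value from a chi-square(1) null (the
#' chi-square(2) reference is available for comparison but is poorly
#' calibrated), and if neutrality is rejected label the locus by the
#' argmax-likelihood mode.  When heterozygote difference wins, the label
#' is split into overdominant (`s1 > 0`) or underdominant (`s1 < 0`).
#' Exact likelihood ties are resolved in the fixed order additive,
#' dominant, recessive, heterozygote difference and flagged.
#'
#' @param fits a `mode_fits` object from [fit_all_modes()], or a list with
#'   elements `ll0`, `ll_modes` (named numeric vector over the four
#'   one-parameter modes) and `s1_het`.
#' @param threshold significance level for rejecting neutrality.
#' @param df degrees of freedom for the chi-square null (default 1).
#' @return list with `delta`, `p`, `label` (one of neutral, additive,
#'   dominant, recessive, overdominant, underdominant), `best_mode` (the
#'   argmax one-parameter mode regardless of significance), `tie`.
#' @export
classify_mode <- function(fits, threshold = 0.05, df = 1) {
  stopifnot(threshold > 0, threshold < 1)
  if (inherits(fits, "mode_fits")) {
    ll0 <- fits$ll0
    ll_modes <- vapply(fits$fits[.mode_labels], `[[`, 0, "ll")
    s1_het <- fits$fits$het_diff$s1
  } else {
    ll0 <- fits$ll0
    ll_modes <- fits$ll_modes[.mode_labels]
    s1_het <- fits$s1_het
  }
  delta <- delta_statistic(ll0, ll_modes)
  p <- pchisq(delta, df = df, lower.tail = FALSE)
  best_i <- which(ll_modes == max(ll_modes))
  tie <- length(best_i) > 1L
  best_mode <- .mode_labels[min(best_i)]
  label <- if (p >= threshold) "neutral"
           else if (best_mode != "het_diff") best_mode
           else if (s1_het > 0) "overdominant"
           else if (s1_het < 0) "underdominant"
           else "neutral"
  list(delta = delta, p = p, label = label, best_mode = best_mode, tie = tie)
}

#' Rank-based ROC AUC
#'
#' Probability that the statistic of a randomly chosen selected replicate
#' exceeds that of a randomly chosen neutral replicate, with ties counted
#' as one half (the Mann-Whitney estimator).  Invariant under strictly
#' monotone transforms of the statistic.
#'
#' @param neutral_stats statistics for replicates simulated under the null.
#' @param selected_stats statistics for replicates simulated under
#'   selection.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(neutral_stats, selected_stats) {
  n0 <- length(neutral_stats); n1 <- length(selected_stats)
  if (n0 == 0 || n1 == 0) stop("both input vectors must be nonempty")
  r <- rank(c(selected_stats, neutral_stats))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Row-normalized confusion matrix of selection-mode classification
#'
#' @param true_labels simulated mode per replicate.
#' @param inferred_labels inferred label per replicate.
#' @param levels label set defining row/column order.
#' @return square matrix; rows are simulated modes (normalized to sum to 1
#'   where the row has any replicates), columns inferred labels.
#' @export
confusion_matrix <- function(true_labels, inferred_labels,
                             levels = c("neutral", "additive", "dominant",
                                        "recessive", "overdominant",
                                        "underdominant")) {
  stopifnot(length(true_labels) == length(inferred_labels))
  tab <- table(factor(true_labels, levels = levels),
               factor(inferred_labels, levels = levels))
  m <- unclass(tab)
  rs <- rowSums(m)
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  m
}
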