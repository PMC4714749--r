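# Gaussian noise-channel model of classifier scores.
#
# A real-valued per-term prediction y is modelled as y = x + z with latent
# annotation x in {+1, -1} and zero-mean Gaussian noise z of per-term
# variance eta. Under equal priors the channel posterior has the logistic
# closed form p(x | y) = 1 / (1 + exp(-2 * y * x / eta)).

#' Numerical floor for channel variances
#'
#' A strictly zero variance turns the channel posterior into a hard 0/1 and
#' can annihilate whole message products; the floor keeps inference finite
#' while remaining effectively deterministic.
#' @export
eta_floor <- 1e-6

#' Posterior probability of a latent annotation given a score
#'
#' @param y Real-valued score(s).
#' @param x Latent annotation value, `+1` or `-1` (recyclable).
#' @param eta Channel noise variance(s), at least [eta_floor].
#' @return `1 / (1 + exp(-2 * y * x / eta))`, vectorised. For each `y` and
#'   `eta` the probabilities at `x = +1` and `x = -1` sum to one.
#' @export
channel_posterior <- function(y, x, eta) {
  if (!all(x %in% c(-1, 1))) stop("x must be +1 or -1")
  if (any(eta < eta_floor)) {
    stop("eta below eta_floor (", format(eta_floor), "); clamp variances first")
  }
  stats::plogis(2 * y * x / eta)
}

#' Estimate channel noise variance from positively annotated scores
#'
#' Unbiased estimator of the noise variance around the positive signal level:
#' `sum((y - 1)^2) / (L - 1)` over the `L` positive validation scores,
#' clamped below at [eta_floor]. An optional pooled mode also uses negative
#' scores (signal level -1) under the symmetric-channel assumption.
#'
#' @param pos_scores Scores of positively annotated validation samples.
#' @param neg_scores Optional scores of negatively annotated samples; when
#'   supplied, squared deviations `(y + 1)^2` are pooled into the estimate.
#' @param term Optional term id used in error messages.
#' @return Positive variance estimate.
#' @export
estimate_variance <- function(pos_scores, neg_scores = NULL, term = NULL) {
  dev2 <- (pos_scores - 1)^2
  if (!is.null(neg_scores)) dev2 <- c(dev2, (neg_scores + 1)^2)
  if (length(dev2) < 2) {
    stop("need at least 2 scores to estimate a variance",
         if (!is.null(term)) paste0(" for term ", term) else "")
  }
  max(sum(dev2) / (length(dev2) - 1), eta_floor)
}

#' Channel message for an observed score
#'
#' The message a probabilistic leaf factor sends to its latent variable:
#' the normalised pair of channel posteriors at `x = +1` and `x = -1`.
#'
#' @param y Real-valued score (scalar or vector).
#' @param eta Channel variance(s), at least [eta_floor].
#' @return For scalar `y`, a named numeric pair `c(pos, neg)` summing to 1;
#'   for vector `y`, a two-column matrix with columns `pos`, `neg`.
#' @export
leaf_message <- function(y, eta) {
  p <- channel_posterior(y, +1, eta)
  out <- cbind(pos = p, neg = 1 - p)
  if (length(y) == 1) out[1, ] else out
}
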