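# Loss functions: cross-entropy grading loss, binary cross-entropy quality
# loss, and their weighted combination L_total = L_cls + lambda * L_q.

BCE_EPS <- 1e-7

#' Mean cross-entropy classification loss
#'
#' @param probs `n x K` matrix of predicted class probabilities.
#' @param grades Integer true grades in `0..K-1`.
#' @return Mean negative log-probability of the true class.
#' @export
cross_entropy_loss <- function(probs, grades) {
  n <- nrow(probs)
  stopifnot(length(grades) == n)
  p <- probs[cbind(seq_len(n), grades + 1L)]
  -mean(log(pmax(p, BCE_EPS)))
}

#' Mean binary cross-entropy quality loss
#'
#' `L_q = mean( -q log(q_hat) - (1-q) log(1-q_hat) )`, with predictions
#' clamped to `[eps, 1-eps]`, `eps = 1e-7`.
#'
#' @param q_hat Predicted quality scores in (0,1).
#' @param q Binary quality targets (0 or 1).
#' @return Non-negative mean BCE.
#' @export
quality_loss <- function(q_hat, q) {
  if (!all(q %in% c(0, 1))) stopf("quality targets must be binary (0 or 1)")
  qh <- pmin(pmax(q_hat, BCE_EPS), 1 - BCE_EPS)
  mean(-q * log(qh) - (1 - q) * log(1 - qh))
}

#' Combined training objective
#'
#' `L_total = L_cls + lambda * L_q`.
#'
#' @param l_cls Classification loss.
#' @param l_q Quality-assessment loss.
#' @param lambda Non-negative quality-loss weight (default 0.1).
#' @return The weighted sum.
#' @export
total_loss <- function(l_cls, l_q, lambda = 0.1) {
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    stopf("lambda must be a single non-negative value")
  }
  l_cls + lambda * l_q
}

#' Binary quality targets from prediction correctness
#'
#' The ground-truth quality `q` is defined as prediction correctness:
#' `q_i = 1` when the arg-max predicted grade (ties broken by the lowest
#' class index) equals the true grade, else 0.  No gradient flows through
#' this target.  Users with real image-quality labels can substitute them
#' by passing their own `q` to [quality_loss()].
#'
#' @param probs `n x K` matrix of predicted probabilities.
#' @param grades Integer true grades in `0..K-1`.
#' @return Integer vector of 0/1 targets.
#' @export
derive_quality_targets <- function(probs, grades) {
  as.integer(argmax_row(probs) - 1L == grades)
}
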