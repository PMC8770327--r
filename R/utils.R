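# internal numeric helpers

#' Round half away from zero
#'
#' Commercial rounding used when reproducing printed table values
#' (e.g. 8581.5 -> 8582), as opposed to the round-half-to-even rule of
#' [base::round()].
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Weighted empirical quantiles
#'
#' Inverse-CDF quantiles of a sample carrying frequency (survey) weights:
#' the smallest observation whose cumulative normalized weight reaches the
#' requested probability.
#'
#' @param x numeric sample
#' @param w non-negative weights, recycled to `length(x)`; `NULL` for equal
#' @param probs probabilities in \[0, 1\]
#' @return numeric vector of quantiles, named by probability
#' @export
weighted_quantile <- function(x, w = NULL, probs = c(0.5, 0.75, 0.95)) {
  stopifnot(all(probs >= 0 & probs <= 1))
  if (is.null(w)) w <- rep(1, length(x))
  w <- rep_len(w, length(x))
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(stats::setNames(rep(NA_real_, length(probs)), probs))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  out <- vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
  stats::setNames(out, probs)
}

weighted_mean <- function(x, w = NULL) {
  if (is.null(w)) return(mean(x))
  sum(w * x) / sum(w)
}

# Gauss-Hermite nodes/weights rescaled for E[g(Z)], Z ~ N(0, 1):
# E[g(Z)] ~= sum(w * g(z)).
gh_rule <- function(n = 21) {
  g <- pracma::gaussHermite(n)
  list(z = sqrt(2) * g$x, w = g$w / sqrt(pi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
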