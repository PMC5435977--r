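# Standardization and lambda-grid machinery.

#' Soft-thresholding operator
#'
#' The proximal operator of the absolute value, the elementary kernel of
#' coordinate descent for L1 penalties:
#' `sign(z) * max(|z| - gamma, 0)`.
#'
#' @param z numeric vector.
#' @param gamma nonnegative threshold.
#' @return Shrunken vector of the same length.
#' @examples
#' soft_threshold(0.7, 0.2)   # 0.5
#' soft_threshold(-0.3, 0.5)  # 0
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) stop("gamma must be nonnegative")
  sign(z) * pmax(abs(z) - gamma, 0)
}

# Center/scale columns with divisor-n variance. Zero-variance columns are
# reported so callers can exclude them from penalized fitting.
standardize_x <- function(x) {
  n <- nrow(x)
  center <- colMeans(x)
  xs <- sweep(x, 2L, center, "-")
  scale <- sqrt(colMeans(xs^2))
  zero <- scale < 1e-12
  scale[zero] <- 1
  xs <- sweep(xs, 2L, scale, "/")
  list(xs = xs, center = center, scale = scale, zero = zero)
}

# Gradient of the (1/n-scaled) unpenalized loss at the null model
# (intercept-only for gaussian/binomial, beta = 0 for cox), per column of
# the standardized design.
null_gradient <- function(xs, out) {
  n <- nrow(xs)
  r <- switch(out$family,
    gaussian = out$y - mean(out$y),
    binomial = out$y - mean(out$y),
    cox = cox_null_residuals(out$time, out$status))
  drop(crossprod(xs, r)) / n
}

#' Smallest penalty giving the all-zero solution
#'
#' Computes the grid anchor `lambda_max`: the smallest `lambda` at which the
#' weighted-L1 penalized fit has every penalized coefficient equal to zero.
#' It equals `max_j |g_j| / w_j`, where `g_j` is the null-model gradient of
#' the unpenalized loss for (standardized) column `j` and `w_j` the
#' per-feature penalty weight.
#'
#' @param x predictor matrix (samples x features); standardized internally.
#' @param y outcome (see [ipflasso()]).
#' @param family one of `"gaussian"`, `"binomial"`, `"cox"`.
#' @param penalty.weights optional positive per-feature weights (default 1).
#' @return A positive scalar.
#' @export
lambda_max <- function(x, y, family = c("gaussian", "binomial", "cox"),
                       penalty.weights = NULL) {
  family <- match.arg(family)
  x <- as.matrix(x)
  out <- prepare_outcome(y, family, nrow(x))
  std <- standardize_x(x)
  if (is.null(penalty.weights)) penalty.weights <- rep(1, ncol(x))
  if (any(penalty.weights <= 0)) stop("penalty weights must be positive")
  g <- null_gradient(std$xs, out)
  g[std$zero] <- 0
  max(abs(g) / penalty.weights)
}

# log-spaced grid from lmax down to ratio*lmax
default_lambda_grid <- function(lmax, nlambda, ratio) {
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}
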