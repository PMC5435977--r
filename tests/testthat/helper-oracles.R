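# Independent oracles used across the test files: standardization helpers,
# loss/gradient computations per family, a generic proximal-gradient
# minimizer (ISTA with backtracking) for weighted-L1 and sparse-group
# objectives, and optimality-certificate checks. These share no code with
# the package solver.

std_cols <- function(x) {
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sc <- sqrt(colMeans(xc^2))
  list(xs = sweep(xc, 2L, sc, "/"), center = ctr, scale = sc)
}

# per-subject gradient of the Breslow log partial likelihood wrt eta
oracle_cox_grad_eta <- function(eta, time, status) {
  ee <- exp(eta)
  ev <- sort(unique(time[status == 1]))
  s0 <- vapply(ev, function(t) sum(ee[time >= t]), 1)
  d <- vapply(ev, function(t) sum(time == t & status == 1), 1)
  cum <- vapply(seq_along(time), function(i)
    sum((d / s0)[ev <= time[i]]), 1)
  status - ee * cum
}

oracle_cox_negll <- function(eta, time, status) {
  ev <- sort(unique(time[status == 1]))
  ll <- 0
  for (t in ev) {
    dset <- time == t & status == 1
    ll <- ll + sum(eta[dset]) - sum(dset) * log(sum(exp(eta[time >= t])))
  }
  -ll
}

# (1/n)-scaled loss and its gradient wrt standardized-scale coefficients.
# out: list(family, y | time+status); b0 is the standardized-scale
# intercept (ignored for cox).
oracle_loss <- function(xs, out, bs, b0) {
  n <- nrow(xs)
  eta <- drop(xs %*% bs) + if (out$family == "cox") 0 else b0
  switch(out$family,
    gaussian = sum((out$y - eta)^2) / (2 * n),
    binomial = sum(log1p(exp(eta)) - out$y * eta) / n,
    cox = oracle_cox_negll(eta, out$time, out$status) / n)
}

oracle_grad <- function(xs, out, bs, b0) {
  n <- nrow(xs)
  eta <- drop(xs %*% bs) + if (out$family == "cox") 0 else b0
  r <- switch(out$family,
    gaussian = eta - out$y,
    binomial = 1 / (1 + exp(-eta)) - out$y,
    cox = -oracle_cox_grad_eta(eta, out$time, out$status))
  list(g = drop(crossprod(xs, r)) / n, g0 = sum(r) / n)
}

# Generic proximal-gradient (ISTA, backtracking) minimizer of
#   loss + lambda * sum_j w_j |beta_j|            (blocks = NULL), or
#   loss + sgl penalty (alpha, sqrt(p_m) group weights)  (blocks given)
# on the standardized scale, unpenalized intercept for gaussian/binomial.
# Intentionally plain and slow; the independent check for the solvers.
oracle_prox_fit <- function(xs, out, lambda, w = NULL, blocks = NULL,
                            alpha = NULL, maxiter = 50000, tol = 1e-11) {
  p <- ncol(xs)
  bs <- rep(0, p)
  b0 <- if (out$family == "binomial") {
    pbar <- mean(out$y)
    log(pbar / (1 - pbar))
  } else if (out$family == "gaussian") mean(out$y) else 0
  step <- 1
  f <- oracle_loss(xs, out, bs, b0)
  for (it in seq_len(maxiter)) {
    gr <- oracle_grad(xs, out, bs, b0)
    repeat {
      if (is.null(blocks)) {
        cand <- soft_threshold(bs - step * gr$g, step * lambda * w)
      } else {
        cand <- soft_threshold(bs - step * gr$g, step * lambda * alpha)
        for (b in blocks) {
          nb <- sqrt(sum(cand[b]^2))
          thr <- step * lambda * (1 - alpha) * sqrt(length(b))
          cand[b] <- if (nb <= thr) 0 else cand[b] * (1 - thr / nb)
        }
      }
      c0 <- if (out$family == "cox") 0 else b0 - step * gr$g0
      fnew <- oracle_loss(xs, out, cand, c0)
      d <- cand - bs
      d0 <- c0 - b0
      q <- f + sum(gr$g * d) + gr$g0 * d0 +
        (sum(d^2) + d0^2) / (2 * step)
      if (fnew <= q + 1e-14) break
      step <- step / 2
    }
    delta <- max(abs(cand - bs), abs(c0 - b0))
    bs <- cand
    b0 <- c0
    f <- fnew
    if (delta < tol) break
  }
  list(beta = bs, b0 = b0, iterations = it)
}

# Max KKT (subgradient) violation of a fitted ipflasso object at one grid
# index, evaluated on the standardized scale.
kkt_violation <- function(fit, x, y, index) {
  out <- ipfreg:::prepare_outcome(y, fit$family, nrow(x))
  if (out$family == "gaussian") out$y <- out$y - mean(out$y)
  s <- std_cols(x)
  bs <- fit$beta[, index] * s$scale
  b0 <- if (!is.null(fit$a0))
    fit$a0[index] + sum(fit$center * fit$beta[, index]) else 0
  g <- oracle_grad(s$xs, out, bs, b0)$g
  lam <- fit$lambda[index]
  w <- ipfreg:::pf_weights(fit$blocks, fit$penalty.factors, ncol(x))
  nz <- bs != 0
  max(c(pmax(abs(g[!nz]) - lam * w[!nz], 0),
        abs(g[nz] + lam * w[nz] * sign(bs[nz]))))
}

# SGL block-optimality certificate: returns max violation across blocks.
sgl_certificate <- function(fit, x, y, index) {
  out <- ipfreg:::prepare_outcome(y, fit$family, nrow(x))
  if (out$family == "gaussian") out$y <- out$y - mean(out$y)
  s <- std_cols(x)
  bs <- fit$beta[, index] * s$scale
  b0 <- fit$a0[index] + sum(fit$center * fit$beta[, index])
  g <- oracle_grad(s$xs, out, bs, b0)$g
  lam <- fit$lambda[index]
  a <- fit$alpha
  viol <- 0
  for (b in fit$blocks) {
    pm <- length(b)
    gb <- g[b]
    bb <- bs[b]
    if (all(bb == 0)) {
      v <- sqrt(sum(soft_threshold(gb, a * lam)^2)) -
        (1 - a) * lam * sqrt(pm)
      viol <- max(viol, v)
    } else {
      nb <- sqrt(sum(bb^2))
      nz <- bb != 0
      viol <- max(viol,
                  abs(gb[nz] + a * lam * sign(bb[nz]) +
                        (1 - a) * lam * sqrt(pm) * bb[nz] / nb),
                  pmax(abs(gb[!nz]) - a * lam, 0))
    }
  }
  viol
}

# small random regression instances for property loops
random_instance <- function(family, n, p, seed, snr = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  beta <- c(rnorm(max(2, p %/% 5)), rep(0, p - max(2, p %/% 5))) * snr
  eta <- drop(x %*% beta)
  y <- switch(family,
    gaussian = eta + rnorm(n),
    binomial = rbinom(n, 1, 1 / (1 + exp(-eta))),
    cox = cbind(rexp(n, exp(eta - mean(eta))), rbinom(n, 1, 0.7)))
  if (family == "binomial" && length(unique(y)) < 2) y[1:2] <- c(0, 1)
  if (family == "cox" && sum(y[, 2]) == 0) y[1, 2] <- 1
  list(x = x, y = y)
}
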