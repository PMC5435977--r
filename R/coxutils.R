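# Cox model utilities: Breslow partial likelihood and baseline hazard.

#' Breslow partial log-likelihood
#'
#' The log partial likelihood of a Cox model at given linear predictors,
#' with Breslow's approximation for tied event times:
#' \deqn{\ell = \sum_k \Big( \sum_{i \in D_k} \eta_i
#'   - d_k \log \sum_{i \in R_k} e^{\eta_i} \Big)}
#' over distinct event times `k` with event sets `D_k`, risk sets `R_k`, and
#' tie counts `d_k`. Unscaled (no `1/n`).
#'
#' @param eta linear predictors.
#' @param time,status survival outcome (status 1 = event).
#' @return Scalar log partial likelihood.
#' @export
cox_pl <- function(eta, time, status) {
  ev <- sort(unique(time[status == 1]))
  ll <- 0
  for (t in ev) {
    dset <- time == t & status == 1
    rset <- time >= t
    m <- max(eta[rset])
    ll <- ll + sum(eta[dset]) -
      sum(dset) * (m + log(sum(exp(eta[rset] - m))))
  }
  ll
}

# Breslow cumulative baseline hazard from training data:
# H0(t) = sum_{event times t_k <= t} d_k / sum_{i in R_k} exp(eta_i).
# Returns a step function representation (times, cumhaz).
breslow_basehaz <- function(eta, time, status) {
  ev <- sort(unique(time[status == 1]))
  inc <- vapply(ev, function(t) {
    sum(time == t & status == 1) / sum(exp(eta[time >= t]))
  }, 1)
  list(time = ev, cumhaz = cumsum(inc))
}

# Evaluate per-subject survival probabilities S_i(t) = exp(-H0(t) e^{eta_i})
# at the given times; rows subjects, columns times.
breslow_survival <- function(bh, eta_new, times) {
  H0 <- vapply(times, function(t) {
    k <- sum(bh$time <= t)
    if (k > 0) bh$cumhaz[k] else 0
  }, 1)
  outer(exp(eta_new), H0, function(r, h) exp(-h * r))
}
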