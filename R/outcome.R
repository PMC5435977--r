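# Outcome preparation and validation shared by all fitting routines.
#
# gaussian: numeric vector
# binomial: 0/1 vector or 2-level factor, both classes present
# cox:      survival::Surv object or 2-column (time, status) matrix,
#           time > 0, status in {0,1}, at least one event

prepare_outcome <- function(y, family, n) {
  family <- match.arg(family, c("gaussian", "binomial", "cox"))
  if (family == "cox") {
    if (inherits(y, "Surv")) {
      ym <- unclass(y)
      time <- ym[, 1L]
      status <- ym[, 2L]
    } else if (is.matrix(y) && ncol(y) == 2L) {
      time <- y[, 1L]
      status <- y[, 2L]
    } else {
      stop("for family 'cox', y must be a Surv object or a ",
           "2-column (time, status) matrix")
    }
    if (length(time) != n) stop("outcome length does not match nrow(x)")
    if (anyNA(time) || anyNA(status)) stop("missing values in survival outcome")
    if (any(time <= 0)) stop("survival times must be positive")
    if (!all(status %in% c(0, 1)))
      stop("status must be 0 (censored) or 1 (event)")
    if (sum(status) < 1) stop("at least one event is required")
    return(list(family = family, time = as.numeric(time),
                status = as.integer(status)))
  }
  if (is.factor(y)) {
    if (family == "binomial" && nlevels(y) == 2L) {
      y <- as.numeric(y) - 1
    } else stop("factor outcome requires family 'binomial' with 2 levels")
  }
  y <- as.numeric(y)
  if (length(y) != n) stop("outcome length does not match nrow(x)")
  if (anyNA(y)) stop("missing values in outcome")
  if (family == "binomial") {
    if (!all(y %in% c(0, 1))) stop("binomial outcome must be 0/1")
    if (length(unique(y)) < 2L)
      stop("binomial outcome has a single class; cannot fit")
  }
  if (family == "gaussian" && sd(y) == 0)
    stop("gaussian outcome is constant; cannot fit")
  list(family = family, y = y)
}

# Breslow risk-set bookkeeping for the C++ Cox solver.
# Subjects are reordered by increasing time; returns 0-based indices of the
# first subject in each distinct event time's risk set, and event counts.
cox_risk_sets <- function(time, status) {
  ord <- order(time)
  time <- time[ord]
  status <- status[ord]
  ev_times <- unique(time[status == 1L])
  rstart <- vapply(ev_times, function(t) which.max(time >= t), 1L) - 1L
  devents <- vapply(ev_times, function(t) sum(time == t & status == 1L), 1L)
  list(order = ord, time = time, status = status,
       rstart = as.integer(rstart), devents = as.integer(devents),
       ev_times = ev_times)
}

# Martingale-type residuals of the null Cox model (beta = 0, Breslow):
# delta_i - sum_{event times t_k <= t_i} d_k / |risk set at t_k|.
cox_null_residuals <- function(time, status) {
  n <- length(time)
  res <- numeric(n)
  ev <- sort(unique(time[status == 1]))
  dk <- vapply(ev, function(t) sum(time == t & status == 1), 1)
  nk <- vapply(ev, function(t) sum(time >= t), 1)
  haz <- dk / nk
  cum <- cumsum(haz)
  for (i in seq_len(n)) {
    k <- sum(ev <= time[i])
    res[i] <- status[i] - if (k > 0) cum[k] else 0
  }
  res
}
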