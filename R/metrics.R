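# Performance metrics for cross-validation tuning and test-set evaluation.
# All metrics are pure functions of their inputs.

#' Mean squared error
#' @param pred,y numeric vectors of equal length.
#' @return Scalar MSE.
#' @export
mse <- function(pred, y) {
  if (length(pred) != length(y) || length(y) == 0L)
    stop("inputs must be nonempty and of equal length")
  mean((pred - y)^2)
}

#' Misclassification rate
#'
#' Fraction of samples whose predicted probability, thresholded at 0.5
#' (probabilities of exactly 0.5 are classed as 1), differs from the true
#' class.
#'
#' @param prob predicted probabilities in `[0,1]`.
#' @param y 0/1 vector.
#' @return Scalar in `[0,1]`.
#' @export
misclassification_rate <- function(prob, y) {
  if (length(prob) != length(y) || length(y) == 0L)
    stop("inputs must be nonempty and of equal length")
  mean((prob >= 0.5) != (y == 1))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the proportion of (case, control) pairs
#' in which the case scores higher, ties counting 1/2. Invariant to strictly
#' increasing transformations of the score.
#'
#' @param score real-valued predictions (higher = more likely class 1).
#' @param y 0/1 vector with both classes present.
#' @return Scalar in `[0,1]`.
#' @export
auc <- function(score, y) {
  if (length(score) != length(y) || length(y) == 0L)
    stop("inputs must be nonempty and of equal length")
  y <- as.numeric(y == 1)
  n1 <- sum(y)
  n0 <- length(y) - n1
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated Cox partial-likelihood contribution
#'
#' The held-out partial-likelihood criterion of Verweij and van
#' Houwelingen: the log partial likelihood of the full data (training plus
#' held-out fold) at the training-fit coefficients minus that of the
#' training data alone, \eqn{\ell_{full}(\hat\beta) -
#' \ell_{train}(\hat\beta)}. Summed over folds it gives the CV criterion
#' (to be maximized). When the held-out set equals the training set the
#' contribution is 0 by construction.
#'
#' @param eta_full linear predictors for the combined (training + fold) data.
#' @param time_full,status_full combined outcome.
#' @param eta_train,time_train,status_train training-only counterparts.
#' @return Scalar held-out log partial-likelihood contribution.
#' @export
cox_cvpl <- function(eta_full, time_full, status_full,
                     eta_train, time_train, status_train) {
  if (sum(status_full) == sum(status_train) &&
      length(time_full) > length(time_train)) {
    warning("held-out fold contains no events; contribution is the ",
            "risk-set adjustment only")
  }
  cox_pl(eta_full, time_full, status_full) -
    cox_pl(eta_train, time_train, status_train)
}

#' Time-dependent Brier score curve with IPCW
#'
#' Computes the time-dependent Brier score
#' \deqn{BS(t) = \frac{1}{n}\sum_i w_i(t)\,(1\{T_i > t\} - \hat S_i(t))^2}
#' with inverse-probability-of-censoring weights (Graf et al.):
#' \eqn{w_i(t) = 1\{T_i \le t, \delta_i = 1\}/\hat G(T_i^-) +
#' 1\{T_i > t\}/\hat G(t)}, where \eqn{\hat G} is the Kaplan-Meier estimate
#' of the censoring distribution. Subjects censored before `t` get weight 0.
#'
#' @param surv_pred matrix of predicted survival probabilities, samples in
#'   rows, `eval_times` in columns.
#' @param time,status observed outcome for the evaluated samples.
#' @param eval_times increasing evaluation times.
#' @param cens_km optional censoring Kaplan-Meier (a `survival::survfit`
#'   object on `Surv(time, 1 - status)`), typically estimated on training
#'   data; estimated from `time`/`status` if missing.
#' @return Object of class `"brier_curve"`: list with `eval_times`, `scores`
#'   and `horizon`. Times where the censoring survival reaches 0 are
#'   dropped with a warning (truncated horizon).
#' @export
brier_curve <- function(surv_pred, time, status, eval_times,
                        cens_km = NULL) {
  surv_pred <- as.matrix(surv_pred)
  n <- length(time)
  if (nrow(surv_pred) != n || ncol(surv_pred) != length(eval_times))
    stop("surv_pred must be n x length(eval_times)")
  if (is.null(cens_km))
    cens_km <- survival::survfit(
      survival::Surv(time, 1 - status) ~ 1)
  G <- function(t) {  # censoring survival G(t), right-continuous
    s <- summary(cens_km, times = t, extend = TRUE)$surv
    s
  }
  Gminus <- function(t) {  # G(t-): left limit
    vapply(t, function(ti) {
      k <- cens_km$time < ti
      if (!any(k)) 1 else min(cens_km$surv[k])
    }, 1)
  }
  Gt <- G(eval_times)
  Gi_minus <- Gminus(time)
  keep <- Gt > 0
  if (!all(keep)) {
    warning("censoring survival reaches 0 before some evaluation times; ",
            "horizon truncated to ", max(eval_times[keep]))
    eval_times <- eval_times[keep]
    Gt <- Gt[keep]
    surv_pred <- surv_pred[, keep, drop = FALSE]
  }
  scores <- vapply(seq_along(eval_times), function(k) {
    t <- eval_times[k]
    event_before <- time <= t & status == 1
    at_risk <- time > t
    w <- numeric(n)
    w[event_before] <- 1 / Gi_minus[event_before]
    w[at_risk] <- 1 / Gt[k]
    ind <- as.numeric(time > t)
    sum(w * (ind - surv_pred[, k])^2) / n
  }, 1)
  structure(list(eval_times = eval_times, scores = scores,
                 horizon = max(eval_times)),
            class = "brier_curve")
}

#' Integrated Brier score
#'
#' Trapezoidal integral of the Brier curve over `[0, horizon]`, divided by
#' the horizon, summarizing a prediction-error curve into a single index.
#'
#' @details The integral is computed by the trapezoid rule over
#'   `c(0, eval_times)`, with the score at time 0 taken equal to the score
#'   at the first evaluation time (the Brier score is flat before the first
#'   event), then divided by the horizon.
#'
#' @param curve a `"brier_curve"` object (or a list with `eval_times`,
#'   `scores`, `horizon`).
#' @return Scalar integrated Brier score.
#' @export
integrated_brier <- function(curve) {
  t <- curve$eval_times
  s <- curve$scores
  if (length(t) < 2L) stop("need at least 2 evaluation times")
  t <- c(0, t)
  s <- c(s[1L], s)
  sum(diff(t) * (utils::head(s, -1) + utils::tail(s, -1)) / 2) /
    curve$horizon
}

#' @export
print.brier_curve <- function(x, ...) {
  cat("Time-dependent Brier score at", length(x$eval_times),
      "times up to", format(x$horizon, digits = 4), "\n")
  cat("  IBS =", format(integrated_brier(x), digits = 4), "\n")
  invisible(x)
}
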