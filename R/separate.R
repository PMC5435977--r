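# Method "S": one cross-validated standard lasso per modality, combined
# through a low-dimensional regression on the modality linear predictors.

#' Separate per-modality lasso models with a combining regression
#'
#' Fits a cross-validated standard lasso to each modality's columns alone,
#' computes each modality's in-sample linear predictor, and combines the
#' `M` predictors in an unpenalized low-dimensional model: logistic
#' regression for binomial outcomes, linear regression for gaussian, Cox
#' regression for survival. A modality whose cross-validated model is empty
#' contributes a constant predictor and is dropped from the combiner; if
#' all modalities are empty the combiner is the null (intercept-only)
#' model.
#'
#' The combiner is trained on in-sample linear predictors (not
#' cross-validated ones), a known source of optimism in its weights.
#'
#' @inheritParams cv.ipflasso
#' @param ... further arguments to [cv.ipflasso()] (e.g. `nlambda`, `tol`).
#' @return Object of class `"separate_lasso"`: per-modality `"cv.ipflasso"`
#'   fits, the combiner model, and bookkeeping. `nzero` gives the total
#'   selected-variable count (sum over modalities).
#' @export
separate_lasso <- function(x, y, blocks,
                           family = c("gaussian", "binomial", "cox"),
                           nfolds = 5L, ncv = 10L, folds = NULL,
                           type.measure = NULL, seed = NULL, ...) {
  family <- match.arg(family)
  x <- as.matrix(x)
  n <- nrow(x)
  blocks <- check_blocks(blocks, ncol(x))
  out <- prepare_outcome(y, family, n)
  if (is.null(folds)) {
    strata <- if (family == "binomial") out$y else NULL
    folds <- make_folds(n, nfolds, ncv, seed = seed, strata = strata)
  }
  fits <- vector("list", length(blocks))
  lp <- matrix(0, n, length(blocks))
  for (m in seq_along(blocks)) {
    xm <- x[, blocks[[m]], drop = FALSE]
    fits[[m]] <- cv.ipflasso(xm, y, blocks = list(seq_len(ncol(xm))),
                             family = family, folds = folds,
                             type.measure = type.measure, ...)
    lp[, m] <- drop(predict(fits[[m]], xm, type = "link"))
  }
  nzero <- vapply(fits, function(f) f$nzero.opt, 1)
  active <- nzero > 0
  df <- as.data.frame(lp)
  names(df) <- paste0("lp", seq_along(blocks))
  form <- if (any(active))
    paste("~", paste(names(df)[active], collapse = " + "))
  else "~ 1"
  combiner <- switch(family,
    gaussian = lm(stats::as.formula(paste("y", form)),
                  data = cbind(df, y = out$y)),
    binomial = glm(stats::as.formula(paste("y", form)),
                   data = cbind(df, y = out$y), family = binomial()),
    cox = survival::coxph(
      stats::as.formula(paste("survival::Surv(time, status)", form)),
      data = cbind(df, time = out$time, status = out$status)))
  structure(list(call = match.call(), family = family, blocks = blocks,
                 fits = fits, combiner = combiner, active = active,
                 lp.train = lp, nzero = sum(nzero),
                 nzero.by.block = nzero),
            class = "separate_lasso")
}

#' @export
print.separate_lasso <- function(x, ...) {
  cat("Separate per-modality lasso models (", x$family, ")\n", sep = "")
  cat("  selected variables by modality: ",
      paste(x$nzero.by.block, collapse = ", "),
      "  (total ", x$nzero, ")\n", sep = "")
  cat("  combiner: ", if (any(x$active))
    paste(sum(x$active), "modality predictor(s)") else
      "intercept-only (all modality models empty)", "\n", sep = "")
  invisible(x)
}

#' Predict from a separate-models fit
#'
#' Applies each modality's cross-validated lasso to its columns of `newx`,
#' then the combining regression.
#'
#' @param object a `"separate_lasso"` fit.
#' @param newx new predictor matrix (all modalities' columns).
#' @param type `"link"` or `"response"` (probabilities for binomial,
#'   relative hazard for cox).
#' @param ... unused.
#' @export
predict.separate_lasso <- function(object, newx,
                                   type = c("link", "response"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  lp <- vapply(seq_along(object$blocks), function(m)
    drop(predict(object$fits[[m]],
                 newx[, object$blocks[[m]], drop = FALSE],
                 type = "link")),
    numeric(nrow(newx)))
  df <- as.data.frame(matrix(lp, nrow = nrow(newx)))
  names(df) <- paste0("lp", seq_along(object$blocks))
  eta <- switch(object$family,
    gaussian = predict(object$combiner, newdata = df),
    binomial = predict(object$combiner, newdata = df, type = "link"),
    cox = if (any(object$active))
      predict(object$combiner, newdata = df, type = "lp")
    else rep(0, nrow(df)))
  eta <- as.numeric(eta)
  if (type == "link") return(eta)
  switch(object$family,
         gaussian = eta,
         binomial = 1 / (1 + exp(-eta)),
         cox = exp(eta))
}
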