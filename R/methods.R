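# S3 methods for the "ipflasso" path object.

#' @export
print.ipflasso <- function(x, ...) {
  cat("Block-weighted L1 path (", x$family, ")\n", sep = "")
  cat("  ", length(x$blocks), " block(s), sizes: ",
      paste(vapply(x$blocks, length, 1L), collapse = ", "), "\n", sep = "")
  cat("  penalty factors: ",
      paste(format(x$penalty.factors, digits = 4), collapse = ", "),
      "\n", sep = "")
  cat("  lambda grid: ", length(x$lambda), " values in [",
      format(min(x$lambda), digits = 4), ", ",
      format(max(x$lambda), digits = 4), "]\n", sep = "")
  cat("  nonzero coefficients: ", x$df[1L], " (largest lambda) to ",
      x$df[length(x$df)], " (smallest)\n", sep = "")
  invisible(x)
}

#' Coefficients along an L1 path
#'
#' @param object an `"ipflasso"` fit.
#' @param s lambda value(s) at which to report coefficients (nearest grid
#'   point); default the whole grid.
#' @param index grid index (alternative to `s`).
#' @param ... unused.
#' @return Coefficient matrix with an `(Intercept)` row for gaussian and
#'   binomial families.
#' @export
coef.ipflasso <- function(object, s = NULL, index = NULL, ...) {
  idx <- lambda_index(object$lambda, s, index)
  b <- object$beta[, idx, drop = FALSE]
  if (!is.null(object$a0))
    b <- rbind(`(Intercept)` = object$a0[idx], b)
  colnames(b) <- format(object$lambda[idx], digits = 5)
  b
}

lambda_index <- function(lambda, s = NULL, index = NULL) {
  if (!is.null(index)) {
    index <- as.integer(index)
    if (any(index < 1L | index > length(lambda)))
      stop("lambda index out of range")
    return(index)
  }
  if (is.null(s)) return(seq_along(lambda))
  vapply(s, function(si) which.min(abs(lambda - si)), 1L)
}

#' Predict from a block-weighted L1 path
#'
#' @param object an `"ipflasso"` fit.
#' @param newx matrix of new samples with the training column layout, on the
#'   original (un-rescaled) scale.
#' @param s,index lambda selection as in [coef.ipflasso()].
#' @param type `"link"` (linear predictor), `"response"` (fitted values;
#'   probabilities for binomial, relative hazard for cox), `"class"`
#'   (binomial, threshold 0.5), or `"survival"` (cox: per-subject survival
#'   probabilities from the Breslow baseline hazard; requires `times` and a
#'   single lambda).
#' @param times evaluation times for `type = "survival"`.
#' @param ... unused.
#' @return Matrix of predictions (samples x selected lambdas), or for
#'   `type = "survival"` a samples x times matrix.
#' @export
predict.ipflasso <- function(object, newx, s = NULL, index = NULL,
                             type = c("link", "response", "class",
                                      "survival"),
                             times = NULL, ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (ncol(newx) != nrow(object$beta))
    stop("newx has ", ncol(newx), " columns but the fit has ",
         nrow(object$beta), " features")
  idx <- lambda_index(object$lambda, s, index)
  if (type == "survival") {
    if (object$family != "cox") stop("type 'survival' requires a cox fit")
    if (is.null(times)) stop("type 'survival' requires 'times'")
    if (length(idx) != 1L)
      stop("type 'survival' requires a single lambda (use 's' or 'index')")
    eta_new <- drop(sweep(newx, 2L, object$center, "-") %*%
                      object$beta[, idx])
    bh <- breslow_basehaz(object$cox$linpred[, idx],
                          object$cox$time, object$cox$status)
    return(breslow_survival(bh, eta_new, times))
  }
  eta <- newx %*% object$beta[, idx, drop = FALSE]
  if (!is.null(object$a0))
    eta <- sweep(eta, 2L, object$a0[idx], "+")
  switch(type,
    link = eta,
    response = switch(object$family,
      gaussian = eta,
      binomial = 1 / (1 + exp(-eta)),
      cox = exp(eta)),
    class = {
      if (object$family != "binomial")
        stop("type 'class' requires a binomial fit")
      (1 / (1 + exp(-eta)) >= 0.5) * 1
    })
}

#' @export
summary.ipflasso <- function(object, ...) {
  out <- data.frame(lambda = object$lambda, df = object$df,
                    t(object$df.block))
  names(out)[-(1:2)] <- paste0("df.", names(object$blocks))
  structure(list(family = object$family,
                 penalty.factors = object$penalty.factors,
                 path = out), class = "summary.ipflasso")
}

#' @export
print.summary.ipflasso <- function(x, ...) {
  cat("family:", x$family, " penalty factors:",
      paste(format(x$penalty.factors, digits = 4), collapse = ", "), "\n")
  print(utils::head(x$path, 10))
  if (nrow(x$path) > 10) cat("... (", nrow(x$path), " grid points)\n")
  invisible(x)
}

#' Coefficient profile plot
#'
#' Plots coefficient paths against `log(lambda)`, colored by block.
#'
#' @param x an `"ipflasso"` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ipflasso <- function(x, ...) {
  M <- length(x$blocks)
  colr <- rep(NA_integer_, nrow(x$beta))
  for (m in seq_len(M)) colr[x$blocks[[m]]] <- m
  graphics::matplot(log(x$lambda), t(x$beta), type = "l", lty = 1,
                    col = colr, xlab = expression(log(lambda[1])),
                    ylab = "coefficient", ...)
  graphics::legend("topleft", legend = names(x$blocks), col = seq_len(M),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Nonzero coefficient counts
#'
#' @param fit an `"ipflasso"` fit.
#' @param index optional grid indices.
#' @return Named list with total and per-block nonzero counts.
#' @export
nonzero <- function(fit, index = NULL) {
  if (is.null(index)) index <- seq_along(fit$lambda)
  list(total = fit$df[index],
       by.block = fit$df.block[, index, drop = FALSE])
}
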