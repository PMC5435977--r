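# Repeated k-fold cross-validation: lambda tuning at fixed penalty factors,
# and the outer search over candidate penalty-factor vectors.

#' Build a repeated k-fold plan
#'
#' Deterministic given `seed`; fold sizes within each repeat differ by at
#' most one. When `strata` is supplied (e.g. a 0/1 outcome), assignment is
#' stratified so every fold receives a near-proportional share of each
#' stratum while keeping global fold sizes balanced.
#'
#' @param n number of samples.
#' @param k folds per repeat (`2 <= k <= n`).
#' @param repeats number of independent repeats.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param strata optional vector of stratum labels of length `n`.
#' @return Object of class `"fold_plan"`: list with `k`, `repeats`, `seed`,
#'   and `assignments`, a `repeats x n` matrix of fold labels in `1..k`.
#' @export
make_folds <- function(n, k = 5L, repeats = 1L, seed = NULL, strata = NULL) {
  k <- as.integer(k)
  if (k < 2L || k > n) stop("'k' must satisfy 2 <= k <= n")
  if (!is.null(strata) && length(strata) != n)
    stop("'strata' must have length n")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  assignments <- matrix(0L, repeats, n)
  for (r in seq_len(repeats)) {
    # one balanced label sequence per repeat, fold order shuffled
    fold_seq <- rep(sample.int(k), length.out = n)
    lab <- integer(n)
    if (is.null(strata)) {
      lab <- sample(fold_seq)
    } else {
      pos <- 1L
      for (s in unique(strata)) {
        idx <- which(strata == s)
        chunk <- fold_seq[seq(pos, length.out = length(idx))]
        lab[idx] <- sample(chunk)
        pos <- pos + length(idx)
      }
    }
    assignments[r, ] <- lab
  }
  structure(list(k = k, repeats = as.integer(repeats), seed = seed,
                 assignments = assignments),
            class = "fold_plan")
}

measure_direction <- function(type.measure) {
  switch(type.measure,
         mse = "min", class = "min", auc = "max", cvpl = "max",
         stop("unknown type.measure: ", type.measure))
}

default_measure <- function(family) {
  switch(family, gaussian = "mse", binomial = "class", cox = "cvpl")
}

# Evaluate one candidate penalty-factor vector: full-data path (defining the
# grid), then repeated-CV mean/sd of the metric per lambda.
cv_one_candidate <- function(x, out, blocks, pf, folds, type.measure,
                             nlambda, lambda.min.ratio, tol, maxit) {
  family <- out$family
  yfit <- switch(family, cox = cbind(out$time, out$status), out$y)
  full <- ipflasso(x, yfit, blocks = blocks, family = family,
                   penalty.factors = pf, nlambda = nlambda,
                   lambda.min.ratio = lambda.min.ratio,
                   tol = tol, maxit = maxit)
  grid <- full$lambda
  nlam <- length(grid)
  vals <- matrix(NA_real_, folds$repeats * folds$k, nlam)
  row <- 0L
  skipped <- 0L
  for (r in seq_len(folds$repeats)) {
    for (f in seq_len(folds$k)) {
      row <- row + 1L
      test <- folds$assignments[r, ] == f
      train <- !test
      # degenerate training part?
      bad <- switch(family,
        binomial = length(unique(out$y[train])) < 2L,
        cox = sum(out$status[train]) < 1L,
        gaussian = sd(out$y[train]) == 0)
      if (bad ||
          (family == "binomial" && type.measure == "auc" &&
           length(unique(out$y[test])) < 2L)) {
        skipped <- skipped + 1L
        warning("skipping degenerate fold ", f, " of repeat ", r)
        next
      }
      ytr <- switch(family,
                    cox = cbind(out$time[train], out$status[train]),
                    out$y[train])
      # columns constant within a training fold are handled inside the
      # fitter; its warning would fire once per fold, so muffle here
      fitf <- suppressWarnings(
        ipflasso(x[train, , drop = FALSE], ytr, blocks = blocks,
                 family = family, penalty.factors = pf, lambda = grid,
                 tol = tol, maxit = maxit))
      vals[row, ] <- fold_measure(fitf, x, out, train, test, type.measure)
    }
  }
  if (skipped == folds$repeats * folds$k)
    stop("all CV folds were degenerate; cannot cross-validate")
  cvm <- colMeans(vals, na.rm = TRUE)
  cvsd <- apply(vals, 2L, sd, na.rm = TRUE)
  list(fit = full, lambda = grid, cvm = cvm, cvsd = cvsd,
       nzero = full$df, skipped = skipped)
}

fold_measure <- function(fitf, x, out, train, test, type.measure) {
  xte <- x[test, , drop = FALSE]
  if (out$family == "cox") {
    # Verweij-van Houwelingen held-out partial likelihood per lambda
    comb <- train | test  # all samples
    eta_all <- x %*% fitf$beta
    vapply(seq_along(fitf$lambda), function(l) {
      cox_cvpl(eta_all[comb, l], out$time[comb], out$status[comb],
               eta_all[train, l], out$time[train], out$status[train])
    }, 1)
  } else {
    pred <- predict(fitf, xte,
                    type = if (out$family == "binomial") "response"
                           else "link")
    yte <- out$y[test]
    switch(type.measure,
      mse = colMeans((pred - yte)^2),
      class = apply(pred, 2L, misclassification_rate, y = yte),
      auc = apply(pred, 2L, auc, y = yte))
  }
}

#' Cross-validated IPF-LASSO: tune lambda and the penalty factors
#'
#' Runs repeated k-fold cross-validation for \eqn{\lambda_1} separately for
#' each candidate penalty-factor vector in `pflist` (the same fold plan is
#' reused across candidates, a paired design), then selects the candidate
#' whose optimal \eqn{\lambda_1} achieves the best cross-validated
#' performance. Each candidate gets its own lambda grid anchored at its own
#' `lambda_max`, since the penalty factors change the scale of
#' \eqn{\lambda_1}. With a single all-ones candidate this is ordinary
#' cross-validated lasso.
#'
#' The optimum is the minimum mean CV error (maximum for AUC and the Cox
#' partial-likelihood criterion), with ties broken toward larger lambda
#' (the sparser model) and, across candidates, toward the earlier candidate.
#' If `max.vars` is set, the lambda search for every candidate is restricted
#' to grid points whose full-data refit selects at most `max.vars`
#' variables.
#'
#' @inheritParams ipflasso
#' @param pflist list of candidate penalty-factor vectors (each length `M`);
#'   e.g. [pf_candidates_pow2()] for the bi-modal powers-of-two grid.
#' @param nfolds folds per repeat (default 5).
#' @param ncv number of CV repeats (default 10).
#' @param folds optional `"fold_plan"` (overrides `nfolds`/`ncv`/`seed`).
#' @param type.measure CV criterion: `"mse"` (gaussian), `"class"` or
#'   `"auc"` (binomial), `"cvpl"` (cox, held-out partial likelihood,
#'   maximized). Defaults per family to mse / class / cvpl.
#' @param max.vars optional cap on the number of selected variables.
#' @param seed integer seed for the fold plan.
#' @return Object of class `"cv.ipflasso"`: the selected penalty factors
#'   (`pf.opt`), selected `lambda.opt` and its grid index, the full-data
#'   `fit` for the winning candidate, `coef.opt`, `nzero.opt`, per-candidate
#'   CV curves (`curves`), and bookkeeping (`type.measure`, fold plan,
#'   skipped-fold counts).
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(60 * 20), 60, 20)
#' y <- x[, 1] * 1.5 + rnorm(60)
#' cvfit <- cv.ipflasso(x, y, blocks = list(1:5, 6:20), family = "gaussian",
#'                      pflist = list(c(1, 1), c(1, 4)), nfolds = 5,
#'                      ncv = 2, nlambda = 30, seed = 42)
#' cvfit$pf.opt
#' @export
cv.ipflasso <- function(x, y, blocks = list(seq_len(ncol(x))),
                        family = c("gaussian", "binomial", "cox"),
                        pflist = list(rep(1, length(blocks))),
                        nfolds = 5L, ncv = 10L, folds = NULL,
                        type.measure = NULL, max.vars = NULL,
                        nlambda = 100L, lambda.min.ratio = NULL,
                        seed = NULL, tol = 1e-7, maxit = 1e5L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  n <- nrow(x)
  blocks <- check_blocks(blocks, ncol(x))
  out <- prepare_outcome(y, family, n)
  if (is.null(type.measure)) type.measure <- default_measure(family)
  dir <- measure_direction(type.measure)
  if (family != "binomial" && type.measure %in% c("class", "auc"))
    stop("type.measure '", type.measure, "' requires family binomial")
  if (family == "cox" && type.measure != "cvpl")
    stop("family cox uses type.measure 'cvpl'")
  if (family == "gaussian" && type.measure != "mse")
    stop("family gaussian uses type.measure 'mse'")
  if (!length(pflist)) stop("'pflist' must contain at least one candidate")
  pflist <- lapply(pflist, canonical_pf, M = length(blocks))
  if (is.null(folds)) {
    strata <- if (family == "binomial") out$y else NULL
    folds <- make_folds(n, nfolds, ncv, seed = seed, strata = strata)
  }
  if (!inherits(folds, "fold_plan")) stop("'folds' must be a fold_plan")

  curves <- vector("list", length(pflist))
  best_val <- rep(if (dir == "min") Inf else -Inf, length(pflist))
  best_idx <- rep(NA_integer_, length(pflist))
  for (ci in seq_along(pflist)) {
    cur <- cv_one_candidate(x, out, blocks, pflist[[ci]], folds,
                            type.measure, nlambda, lambda.min.ratio,
                            tol, maxit)
    allowed <- seq_along(cur$lambda)
    if (!is.null(max.vars)) allowed <- which(cur$nzero <= max.vars)
    if (length(allowed)) {
      m <- cur$cvm[allowed]
      j <- if (dir == "min") which.min(m) else which.max(m)
      best_idx[ci] <- allowed[j]
      best_val[ci] <- m[j]
    }
    curves[[ci]] <- cur
  }
  if (all(is.na(best_idx)))
    stop("'max.vars' excludes every lambda for every candidate; ",
         "increase the cap")
  copt <- if (dir == "min") which.min(best_val) else which.max(best_val)
  cur <- curves[[copt]]
  iopt <- best_idx[copt]
  res <- list(call = match.call(), family = family,
              type.measure = type.measure, direction = dir,
              candidates = pflist, curves = lapply(curves, function(cu)
                cu[c("lambda", "cvm", "cvsd", "nzero", "skipped")]),
              pf.opt = pflist[[copt]], ind.pf.opt = copt,
              lambda = cur$lambda, cvm = cur$cvm, cvsd = cur$cvsd,
              lambda.opt = cur$lambda[iopt], ind.lambda.opt = iopt,
              cv.opt = best_val[copt],
              fit = cur$fit,
              coef.opt = cur$fit$beta[, iopt],
              a0.opt = if (!is.null(cur$fit$a0)) cur$fit$a0[iopt] else NULL,
              nzero.opt = cur$nzero[iopt],
              folds = folds, nfolds = folds$k, ncv = folds$repeats,
              skipped = vapply(curves, `[[`, 1L, "skipped"))
  class(res) <- "cv.ipflasso"
  res
}

#' @export
print.cv.ipflasso <- function(x, ...) {
  cat("Cross-validated block-weighted lasso (", x$family, ", ",
      x$type.measure, ")\n", sep = "")
  cat("  ", length(x$candidates), " candidate penalty-factor vector(s), ",
      x$nfolds, "-fold CV x ", x$ncv, " repeat(s)\n", sep = "")
  cat("  selected penalty factors: ",
      paste(format(x$pf.opt, digits = 4), collapse = ", "), "\n", sep = "")
  cat("  lambda.opt = ", format(x$lambda.opt, digits = 4),
      "  CV ", x$type.measure, " = ", format(x$cv.opt, digits = 4),
      "  nonzero = ", x$nzero.opt, "\n", sep = "")
  invisible(x)
}

#' @export
coef.cv.ipflasso <- function(object, ...) {
  coef(object$fit, index = object$ind.lambda.opt)
}

#' Predict from a cross-validated fit at the selected lambda
#' @param object a `"cv.ipflasso"` object.
#' @param newx new predictor matrix.
#' @param ... passed to [predict.ipflasso()] (e.g. `type`).
#' @export
predict.cv.ipflasso <- function(object, newx, ...) {
  predict(object$fit, newx, index = object$ind.lambda.opt, ...)
}

#' CV-curve plot
#'
#' Mean CV metric against `log(lambda)` for every candidate penalty-factor
#' vector; the selected optimum is marked.
#'
#' @param x a `"cv.ipflasso"` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cv.ipflasso <- function(x, ...) {
  nl <- max(vapply(x$curves, function(cu) length(cu$lambda), 1L))
  graphics::plot(NA, xlim = range(log(unlist(lapply(x$curves, `[[`,
                                                    "lambda")))),
                 ylim = range(unlist(lapply(x$curves, `[[`, "cvm")),
                              na.rm = TRUE),
                 xlab = expression(log(lambda[1])),
                 ylab = paste("CV", x$type.measure), ...)
  for (ci in seq_along(x$curves))
    graphics::lines(log(x$curves[[ci]]$lambda), x$curves[[ci]]$cvm,
                    col = ci)
  graphics::abline(v = log(x$lambda.opt), lty = 2)
  graphics::legend("topright", bty = "n", col = seq_along(x$candidates),
                   lty = 1, legend = vapply(x$candidates, function(pf)
                     paste(format(pf, digits = 3), collapse = ":"), ""))
  invisible(x)
}
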