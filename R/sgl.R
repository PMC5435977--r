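# Sparse group lasso comparator: penalty
#   (1-alpha)*lambda * sum_m sqrt(p_m) ||beta_m||_2 + alpha*lambda ||beta||_1
# solved by blockwise proximal gradient (FISTA with backtracking).

#' Sparse group lasso penalty value
#'
#' @param beta coefficient vector.
#' @param blocks block structure over `seq_along(beta)`.
#' @param lambda penalty level.
#' @param alpha mixing parameter in `[0,1]`: 1 is the pure lasso, 0 the
#'   group lasso.
#' @return Nonnegative penalty value
#'   \eqn{(1-\alpha)\lambda\sum_m \sqrt{p_m}\|\beta^{(m)}\|_2 +
#'   \alpha\lambda\|\beta\|_1}.
#' @export
sgl_penalty <- function(beta, blocks, lambda, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]")
  blocks <- check_blocks(blocks, length(beta))
  gr <- sum(vapply(blocks, function(b)
    sqrt(length(b)) * sqrt(sum(beta[b]^2)), 1))
  (1 - alpha) * lambda * gr + alpha * lambda * sum(abs(beta))
}

# Smallest lambda with an all-zero solution: block m enters when
# || S(g_m, alpha*lambda) ||_2 > (1-alpha)*lambda*sqrt(p_m); solve the
# boundary per block (bisection; closed forms at alpha = 0 and 1).
sgl_lambda_max <- function(g, blocks, alpha) {
  lm_block <- vapply(blocks, function(b) {
    gm <- g[b]
    pm <- length(b)
    if (alpha >= 1) return(max(abs(gm)))
    if (alpha <= 0) return(sqrt(sum(gm^2)) / sqrt(pm))
    h <- function(lam) {
      s <- pmax(abs(gm) - alpha * lam, 0)
      sqrt(sum(s^2)) - (1 - alpha) * lam * sqrt(pm)
    }
    hi <- max(abs(gm)) / alpha
    stats::uniroot(h, c(0, hi), tol = 1e-12)$root
  }, 1)
  max(lm_block)
}

#' Fit a sparse group lasso path
#'
#' Minimizes `loss + sgl_penalty` along a decreasing lambda grid, where the
#' loss is `(1/(2n))` RSS (gaussian) or the `(1/n)`-scaled logistic negative
#' log-likelihood with unpenalized intercept (binomial). Each block is a
#' group; the group term drives all-in/all-out block selection while the L1
#' term keeps within-block sparsity. Columns are standardized globally (as
#' in the other fitters) and coefficients returned on the original scale.
#'
#' The solver is proximal gradient with FISTA momentum and backtracking line
#' search; the proximal operator is elementwise soft-thresholding followed
#' by blockwise group shrinkage. The default tolerance is a loose 1e-2
#' relative coefficient change, matching common practice for this
#' comparator at scale; pass a smaller `tol` for certificate-grade
#' solutions.
#'
#' @inheritParams ipflasso
#' @param alpha mixing parameter in `[0,1]` (default 0.95).
#' @param nlambda grid length (default 20).
#' @param lambda.min.ratio smallest grid fraction (default 0.1).
#' @param tol relative convergence tolerance.
#' @param maxit maximum proximal iterations per lambda.
#' @return Object of class `c("sgl", "ipflasso")` (shares the path-object
#'   layout, so `coef`, `predict` and `plot` apply), with `alpha` recorded.
#' @export
sgl <- function(x, y, blocks = list(seq_len(ncol(x))),
                family = c("gaussian", "binomial"), alpha = 0.95,
                lambda = NULL, nlambda = 20L, lambda.min.ratio = 0.1,
                tol = 1e-2, maxit = 10000L) {
  family <- match.arg(family)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]")
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  blocks <- check_blocks(blocks, p)
  out <- prepare_outcome(y, family, n)
  std <- standardize_x(x)
  if (any(std$zero))
    warning(sum(std$zero), " zero-variance column(s); their coefficients ",
            "remain 0")
  # contiguous column order for the blockwise solver
  perm <- unlist(blocks, use.names = FALSE)
  sizes <- vapply(blocks, length, 1L)
  gstart <- c(0L, cumsum(sizes))[seq_along(sizes)]
  xs <- std$xs[, perm, drop = FALSE]
  yfit <- if (family == "gaussian") out$y - mean(out$y) else out$y
  if (is.null(lambda)) {
    g <- null_gradient(std$xs, out)
    g[std$zero] <- 0
    lmax <- sgl_lambda_max(g, blocks, alpha)
    lambda <- default_lambda_grid(lmax, nlambda, lambda.min.ratio)
  } else {
    lambda <- as.numeric(lambda)
    if (length(lambda) > 1L && any(diff(lambda) >= 0))
      stop("'lambda' must be strictly decreasing")
  }
  res <- sgl_path(xs, yfit, if (family == "gaussian") 0L else 1L,
                  as.integer(gstart), as.integer(sizes), alpha, lambda,
                  intercept = TRUE, tol = tol, maxit = as.integer(maxit))
  if (!all(res$converged))
    warning("SGL solver did not converge at ", sum(!res$converged),
            " lambda value(s)")
  beta_std <- matrix(0, p, length(lambda))
  beta_std[perm, ] <- res$beta
  beta_std[abs(beta_std) < 1e-10] <- 0
  beta <- beta_std / std$scale
  beta[std$zero, ] <- 0
  a0 <- if (family == "gaussian")
    rep(mean(out$y), length(lambda)) - drop(crossprod(std$center, beta))
  else res$a0 - drop(crossprod(std$center, beta))
  fnames <- colnames(x)
  if (is.null(fnames)) fnames <- paste0("V", seq_len(p))
  dimnames(beta) <- list(fnames, NULL)
  df.block <- do.call(rbind, lapply(blocks, function(b)
    colSums(beta[b, , drop = FALSE] != 0)))
  rownames(df.block) <- names(blocks)
  structure(list(call = match.call(), family = family, lambda = lambda,
                 beta = beta, a0 = a0, df = colSums(beta != 0),
                 df.block = df.block, alpha = alpha, blocks = blocks,
                 feature.names = fnames, nobs = n,
                 center = std$center, scale = std$scale,
                 zero.variance = which(std$zero),
                 iters = res$iters, converged = res$converged),
            class = c("sgl", "ipflasso"))
}

#' @export
print.sgl <- function(x, ...) {
  cat("Sparse group lasso path (", x$family, ", alpha = ", x$alpha,
      ")\n", sep = "")
  cat("  ", length(x$blocks), " group(s), sizes: ",
      paste(vapply(x$blocks, length, 1L), collapse = ", "), "\n", sep = "")
  cat("  lambda grid: ", length(x$lambda), " values; nonzero: ",
      x$df[1L], " to ", x$df[length(x$df)], "\n", sep = "")
  invisible(x)
}

#' Cross-validated sparse group lasso
#'
#' k-fold CV (no repeats by default, mirroring how this comparator is
#' commonly run) selecting lambda at fixed `alpha`. The CV loss is the
#' family deviance (logistic negative log-likelihood, or MSE for gaussian).
#'
#' @inheritParams sgl
#' @param nfolds folds (default 5).
#' @param folds optional `"fold_plan"` with `repeats >= 1`.
#' @param seed fold-plan seed.
#' @return Object of class `"cv.sgl"` with the full-data `fit`,
#'   `lambda.opt`, CV curve, and the coefficient vector / nonzero count at
#'   the optimum.
#' @export
cv.sgl <- function(x, y, blocks = list(seq_len(ncol(x))),
                   family = c("gaussian", "binomial"), alpha = 0.95,
                   nfolds = 5L, folds = NULL, seed = NULL,
                   nlambda = 20L, lambda.min.ratio = 0.1,
                   tol = 1e-2, maxit = 10000L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  n <- nrow(x)
  out <- prepare_outcome(y, family, n)
  blocks <- check_blocks(blocks, ncol(x))
  if (is.null(folds)) {
    strata <- if (family == "binomial") out$y else NULL
    folds <- make_folds(n, nfolds, 1L, seed = seed, strata = strata)
  }
  full <- sgl(x, y, blocks = blocks, family = family, alpha = alpha,
              nlambda = nlambda, lambda.min.ratio = lambda.min.ratio,
              tol = tol, maxit = maxit)
  grid <- full$lambda
  vals <- matrix(NA_real_, folds$repeats * folds$k, length(grid))
  row <- 0L
  for (r in seq_len(folds$repeats)) {
    for (f in seq_len(folds$k)) {
      row <- row + 1L
      test <- folds$assignments[r, ] == f
      train <- !test
      if (family == "binomial" && length(unique(out$y[train])) < 2L) {
        warning("skipping degenerate fold ", f, " of repeat ", r)
        next
      }
      fitf <- suppressWarnings(
        sgl(x[train, , drop = FALSE], out$y[train], blocks = blocks,
            family = family, alpha = alpha, lambda = grid,
            tol = tol, maxit = maxit))
      pred <- predict(fitf, x[test, , drop = FALSE], type = "response")
      yte <- out$y[test]
      vals[row, ] <- if (family == "gaussian") colMeans((pred - yte)^2)
      else apply(pred, 2L, function(pr) {
        pr <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
        -2 * mean(yte * log(pr) + (1 - yte) * log(1 - pr))
      })
    }
  }
  if (all(is.na(vals))) stop("all CV folds were degenerate")
  cvm <- colMeans(vals, na.rm = TRUE)
  iopt <- which.min(cvm)
  structure(list(call = match.call(), family = family, alpha = alpha,
                 lambda = grid, cvm = cvm,
                 cvsd = apply(vals, 2L, sd, na.rm = TRUE),
                 lambda.opt = grid[iopt], ind.lambda.opt = iopt,
                 fit = full, coef.opt = full$beta[, iopt],
                 a0.opt = full$a0[iopt], nzero.opt = full$df[iopt],
                 folds = folds),
            class = "cv.sgl")
}

#' @export
print.cv.sgl <- function(x, ...) {
  cat("Cross-validated sparse group lasso (", x$family, ", alpha = ",
      x$alpha, ")\n", sep = "")
  cat("  lambda.opt = ", format(x$lambda.opt, digits = 4),
      "  nonzero = ", x$nzero.opt, "\n", sep = "")
  invisible(x)
}

#' @export
predict.cv.sgl <- function(object, newx, ...) {
  predict(object$fit, newx, index = object$ind.lambda.opt, ...)
}

#' @export
coef.cv.sgl <- function(object, ...) {
  coef(object$fit, index = object$ind.lambda.opt)
}
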