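# Comparator methods: standard lasso delegation, sparse group lasso
# (penalty value, limits, certificates, oracle agreement), separate
# per-modality models.

test_that("the standard lasso is the uniform-penalty fit, bit for bit", {
  inst <- random_instance("gaussian", 30, 16, seed = 2)
  blocks <- list(1:8, 9:16)
  a <- standard_lasso(inst$x, inst$y, family = "gaussian",
                      blocks = blocks, nlambda = 12)
  b <- ipflasso(inst$x, inst$y, blocks = blocks, family = "gaussian",
                penalty.factors = c(1, 1), nlambda = 12)
  expect_identical(a$beta, b$beta)
  expect_identical(a$lambda, b$lambda)
})

test_that("the sparse-group penalty evaluates exactly", {
  expect_equal(sgl_penalty(rep(0, 6), list(1:3, 4:6), 2, 0.3), 0)
  beta <- c(1, -2, 0.5, 0, 3)
  expect_equal(sgl_penalty(beta, list(1:5), 1.5, 1), 1.5 * sum(abs(beta)))
  # one block, p = 4, beta = (1,1,0,0), alpha = 0.5, lambda = 1
  expect_equal(sgl_penalty(c(1, 1, 0, 0), list(1:4), 1, 0.5),
               0.5 * 2 * sqrt(2) + 0.5 * 2)
  expect_error(sgl_penalty(beta, list(1:5), 1, 1.2), "alpha")
})

test_that("SGL at alpha = 1 reduces to the standard lasso", {
  inst <- random_instance("gaussian", 30, 14, seed = 6)
  blocks <- list(1:6, 7:14)
  f_sgl <- sgl(inst$x, inst$y, blocks = blocks, family = "gaussian",
               alpha = 1, nlambda = 8, tol = 1e-8, maxit = 50000)
  f_las <- ipflasso(inst$x, inst$y, blocks = blocks, family = "gaussian",
                    lambda = f_sgl$lambda, tol = 1e-11)
  expect_lt(max(abs(f_sgl$beta - f_las$beta)), 1e-5)
})

test_that("SGL at alpha = 0 is the group lasso: an all-noise block is
          dropped entirely at moderate penalty", {
  set.seed(31)
  n <- 60
  x <- matrix(rnorm(n * 16), n, 16)
  y <- drop(x[, 1:4] %*% c(1.5, -1, 1, 0.8)) + rnorm(n)
  blocks <- list(1:8, 9:16)  # block 2 is pure noise
  fit <- sgl(x, y, blocks = blocks, family = "gaussian", alpha = 0,
             nlambda = 10, lambda.min.ratio = 0.2, tol = 1e-7,
             maxit = 50000)
  mid <- 5
  expect_gt(fit$df.block[1, mid], 0)
  expect_equal(unname(fit$df.block[2, mid]), 0)
  for (l in c(3, 6, 9))
    expect_lt(sgl_certificate(fit, x, y, l), 1e-3)
})

test_that("SGL agrees with the generic proximal oracle and passes block
          certificates at interior alpha", {
  set.seed(17)
  x <- matrix(rnorm(20 * 10), 20, 10)
  y <- drop(x[, c(1, 6)] %*% c(1.2, -0.9)) + rnorm(20)
  blocks <- list(1:5, 6:10)
  fit <- sgl(x, y, blocks = blocks, family = "gaussian", alpha = 0.5,
             nlambda = 6, tol = 1e-9, maxit = 100000)
  out <- list(family = "gaussian", y = y - mean(y))
  s <- std_cols(x)
  for (l in c(3, 6)) {
    orc <- oracle_prox_fit(s$xs, out, fit$lambda[l], blocks = blocks,
                           alpha = 0.5)
    expect_equal(unname(fit$beta[, l] * s$scale), orc$beta,
                 tolerance = 1e-4)
    expect_lt(sgl_certificate(fit, x, y, l), 1e-3)
  }
  # binomial branch with certificates
  yb <- rbinom(20, 1, plogis(x[, 1]))
  if (length(unique(yb)) < 2) yb[1:2] <- c(0, 1)
  fb <- sgl(x, yb, blocks = blocks, family = "binomial", alpha = 0.95,
            nlambda = 6, tol = 1e-9, maxit = 100000)
  for (l in c(3, 6))
    expect_lt(sgl_certificate(fb, x, yb, l), 1e-3)
})

test_that("cross-validated SGL selects a lambda on its grid and predicts", {
  set.seed(23)
  x <- matrix(rnorm(50 * 12), 50, 12)
  y <- rbinom(50, 1, plogis(1.5 * x[, 1] - x[, 7]))
  cvfit <- cv.sgl(x, y, blocks = list(1:6, 7:12), family = "binomial",
                  alpha = 0.95, nfolds = 5, seed = 3, nlambda = 12)
  expect_true(cvfit$lambda.opt %in% cvfit$lambda)
  pr <- predict(cvfit, x, type = "response")
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("separate-models coefficients for one modality ignore the other
          modality entirely", {
  set.seed(41)
  n <- 50
  x <- matrix(rnorm(n * 20), n, 20)
  y <- rbinom(n, 1, plogis(x[, 1] + x[, 11]))
  blocks <- list(1:10, 11:20)
  fp <- make_folds(n, 5, 3, seed = 6, strata = y)
  s1 <- separate_lasso(x, y, blocks, family = "binomial", folds = fp,
                       nlambda = 15)
  # permute the order of modality-2 columns: modality-1 model unchanged
  x2 <- x
  perm <- sample(11:20)
  x2[, 11:20] <- x[, perm]
  s2 <- separate_lasso(x2, y, blocks, family = "binomial", folds = fp,
                       nlambda = 15)
  expect_identical(s1$fits[[1]]$coef.opt, s2$fits[[1]]$coef.opt)
  # total selected equals the sum over modalities
  expect_equal(s1$nzero, sum(s1$nzero.by.block))
})

test_that("with a single modality the combiner is a monotone recalibration,
          leaving the AUC unchanged", {
  set.seed(52)
  n <- 60
  x <- matrix(rnorm(n * 10), n, 10)
  y <- rbinom(n, 1, plogis(2 * x[, 1]))
  fp <- make_folds(n, 5, 2, seed = 8, strata = y)
  sep <- separate_lasso(x, y, blocks = list(1:10), family = "binomial",
                        folds = fp, nlambda = 15)
  las <- cv.ipflasso(x, y, family = "binomial", folds = fp, nlambda = 15)
  a_sep <- auc(predict(sep, x, type = "link"), y)
  a_las <- auc(drop(predict(las, x, type = "link")), y)
  expect_equal(a_sep, a_las, tolerance = 1e-12)
})

test_that("empty modality models fall back to constant predictors and the
          null combiner", {
  set.seed(63)
  n <- 40
  x <- matrix(rnorm(n * 8), n, 8)
  y <- rbinom(n, 1, 0.5)  # pure noise
  fp <- make_folds(n, 5, 2, seed = 2, strata = y)
  sep <- suppressWarnings(
    separate_lasso(x, y, blocks = list(1:4, 5:8), family = "binomial",
                   folds = fp, nlambda = 10, lambda.min.ratio = 0.5))
  if (sep$nzero == 0) {
    pr <- predict(sep, x, type = "response")
    expect_equal(pr, rep(mean(y), n), tolerance = 1e-9)
  } else {
    succeed("CV selected a nonempty noise model for this draw")
  }
})
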