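# Core weighted-L1 path solver: soft-threshold kernel, grid anchor,
# closed-form and oracle agreement, KKT certificates, rescaling route.

test_that("soft-threshold kernel shrinks toward zero", {
  expect_equal(soft_threshold(0.7, 0.2), 0.5)
  expect_equal(soft_threshold(-0.3, 0.5), 0)
  z <- c(-2.5, -0.1, 0, 0.4, 3)
  expect_equal(soft_threshold(z, 0), z)
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("lambda_max matches the orthonormal closed form and anchors an
          empty model in all families", {
  set.seed(11)
  n <- 40
  m <- scale(matrix(rnorm(n * 5), n, 5), center = TRUE, scale = FALSE)
  q <- qr.Q(qr(m))  # centered orthonormal columns
  x <- q * sqrt(n)  # orthonormal under the 1/n inner product
  y <- drop(x %*% c(1, -0.5, 0, 0, 0)) + rnorm(n)
  lm_pkg <- lambda_max(x, y, "gaussian")
  yc <- y - mean(y)
  xs <- std_cols(x)$xs
  expect_equal(lm_pkg, max(abs(crossprod(xs, yc)) / n), tolerance = 1e-12)

  for (fam in c("gaussian", "binomial", "cox")) {
    inst <- random_instance(fam, 30, 12, seed = 100 + match(fam, c(
      "gaussian", "binomial", "cox")))
    lmax <- lambda_max(inst$x, inst$y, fam)
    fit <- ipflasso(inst$x, inst$y, family = fam,
                    lambda = c(lmax * 1.1, lmax))
    expect_identical(unname(fit$df), c(0, 0))
  }
})

test_that("doubling penalty weights halves lambda_max, matching brute-force
          bisection for the smallest all-zero lambda", {
  for (seed in 1:5) {
    inst <- random_instance("gaussian", 20, 10, seed = seed)
    w <- runif(10, 0.5, 2)
    l1 <- lambda_max(inst$x, inst$y, "gaussian", penalty.weights = w)
    l2 <- lambda_max(inst$x, inst$y, "gaussian", penalty.weights = 2 * w)
    expect_equal(l2, l1 / 2, tolerance = 1e-12)
    # bisection oracle: smallest lambda whose fit is empty
    # (weights must map onto a block structure: use per-feature blocks)
    blocks <- as.list(seq_len(10))
    empty_at <- function(lam) {
      f <- ipflasso(inst$x, inst$y, blocks = blocks,
                    family = "gaussian", penalty.factors = w / w[1],
                    lambda = c(lam))
      f$df[1] == 0
    }
    # lambda in ipflasso is the reference-block lambda_1; convert
    l1_ref <- l1 * w[1]
    lo <- l1_ref * 0.8
    hi <- l1_ref * 1.2
    expect_false(empty_at(lo))
    expect_true(empty_at(hi))
    for (i in 1:25) {
      mid <- (lo + hi) / 2
      if (empty_at(mid)) hi <- mid else lo <- mid
    }
    expect_equal((lo + hi) / 2, l1_ref, tolerance = 1e-5)
  }
  expect_error(lambda_max(matrix(rnorm(20), 10, 2), rep(1, 10), "gaussian"),
               "constant")
  expect_error(lambda_max(matrix(rnorm(20), 10, 2), rep(1, 10), "binomial"),
               "single class")
})

test_that("unpenalized limit reproduces least squares on a full-rank design", {
  set.seed(3)
  x <- matrix(rnorm(60 * 6), 60, 6)
  y <- drop(x %*% c(2, -1, 0.5, 0, 0, 1)) + rnorm(60)
  lmax <- lambda_max(x, y, "gaussian")
  fit <- ipflasso(x, y, family = "gaussian",
                  lambda = lmax * c(1, 0.1, 1e-7), tol = 1e-12)
  ls <- coef(lm(y ~ x))
  expect_equal(unname(fit$beta[, 3]), unname(ls[-1]), tolerance = 1e-6)
  expect_equal(unname(fit$a0[3]), unname(ls[1]), tolerance = 1e-5)
})

test_that("orthonormal gaussian path equals coordinatewise soft-thresholding", {
  set.seed(21)
  n <- 50
  m <- scale(matrix(rnorm(n * 5), n, 5), center = TRUE, scale = FALSE)
  q <- qr.Q(qr(m))
  x <- q * sqrt(n)
  y <- drop(x %*% c(1.5, -1, 0.4, 0, 0)) + rnorm(n)
  s <- std_cols(x)
  yc <- y - mean(y)
  z <- drop(crossprod(s$xs, yc)) / n
  grid <- max(abs(z)) * c(0.8, 0.5, 0.2, 0.05)
  fit <- ipflasso(x, y, family = "gaussian", lambda = grid, tol = 1e-10)
  for (l in seq_along(grid)) {
    closed <- soft_threshold(z, grid[l]) / s$scale
    expect_equal(unname(fit$beta[, l]), unname(closed), tolerance = 1e-7)
  }
})

test_that("solutions satisfy the KKT subgradient certificate in all
          families", {
  fams <- c("gaussian", "binomial", "cox")
  for (seed in 1:10) {
    fam <- fams[(seed - 1) %% 3 + 1]
    inst <- random_instance(fam, 30, 40, seed = 300 + seed)
    blocks <- list(1:15, 16:40)
    pf <- sample(c(0.5, 1, 2, 4), 2)
    fit <- suppressWarnings(
      ipflasso(inst$x, inst$y, blocks = blocks, family = fam,
               penalty.factors = pf, nlambda = 12, tol = 1e-9,
               maxit = 3e5))
    for (l in c(4, 8, 12))
      expect_lt(kkt_violation(fit, inst$x, inst$y, l), 1e-4)
  }
})

test_that("weighted fit matches the generic proximal-gradient oracle", {
  for (fam in c("gaussian", "binomial", "cox")) {
    inst <- random_instance(fam, 15, 8, seed = 40 + nchar(fam))
    blocks <- list(1:4, 5:8)
    pf <- c(1, 4)
    lmax <- lambda_max(inst$x, inst$y, fam,
                       penalty.weights = rep(pf, each = 4))
    lam <- lmax * 0.3
    fit <- ipflasso(inst$x, inst$y, blocks = blocks, family = fam,
                    penalty.factors = pf, lambda = c(lmax, lam),
                    tol = 1e-11)
    out <- ipfreg:::prepare_outcome(inst$y, fam, 15)
    if (fam == "gaussian") out$y <- out$y - mean(out$y)
    s <- std_cols(inst$x)
    orc <- oracle_prox_fit(s$xs, out, lam, w = rep(pf, each = 4))
    expect_equal(unname(fit$beta[, 2] * s$scale), orc$beta,
                 tolerance = 1e-5)
  }
})

test_that("rescaling route and per-feature weight route agree to 1e-6", {
  fams <- c("gaussian", "binomial", "cox")
  pf_pool <- c(1 / 4, 1 / 2, 1, 2, 4)
  for (seed in 1:9) {
    fam <- fams[(seed - 1) %% 3 + 1]
    inst <- random_instance(fam, 40, 24, seed = 500 + seed)
    blocks <- list(1:10, 11:24)
    pf <- c(1, sample(pf_pool, 1))
    fit <- ipflasso(inst$x, inst$y, blocks = blocks, family = fam,
                    penalty.factors = pf, nlambda = 8, tol = 1e-10)
    s <- std_cols(inst$x)
    xr <- rescale_design(s$xs, blocks, pf)
    w <- ipfreg:::pf_weights(blocks, pf, 24)
    fit_r <- ipflasso(xr, inst$y, family = fam, lambda = fit$lambda,
                      standardize = FALSE, tol = 1e-10)
    back <- (fit_r$beta / w) / s$scale
    expect_lt(max(abs(back - fit$beta)), 1e-6)
  }
})

test_that("penalty factors are scalar-multiplication invariant and the
          uniform vector reduces to the standard lasso exactly", {
  inst <- random_instance("binomial", 40, 20, seed = 77)
  blocks <- list(1:8, 9:20)
  f1 <- ipflasso(inst$x, inst$y, blocks, family = "binomial",
                 penalty.factors = c(1, 4), nlambda = 10)
  f2 <- ipflasso(inst$x, inst$y, blocks, family = "binomial",
                 penalty.factors = c(3, 12), nlambda = 10)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$lambda, f2$lambda)

  fu <- ipflasso(inst$x, inst$y, blocks, family = "binomial",
                 penalty.factors = c(1, 1), nlambda = 10)
  fs <- standard_lasso(inst$x, inst$y, family = "binomial",
                       blocks = blocks, nlambda = 10)
  expect_identical(fu$beta, fs$beta)
})

test_that("loss is nonincreasing along the path and the top model is empty", {
  for (fam in c("gaussian", "binomial", "cox")) {
    inst <- random_instance(fam, 35, 20, seed = 60 + nchar(fam))
    fit <- ipflasso(inst$x, inst$y, family = fam, nlambda = 15)
    expect_identical(unname(fit$df[1]), 0)
    out <- ipfreg:::prepare_outcome(inst$y, fam, 35)
    if (fam == "gaussian") out$y <- out$y - mean(out$y)
    s <- std_cols(inst$x)
    losses <- vapply(seq_along(fit$lambda), function(l) {
      b0 <- if (!is.null(fit$a0))
        fit$a0[l] + sum(fit$center * fit$beta[, l]) else 0
      oracle_loss(s$xs, out, fit$beta[, l] * s$scale, b0)
    }, 1)
    expect_true(all(diff(losses) < 1e-8))
  }
})

test_that("path agrees with an independent penalized-GLM implementation", {
  skip_if_not_installed("glmnet")
  inst <- random_instance("gaussian", 50, 20, seed = 9)
  w <- rep(c(1, 2), each = 10)
  fit <- ipflasso(inst$x, inst$y, blocks = list(1:10, 11:20),
                  family = "gaussian", penalty.factors = c(1, 2),
                  nlambda = 15, tol = 1e-10)
  # glmnet rescales penalty.factor to sum to p; shift the grid to match
  g <- glmnet::glmnet(inst$x, inst$y, penalty.factor = w,
                      lambda = fit$lambda * sum(w) / 20,
                      standardize = TRUE, thresh = 1e-14)
  expect_lt(max(abs(as.matrix(g$beta) - fit$beta)), 1e-5)
})

test_that("zero-variance columns are excluded with a warning and degenerate
          inputs are rejected", {
  inst <- random_instance("gaussian", 30, 10, seed = 15)
  x <- inst$x
  x[, 4] <- 2.5
  expect_warning(fit <- ipflasso(x, inst$y, family = "gaussian",
                                 nlambda = 8), "zero-variance")
  expect_true(all(fit$beta[4, ] == 0))
  expect_error(ipflasso(x[1, , drop = FALSE], 1, family = "gaussian"),
               "at least 2")
  expect_error(ipflasso(x, rep(1, 30), family = "binomial"),
               "single class")
})

test_that("predictions follow the link conventions and validate shapes", {
  # all-zero coefficients: binomial predicts the constant logistic(a0)
  inst <- random_instance("binomial", 30, 6, seed = 8)
  lmax <- lambda_max(inst$x, inst$y, "binomial")
  fit <- ipflasso(inst$x, inst$y, family = "binomial", lambda = c(lmax))
  expect_identical(unname(fit$df[1]), 0)
  pr <- predict(fit, inst$x, index = 1, type = "response")
  expect_equal(unname(pr[, 1]),
               rep(1 / (1 + exp(-fit$a0[1])), 30), tolerance = 1e-12)
  expect_error(predict(fit, inst$x[, 1:3]), "columns")
})

test_that("Breslow baseline survival matches the hand-computed product on a
          six-subject toy", {
  time <- c(1, 2, 2, 3, 5, 6)
  status <- c(1, 1, 0, 1, 0, 1)
  eta <- c(0.5, -0.2, 0.1, 0, 0.3, -0.4)
  bh <- ipfreg:::breslow_basehaz(eta, time, status)
  ee <- exp(eta)
  h1 <- 1 / sum(ee)                 # event at t=1, risk set all
  h2 <- 1 / sum(ee[2:6])            # event at t=2
  h3 <- 1 / sum(ee[4:6])            # event at t=3
  h6 <- 1 / ee[6]                   # event at t=6
  expect_equal(bh$time, c(1, 2, 3, 6))
  expect_equal(bh$cumhaz, cumsum(c(h1, h2, h3, h6)), tolerance = 1e-12)
  sp <- ipfreg:::breslow_survival(bh, eta[1], c(2.5, 6))
  expect_equal(sp[1, 1], exp(-(h1 + h2) * ee[1]), tolerance = 1e-12)
})
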