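# Benchmark generator: setting catalogue, covariance layout, sampling
# moments, and runner determinism.

test_that("the setting catalogue returns the published parameter rows", {
  a <- sim_setting("A")
  expect_equal(c(a$p1, a$p2, a$p1r, a$p2r), c(1000L, 1000L, 10L, 10L))
  expect_equal(c(a$beta1, a$beta2), c(0.5, 0.5))
  expect_false(a$correlated)
  f <- sim_setting("F")
  expect_equal(c(f$p1, f$p2, f$p1r, f$p2r, f$beta1, f$beta2),
               c(20, 1000, 15, 3, 0.5, 0.5))
  d <- sim_setting("D")
  expect_equal(c(d$p1r, d$p2r), c(20L, 0L))
  expect_equal(d$beta2, 0)  # no relevant variables in modality 2
  dp <- sim_setting("D'")
  expect_true(dp$correlated)
  expect_equal(dp$rho, 0.4)
  expect_equal(dp$b, 10L)
  expect_equal(dp$p1, d$p1)
  expect_error(sim_setting("Z"), "valid names")
})

test_that("custom settings validate their parameters", {
  expect_error(sim_setting(p1 = 10, p2 = 10, p1r = 12, p2r = 0,
                           beta1 = 1, beta2 = 0), "exceed")
  expect_error(sim_setting(p1 = 10, p2 = 10, p1r = 2, p2r = 0,
                           beta1 = 1, beta2 = 0, tau = 1.5), "tau")
  expect_error(sim_setting(p1 = 10, p2 = 12, p1r = 1, p2r = 1, beta1 = 1,
                           beta2 = 1, correlated = TRUE, b = 4),
               "divide")
})

test_that("the block covariance has the documented layout", {
  expect_equal(sim_covariance(4, 4, 2, 0), diag(8))
  S <- sim_covariance(4, 4, 2, 0.4)
  A <- matrix(0.4, 2, 2); diag(A) <- 1
  B <- matrix(0.4, 2, 2)
  Z <- matrix(0, 2, 2)
  expected <- rbind(
    cbind(A, Z, B, Z),
    cbind(Z, A, Z, B),
    cbind(B, Z, A, Z),
    cbind(Z, B, Z, A))
  expect_equal(S, expected)
  # PSD for the benchmark correlation level at realistic sizes
  S2 <- sim_covariance(100, 1000, 10, 0.4)
  expect_silent(chol(S2 + diag(1e-10, 1100)))
})

test_that("generated datasets have the advertised structure and are
          reproducible from the seed", {
  st <- sim_setting(p1 = 30, p2 = 50, p1r = 5, p2r = 3, beta1 = 0.5,
                    beta2 = 0.4, n = 40)
  d1 <- sim_data(st, seed = 11)
  d2 <- sim_data(st, seed = 11)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  expect_equal(dim(d1$x), c(40L, 80L))
  expect_equal(lengths(d1$blocks), c(mod1 = 30L, mod2 = 50L))
  expect_equal(d1$truth$index, c(1:5, 31:33))
  expect_equal(d1$truth$effect, c(rep(0.5, 5), rep(0.4, 3)))
})

test_that("class-conditional means and class frequency follow the design", {
  st <- sim_setting(p1 = 20, p2 = 20, p1r = 5, p2r = 5, beta1 = 0.5,
                    beta2 = 0.3, n = 4000)
  d <- sim_data(st, seed = 5)
  expect_lt(abs(mean(d$y) - 0.5), 2.58 * sqrt(0.25 / 4000))
  se <- 1 / sqrt(sum(d$y == 1))
  for (j in 1:5) {
    expect_lt(abs(mean(d$x[d$y == 1, j]) - 0.5), 4 * se)
    expect_lt(abs(mean(d$x[d$y == 0, j]) - 0), 4 * se)
    expect_lt(abs(mean(d$x[d$y == 1, 20 + j]) - 0.3), 4 * se)
  }
  # irrelevant columns are centered in both classes
  expect_lt(abs(mean(d$x[d$y == 1, 12])), 4 * se)
})

test_that("correlated settings scatter the relevant columns by a per-dataset
          permutation and preserve the correlation structure", {
  st <- sim_setting(p1 = 20, p2 = 40, p1r = 4, p2r = 2, beta1 = 0.6,
                    beta2 = 0.6, n = 3000, correlated = TRUE, b = 4)
  d <- sim_data(st, seed = 21)
  expect_length(d$truth$index, 6)
  expect_true(all(d$truth$index[1:4] <= 20) &&
                all(d$truth$index[5:6] > 20))
  # the truth indices carry the mean shift
  se <- 1 / sqrt(sum(d$y == 1))
  for (k in seq_along(d$truth$index))
    expect_lt(abs(mean(d$x[d$y == 1, d$truth$index[k]]) -
                    d$truth$effect[k]), 4 * se)
  # two datasets from different seeds use different permutations
  d2 <- sim_data(st, seed = 22)
  expect_false(identical(d$truth$index, d2$truth$index))
})

test_that("the experiment runner is reproducible end to end and reports
          per-method summaries", {
  st <- sim_setting(p1 = 25, p2 = 25, p1r = 4, p2r = 0, beta1 = 0.8,
                    beta2 = 0, n = 60, n_test = 300)
  r1 <- run_simulation(st, B = 2, methods = c("ipf", "lasso"), seed = 3,
                       nlambda = 15,
                       pf_candidates = list(c(1, 1), c(1, 4), c(4, 1)),
                       ncv = 2)
  r2 <- run_simulation(st, B = 2, methods = c("ipf", "lasso"), seed = 3,
                       nlambda = 15,
                       pf_candidates = list(c(1, 1), c(1, 4), c(4, 1)),
                       ncv = 2)
  expect_identical(r1$replicates, r2$replicates)
  expect_setequal(unique(r1$replicates$method), c("ipf", "lasso"))
  expect_true(all(c("misclass", "auc", "nselected") %in%
                    r1$summary$metric))
  expect_true(all(r1$replicates$auc >= 0 & r1$replicates$auc <= 1))
  # pf2 recorded for ipf only
  expect_true(all(is.na(
    r1$replicates$pf2[r1$replicates$method == "lasso"])))
  expect_true(all(!is.na(
    r1$replicates$pf2[r1$replicates$method == "ipf"])))
})

test_that("the advantage of penalty-factor tuning over the standard lasso
          grows with the gap in relevant-variable proportions", {
  # settings A (equal proportions), C (0.1 vs 0.01), D (0.2 vs 0): the
  # extreme comparison of the monotone trend, at reduced B and CV repeats
  adv <- sapply(c("A", "C", "D"), function(sname) {
    res <- run_simulation(sim_setting(sname), B = 4,
                          methods = c("ipf", "lasso"), seed = 17,
                          nlambda = 25, ncv = 3, n_test = 2000)
    med <- with(res$replicates, tapply(auc, method, median))
    unname(med["ipf"] - med["lasso"])
  })
  expect_lte(adv["A"], adv["D"])
  expect_gt(adv["D"], 0)
})
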