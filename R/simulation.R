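# Bi-modal Gaussian benchmark designs: two predictor modalities, binary
# class, optional within/cross-modality block correlation; plus the
# replicated experiment runner.

.sim_table <- list(
  A = list(p1 = 1000L, p2 = 1000L, p1r = 10L, p2r = 10L,
           beta1 = 0.5, beta2 = 0.5),
  B = list(p1 = 100L, p2 = 1000L, p1r = 3L, p2r = 30L,
           beta1 = 0.5, beta2 = 0.5),
  C = list(p1 = 100L, p2 = 1000L, p1r = 10L, p2r = 10L,
           beta1 = 0.5, beta2 = 0.5),
  D = list(p1 = 100L, p2 = 1000L, p1r = 20L, p2r = 0L,
           beta1 = 0.3, beta2 = 0),
  E = list(p1 = 20L, p2 = 1000L, p1r = 3L, p2r = 10L,
           beta1 = 1, beta2 = 0.3),
  F = list(p1 = 20L, p2 = 1000L, p1r = 15L, p2r = 3L,
           beta1 = 0.5, beta2 = 0.5))

#' Benchmark simulation settings
#'
#' Returns the parameters of one named benchmark setting (`"A"`..`"F"`, or
#' the correlated variants `"A'"`..`"F'"`), or builds a custom setting from
#' explicit parameters. Each setting defines two predictor modalities of
#' sizes `p1`, `p2` with `p1r`/`p2r` truly relevant variables of effect
#' sizes `beta1`/`beta2`; a binary class drawn with success probability
#' `tau`; and, for correlated settings, `b` groups of mutually correlated
#' variables per modality with correlation `rho` within groups and between
#' paired groups across modalities.
#'
#' @param name setting name; omit to build a custom setting.
#' @param p1,p2 modality sizes.
#' @param p1r,p2r numbers of relevant variables (`p1r <= p1` etc.).
#' @param beta1,beta2 effect sizes (class-1 mean shift).
#' @param n training-set size (default 100).
#' @param tau class-1 probability (default 0.5).
#' @param correlated use the block covariance instead of identity.
#' @param rho correlation (default 0.4).
#' @param b correlated groups per modality (default 10; must divide `p1`
#'   and `p2` when `correlated`).
#' @param n_test evaluation-set size (default 5000).
#' @return Object of class `"sim_setting"`.
#' @examples
#' sim_setting("A")
#' sim_setting("D'")
#' @export
sim_setting <- function(name = NULL, p1, p2, p1r, p2r, beta1, beta2,
                        n = 100L, tau = 0.5, correlated = FALSE,
                        rho = 0.4, b = 10L, n_test = 5000L) {
  if (!is.null(name)) {
    base <- sub("'$", "", name)
    if (!base %in% names(.sim_table))
      stop("unknown setting '", name, "'; valid names: ",
           paste(c(names(.sim_table), paste0(names(.sim_table), "'")),
                 collapse = ", "))
    pars <- .sim_table[[base]]
    correlated <- grepl("'$", name)
    s <- c(list(name = name), pars,
           list(n = as.integer(n), tau = tau, correlated = correlated,
                rho = rho, b = as.integer(b), n_test = as.integer(n_test)))
  } else {
    s <- list(name = "custom", p1 = as.integer(p1), p2 = as.integer(p2),
              p1r = as.integer(p1r), p2r = as.integer(p2r),
              beta1 = beta1, beta2 = beta2, n = as.integer(n), tau = tau,
              correlated = correlated, rho = rho, b = as.integer(b),
              n_test = as.integer(n_test))
  }
  if (s$p1r > s$p1 || s$p2r > s$p2)
    stop("relevant-variable counts cannot exceed modality sizes")
  if (s$tau <= 0 || s$tau >= 1) stop("tau must be in (0,1)")
  if (abs(s$rho) >= 1) stop("|rho| must be < 1")
  if (s$correlated && (s$p1 %% s$b != 0 || s$p2 %% s$b != 0))
    stop("'b' must divide p1 and p2 for correlated settings")
  structure(s, class = "sim_setting")
}

#' @export
print.sim_setting <- function(x, ...) {
  cat("Simulation setting ", x$name, ": p=(", x$p1, ",", x$p2,
      "), relevant=(", x$p1r, ",", x$p2r, "), beta=(", x$beta1, ",",
      x$beta2, "), n=", x$n, ", tau=", x$tau, sep = "")
  if (x$correlated)
    cat(", correlated (rho=", x$rho, ", b=", x$b, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Block covariance matrix for correlated settings
#'
#' Builds the `(p1+p2) x (p1+p2)` covariance with, inside each modality, a
#' block-diagonal structure of `b` equicorrelated groups (1 on the
#' diagonal, `rho` off-diagonal within a group), and cross-modality blocks
#' of constant `rho` between the j-th group of modality 1 and the j-th
#' group of modality 2; all other entries are 0.
#'
#' @param p1,p2 modality sizes (`b` must divide both).
#' @param b groups per modality.
#' @param rho correlation.
#' @return Symmetric positive-definite matrix (an error reporting the
#'   smallest eigenvalue is raised otherwise).
#' @export
sim_covariance <- function(p1, p2, b, rho) {
  if (p1 %% b != 0 || p2 %% b != 0) stop("'b' must divide p1 and p2")
  p <- p1 + p2
  q1 <- p1 %/% b
  q2 <- p2 %/% b
  S <- matrix(0, p, p)
  for (j in seq_len(b)) {
    i1 <- (j - 1L) * q1 + seq_len(q1)
    i2 <- p1 + (j - 1L) * q2 + seq_len(q2)
    S[i1, i1] <- rho
    S[i2, i2] <- rho
    S[i1, i2] <- rho
    S[i2, i1] <- rho
  }
  diag(S) <- 1
  ok <- tryCatch({chol(S); TRUE}, error = function(e) FALSE)
  if (!ok) {
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    stop("covariance is not positive definite (smallest eigenvalue ",
         format(ev, digits = 4), ")")
  }
  S
}

# sample one group-pair-structured MVN draw without forming the full
# covariance: group pairs are independent of each other
.sample_sim_x <- function(n, setting) {
  p1 <- setting$p1
  p2 <- setting$p2
  p <- p1 + p2
  if (!setting$correlated)
    return(matrix(rnorm(n * p), n, p))
  b <- setting$b
  rho <- setting$rho
  q1 <- p1 %/% b
  q2 <- p2 %/% b
  Spair <- matrix(rho, q1 + q2, q1 + q2)
  diag(Spair) <- 1
  Spair[seq_len(q1), q1 + seq_len(q2)] <- rho
  R <- chol(Spair)
  x <- matrix(0, n, p)
  for (j in seq_len(b)) {
    z <- matrix(rnorm(n * (q1 + q2)), n, q1 + q2) %*% R
    x[, (j - 1L) * q1 + seq_len(q1)] <- z[, seq_len(q1)]
    x[, p1 + (j - 1L) * q2 + seq_len(q2)] <- z[, q1 + seq_len(q2)]
  }
  x
}

#' Generate one benchmark dataset
#'
#' Draws the binary class `y ~ Bernoulli(tau)`, then the predictors from
#' `MVN(0, Sigma)` for class 0 and `MVN(mu, Sigma)` for class 1, with mean
#' vector `mu = (beta1 x p1r, 0..., beta2 x p2r, 0...)`. For correlated
#' settings the columns are then randomly permuted within each modality so
#' the relevant variables scatter across the correlation groups (the truth
#' indices are updated accordingly); the permutation is drawn per dataset.
#'
#' @param setting a `"sim_setting"` (or a name accepted by
#'   [sim_setting()]).
#' @param seed optional integer seed (RNG state restored afterwards).
#' @param n number of samples (defaults to the setting's training size).
#' @return Object of class `"sim_data"`: list with `x`, `y`, `blocks` (two
#'   modalities), and `truth` (`index`, `effect` of relevant columns after
#'   permutation).
#' @export
sim_data <- function(setting, seed = NULL, n = NULL) {
  if (is.character(setting)) setting <- sim_setting(setting)
  stopifnot(inherits(setting, "sim_setting"))
  if (is.null(n)) n <- setting$n
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  p1 <- setting$p1
  p2 <- setting$p2
  y <- rbinom(n, 1L, setting$tau)
  x <- .sample_sim_x(n, setting)
  mu <- c(rep(setting$beta1, setting$p1r), rep(0, p1 - setting$p1r),
          rep(setting$beta2, setting$p2r), rep(0, p2 - setting$p2r))
  if (any(y == 1L))
    x[y == 1L, ] <- sweep(x[y == 1L, , drop = FALSE], 2L, mu, "+")
  truth_idx <- c(seq_len(setting$p1r), p1 + seq_len(setting$p2r))
  truth_eff <- mu[truth_idx]
  if (setting$correlated) {
    perm <- c(sample.int(p1), p1 + sample.int(p2))
    # column k of the permuted matrix is old column perm[k]
    x <- x[, perm, drop = FALSE]
    inv <- order(perm)
    truth_idx <- inv[truth_idx]
    ord <- order(truth_idx)
    truth_idx <- truth_idx[ord]
    truth_eff <- truth_eff[ord]
  }
  colnames(x) <- c(paste0("m1_", seq_len(p1)), paste0("m2_", seq_len(p2)))
  structure(list(x = x, y = y,
                 blocks = list(mod1 = seq_len(p1), mod2 = p1 + seq_len(p2)),
                 truth = list(index = truth_idx, effect = truth_eff,
                              mu = mu),
                 setting = setting),
            class = "sim_data")
}

#' Run a replicated benchmark experiment
#'
#' For each of `B` replicates: generate a training set, fit the requested
#' methods with their standard tuning protocols, and evaluate on an
#' independently drawn test set. Tuning protocols: IPF-LASSO uses the
#' 7-candidate powers-of-two penalty-factor grid with 5-fold CV repeated 10
#' times under the misclassification criterion; the standard lasso is the
#' single-candidate `(1,1)` version of the same; the separate-models method
#' uses per-modality 5x10 CV; the sparse group lasso uses `alpha = 0.95`
#' with 5-fold CV without repeats.
#'
#' Replicate `r` draws its training set with seed `seed + r` and its test
#' set with seed `seed + r + 1000000` (disjoint streams). Per-replicate
#' failures are logged and skipped; more than 20\% failures aborts.
#'
#' @param setting a `"sim_setting"` or setting name.
#' @param B number of replicates.
#' @param methods subset of `c("ipf", "lasso", "separate", "sgl")`.
#' @param seed base seed.
#' @param n_test test-set size (defaults to the setting's, 5000).
#' @param nlambda lambda-grid length for the lasso-family methods
#'   (default 50); the SGL grid has its own default (20 values to 0.1 of
#'   its maximum).
#' @param pf_candidates candidate penalty factors for IPF
#'   (default [pf_candidates_pow2()]).
#' @param nfolds,ncv CV protocol for the lasso-family methods.
#' @param alpha SGL mixing parameter.
#' @param verbose print per-replicate progress.
#' @return Object of class `"sim_result"`: `replicates` (long data frame
#'   with method, misclassification, AUC, selected-variable count, and the
#'   selected modality-2 penalty factor for IPF) and `summary` (median and
#'   quartiles per method and metric).
#' @export
run_simulation <- function(setting, B = 20L,
                           methods = c("ipf", "lasso", "separate", "sgl"),
                           seed = 1L, n_test = NULL, nlambda = 50L,
                           pf_candidates = pf_candidates_pow2(),
                           nfolds = 5L, ncv = 10L, alpha = 0.95,
                           verbose = FALSE) {
  if (is.character(setting)) setting <- sim_setting(setting)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(n_test)) n_test <- setting$n_test
  rows <- list()
  failures <- 0L
  for (r in seq_len(B)) {
    tr <- sim_data(setting, seed = seed + r)
    te <- sim_data(setting, seed = seed + r + 1000000L, n = n_test)
    for (meth in methods) {
      res <- tryCatch(
        .fit_one_method(meth, tr, te, pf_candidates, nfolds, ncv,
                        nlambda, alpha, fold_seed = seed + r),
        error = function(e) {
          warning("replicate ", r, ", method ", meth, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(res)) {
        failures <- failures + 1L
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = r, method = meth,
                   misclass = res$misclass, auc = res$auc,
                   nselected = res$nselected, pf2 = res$pf2)
    }
    if (failures > 0.2 * B * length(methods))
      stop("more than 20% of method fits failed; aborting")
    if (verbose)
      message("replicate ", r, "/", B, " done")
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$method), function(d) {
    data.frame(method = d$method[1L],
               metric = c("misclass", "auc", "nselected"),
               median = c(median(d$misclass), median(d$auc),
                          median(d$nselected)),
               q1 = c(quantile(d$misclass, 0.25), quantile(d$auc, 0.25),
                      quantile(d$nselected, 0.25)),
               q3 = c(quantile(d$misclass, 0.75), quantile(d$auc, 0.75),
                      quantile(d$nselected, 0.75)),
               row.names = NULL)
  }))
  structure(list(setting = setting, B = B, methods = methods, seed = seed,
                 replicates = reps, summary = summ, failures = failures),
            class = "sim_result")
}

.fit_one_method <- function(meth, tr, te, pf_candidates, nfolds, ncv,
                            nlambda, alpha, fold_seed) {
  pf2 <- NA_real_
  if (meth %in% c("ipf", "lasso")) {
    pflist <- if (meth == "ipf") pf_candidates else list(c(1, 1))
    cvfit <- suppressWarnings(
      cv.ipflasso(tr$x, tr$y, blocks = tr$blocks, family = "binomial",
                  pflist = pflist, nfolds = nfolds, ncv = ncv,
                  type.measure = "class", nlambda = nlambda,
                  seed = fold_seed))
    prob <- drop(predict(cvfit, te$x, type = "response"))
    nsel <- cvfit$nzero.opt
    if (meth == "ipf") pf2 <- cvfit$pf.opt[2L]
  } else if (meth == "separate") {
    fit <- suppressWarnings(
      separate_lasso(tr$x, tr$y, blocks = tr$blocks, family = "binomial",
                     nfolds = nfolds, ncv = ncv, seed = fold_seed,
                     nlambda = nlambda))
    prob <- predict(fit, te$x, type = "response")
    nsel <- fit$nzero
  } else {  # sgl
    cvfit <- suppressWarnings(
      cv.sgl(tr$x, tr$y, blocks = tr$blocks, family = "binomial",
             alpha = alpha, nfolds = nfolds, seed = fold_seed))
    prob <- drop(predict(cvfit, te$x, type = "response"))
    nsel <- cvfit$nzero.opt
  }
  list(misclass = misclassification_rate(prob, te$y),
       auc = auc(prob, te$y), nselected = nsel, pf2 = pf2)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Benchmark experiment: setting ", x$setting$name, ", B = ", x$B,
      ", methods: ", paste(x$methods, collapse = ", "), "\n", sep = "")
  if (x$failures > 0) cat("  failed fits:", x$failures, "\n")
  print(x$summary, row.names = FALSE)
  if ("ipf" %in% x$methods) {
    pf2 <- x$replicates$pf2[x$replicates$method == "ipf"]
    cat("  IPF modality-2 penalty factor > 1 in ",
        sum(pf2 > 1), "/", length(pf2), " replicates\n", sep = "")
  }
  invisible(x)
}
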