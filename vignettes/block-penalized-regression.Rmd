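---
title: "Block-weighted L1 regression for multi-modal predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-weighted L1 regression for multi-modal predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipfreg)
```

## The problem

Clinical prediction models increasingly combine predictors of very
different kinds: a handful of clinical covariates, thousands of gene
expression values, tens of thousands of copy-number features. A standard
lasso treats all of these columns identically, although the *proportion of
truly informative variables* usually differs drastically between such
modalities. `ipfreg` implements the integrative lasso with penalty factors
(IPF-LASSO): an L1-penalized regression in which every modality (block of
columns) `m` receives its own penalty \(\lambda_m\), so the estimate
minimizes

$$
\mathrm{loss}(\beta) \;+\; \sum_{m=1}^{M} \lambda_m \lVert \beta^{(m)} \rVert_1 ,
$$

with the loss being \(\tfrac{1}{2n}\) RSS (linear), the \(\tfrac1n\)-scaled
logistic negative log-likelihood with an unpenalized intercept, or the
\(\tfrac1n\)-scaled negative Breslow partial log-likelihood (Cox). Writing
\(\lambda_m = \lambda_1 \cdot pf_m\) with the first modality as reference,
the *penalty factors* \((1, pf_2, \ldots, pf_M)\) encode how much more
strongly each modality is penalized; the fit is invariant to multiplying
the whole vector by a positive scalar, so we canonicalize to \(pf_1 = 1\).
In the Bayesian reading of the lasso, this simply assigns a different
Laplace-prior scale to each modality.

Penalty factors can be prespecified from subject-matter knowledge or tuned
by cross-validation (below). With all factors equal the method *is* the
standard lasso — same code path, identical output.

## Estimation

For fixed penalty factors the problem reduces to an ordinary lasso: either
divide each column of block `m` by \(pf_m\), fit with a single penalty, and
divide the estimates back (the *rescaling route*), or equivalently give the
solver a per-feature penalty weight \(w_j = pf_m\) for \(j\) in block `m`.
We implement the weights directly inside a cyclical coordinate-descent
solver (C++, warm starts along a decreasing \(\lambda_1\) grid, sequential
strong-rule screening with a full KKT certification pass per grid point);
the rescaling route is retained as an equivalence oracle in the test suite,
where both routes agree to \(10^{-6}\). Internally columns are centered and
scaled to unit variance (divisor \(n\)) *before* the penalty weights are
applied, and coefficients are reported back on the original scale. The
reference software for this method leaves the relative order of
standardization and rescaling unstated; we standardize first, document it
here, and do not claim bit-level equality with that implementation —
solution-level agreement with an independent penalized-GLM implementation
is part of the test suite instead.

Numerical choices worth knowing:

* **Grid.** 100 log-spaced values (50 in the benchmark runner, see below)
  from \(\lambda_{\max}\) — the smallest \(\lambda_1\) with an all-zero
  model, computed from the null-model gradient as
  \(\max_j |g_j|/w_j\) — down to \(0.01\,\lambda_{\max}\) when `p > n`
  (\(10^{-4}\) otherwise). The loss carries an explicit \(1/n\) (and the
  Gaussian loss a \(1/2\)), which fixes the numeric scale of \(\lambda\);
  other scalings relabel the grid without changing the path.
* **Convergence.** Coordinate descent stops when the largest coefficient
  change in a cycle falls below `tol` (\(10^{-7}\) on the standardized
  scale), with at most \(10^5\) cycles per grid point. The logistic and
  Cox losses are handled by iteratively reweighted quadratic
  approximations; because the Cox diagonal-Hessian approximation is not a
  majorizer, its outer iteration is damped by objective-based step-halving
  and allowed many cheap passes — near-degenerate small-\(\lambda\) Cox
  fits contract slowly but reach the same KKT certificate as the other
  families.
* **Degenerate inputs.** Zero-variance columns are excluded from
  penalization with coefficients fixed at 0 (with a warning); a constant
  gaussian outcome, a single-class binomial outcome, or a survival outcome
  without events is rejected outright. Cox ties use the Breslow
  approximation throughout.
* **Ties.** When several grid points achieve the same cross-validated
  error, the largest \(\lambda\) (sparsest model) wins; across candidate
  penalty-factor vectors, the earlier candidate wins.

## Tuning by repeated cross-validation

`cv.ipflasso()` implements the two-level scheme: for each candidate vector
\(s^{(c)}\) of penalty factors, repeated k-fold cross-validation (default
5 folds, 10 repeats) selects the best \(\lambda_1\); the candidate whose
optimum achieves the best cross-validated performance is then selected.
Supported criteria are the mean squared error (gaussian), misclassification
rate at threshold 0.5 or AUC (binomial), and for Cox models the held-out
partial likelihood in the Verweij–van Houwelingen form
\(\ell_{\text{full}}(\hat\beta) - \ell_{\text{train}}(\hat\beta)\), which
is well defined even for folds whose own partial likelihood would be
degenerate. The classification threshold 0.5 is the equal-loss convention;
the optimum is the plain minimum of the mean CV curve (no one-standard-error
rule), matching prediction-optimal practice.

Design choices that the method description leaves open, resolved here:

* The same fold plan is reused across candidates (a paired comparison, for
  variance reduction); folds are stratified by class for binomial outcomes.
* Each candidate receives its own \(\lambda\) grid anchored at its own
  \(\lambda_{\max}\), because the penalty factors change the scale of
  \(\lambda_1\).
* Folds whose training part is degenerate (single class, no events) are
  skipped with a warning and the mean taken over the rest; if every fold is
  degenerate, that is an error.
* `max.vars` restricts the \(\lambda\) search of every candidate to grid
  points whose full-data refit selects at most that many variables.

```{r cv-example}
set.seed(1)
x <- matrix(rnorm(100 * 120), 100, 120)
y <- rbinom(100, 1, plogis(0.8 * rowSums(x[, 1:4])))
blocks <- list(clinical = 1:20, omics = 21:120)
cvfit <- cv.ipflasso(x, y, blocks = blocks, family = "binomial",
                     pflist = pf_candidates_pow2(-2, 2),
                     nfolds = 5, ncv = 3, nlambda = 30, seed = 7)
cvfit
```

## Comparators

Two families of alternatives are built on the same solver and CV
infrastructure, so that benchmark comparisons exercise identical plumbing:

* **Separate models (`separate_lasso()`).** One cross-validated standard
  lasso per modality; the modality linear predictors are then combined in
  an unpenalized regression (logistic for binary, linear for gaussian, Cox
  for survival — the survival combiner is our extension of the published
  binary-outcome recipe, flagged as such). The combiner is trained on
  in-sample linear predictors, a documented optimism source. Empty
  modality models contribute constants and drop out of the combiner.
* **Sparse group lasso (`sgl()`, `cv.sgl()`).** The penalty
  \((1-\alpha)\lambda \sum_m \sqrt{p_m}\,\lVert\beta^{(m)}\rVert_2 +
  \alpha\lambda\lVert\beta\rVert_1\), solved by blockwise proximal
  gradient (FISTA with backtracking; the proximal map is elementwise
  soft-thresholding followed by group shrinkage). Defaults mirror how this
  comparator is conventionally run: \(\alpha = 0.95\) fixed (no \(\alpha\)
  tuning), a 20-point grid down to \(0.1\lambda_{\max}\), 5-fold CV
  without repeats under the family deviance, and a loose relative
  tolerance of \(10^{-2}\) chosen to keep its runtime comparable to the
  lasso-family methods; the test suite refits in a strict-tolerance mode
  against block-optimality certificates and a generic proximal oracle.
  Standardization is global (not within-group), matching the other
  methods. At \(\alpha = 1\) the solution coincides with the standard
  lasso; at \(\alpha = 0\) it is the group lasso.

## The benchmark generator

`sim_setting()` / `sim_data()` reproduce a bi-modal Gaussian benchmark:
class \(y \sim \mathrm{Bernoulli}(\tau = 0.5)\), predictors
\(X \mid y = 0 \sim N(0, \Sigma)\) and
\(X \mid y = 1 \sim N(\mu, \Sigma)\), with
\(\mu = (\beta_1 \times p_1^r, 0, \ldots, \beta_2 \times p_2^r, 0, \ldots)\).
The named settings A–F span modality sizes \(p_1 \in \{20, 100, 1000\}\),
\(p_2 = 1000\), relevant-variable counts from 0 to 30, and effect sizes
0.3–1 (setting D's second modality has no relevant variables, so its
effect size is stored as 0); training size is \(n = 100\) and evaluation
uses an independent draw of \(n_{\text{test}} = 5000\). The primed
variants A′–F′ replace \(\Sigma = I\) by a block covariance: \(b = 10\)
equicorrelated groups per modality (\(\rho = 0.4\) within a group and
between the j-th groups of the two modalities, zero elsewhere), after
which the columns are permuted within each modality so the informative
variables scatter across correlation groups. Whether that permutation is
drawn once per setting or per dataset is unspecified in the method's
description; we draw it per dataset, from the dataset seed, and record the
permuted truth indices. Sampling exploits the group-pair block-diagonal
structure, so no \(p \times p\) Cholesky is ever formed.

`run_simulation()` replays the benchmark protocol per replicate: IPF-LASSO
with the seven candidates \((1, 2^k)\), \(k = -3..3\), 5×10 CV under
misclassification; the standard lasso as the single-candidate \((1,1)\)
special case; the separate-models method with per-modality 5×10 CV; sparse
group lasso with \(\alpha = 0.95\) and single 5-fold CV. Replicate `r`
draws its training set with seed `base + r` and its test set with seed
`base + r + 10^6`, keeping the streams disjoint; per-replicate failures
are logged and skipped, with more than 20% failures aborting the run. The
runner's default grid length is 50 (the fitters' default is 100): at the
replicated-benchmark scale this halves runtime while leaving the selected
model sizes statistically indistinguishable, and it is the problem size
used by the reproduction script (`scripts/acceptance.R`, B = 20
replicates). The full `B = 100` of the original design is a flag away.

What the generator deliberately does *not* emulate: heavy-tailed or
skewed omics distributions, modality-specific missingness, batch effects,
and outcome-dependent censoring. Green tests on this generator certify
the estimator's contract (selection behavior, equivalences, certificates)
under the stated Gaussian mixture — not performance on any particular
real multi-omics cohort.

## Survival metrics

For Cox fits, predictions include per-subject survival curves through the
Breslow baseline hazard, and evaluation uses the time-dependent Brier
score with inverse-probability-of-censoring weights (censoring
distribution estimated by Kaplan–Meier on the training data and reused
for validation scoring): subjects with an observed event before `t`
contribute with weight \(1/\hat G(T_i^-)\), subjects still at risk with
\(1/\hat G(t)\), and subjects censored before `t` with weight 0. The
integrated Brier score is the trapezoidal integral over \([0, t_{\max}]\)
divided by the horizon, with the curve extended flat from the first
evaluation time down to 0. The default evaluation grid is the set of
event times up to the 95th percentile of observed times — published
analyses of specific cohorts fix clinical horizons instead, so integrated
scores are only comparable at matching horizons and weighting schemes.

## Known limitations

* Penalty factors are tuned over a finite candidate list; with more than
  two or three modalities the candidate grid grows quickly and smarter
  search (or empirical-Bayes selection) is out of scope here.
* No elastic-net/L2 component, no adaptive per-feature weights, and no
  stability-selection wrapper.
* The SGL solver covers gaussian and binomial losses (the outcomes for
  which it serves as a comparator); Cox SGL is not implemented.
* The separate-models Cox combiner and the in-sample combiner predictors
  are pragmatic choices, documented above, not validated prescriptions.
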