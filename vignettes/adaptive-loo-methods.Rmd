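---
title: "Adaptive importance sampling for Bayesian LOO: models, transformations, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive importance sampling for Bayesian LOO: models, transformations, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Leave-one-out (LOO) cross-validation is the gold standard for estimating the
out-of-sample behaviour of a Bayesian model, but refitting the model n times
is usually unaffordable. For a model with posterior density
$\pi(\theta\mid\mathcal D)$ and pointwise likelihood
$\ell(\theta\mid d_i)$, the LOO posterior for observation $i$ satisfies

$$\frac{\pi(\theta\mid\mathcal D^{(-i)})}{\pi(\theta\mid\mathcal D)}
  \propto \frac{1}{\ell(\theta\mid d_i)},$$

so LOO expectations can be estimated from the full-data posterior draws
$\theta_1,\dots,\theta_s$ with self-normalized importance weights
$\nu_{ik} \propto 1/\ell(\theta_k\mid d_i)$. These $1/\ell$ weights are
notoriously fat-tailed: when the held-out point is influential, the weight
variance can be infinite and the estimator breaks down silently. The
standard remedy is Pareto-smoothed importance sampling (PSIS): fit a
generalized Pareto distribution (GPD) to the largest weights, replace them
by its expected order statistics, and use the fitted shape $\hat k$ as a
reliability diagnostic, with $\hat k > 0.7$ signalling failure.

This package implements the next line of defence: when $\hat k > 0.7$,
*adapt* the proposal by pushing the draws through a perturbative bijection

$$T_i(\theta) = \theta + h\,Q_i(\theta), \qquad 0 < h \ll 1,$$

chosen so the transformed sample sits closer to the LOO posterior, and
reweight with the change-of-variables-corrected weights

$$\eta_{ik} \propto \mathcal J_{T_i}(\theta_k)\,
  \frac{1}{\ell(\phi_k\mid d_i)}\,
  \frac{\pi(\phi_k\mid\mathcal D)}{\pi(\theta_k\mid\mathcal D)},
  \qquad \phi_k = T_i(\theta_k),$$

where the posterior ratio expands exactly into a prior ratio times all $n$
pointwise likelihood ratios, and $\mathcal J_{T}$ is the Jacobian
determinant of the map. An observation counts as rescued as soon as *any*
transformation brings its post-transformation $\hat k$ under the threshold;
only the remaining observations would need an actual refit.

## The transformation suite

Five fields $Q_i$ are provided, attempted in a configurable order:

* **PMM1 / PMM2 (partial moment matching).** Move every draw a fraction
  $\bar h$ of the way from the plain sample moments to the
  importance-weighted moments: PMM1 translates to the weighted mean (log
  Jacobian 0); PMM2 additionally rescales each component toward the
  weighted marginal variance (a diagonal affine map whose log Jacobian is
  the same for all draws). Setting $\bar h = 1$ recovers the classical full
  moment-matching maps MM1/MM2, which are available as method labels and
  implemented by delegation — there is no separate code path, and no
  split-sampling scheme is layered on top, so MM1/MM2 serve as plain
  comparison baselines.
* **KL descent.** A single forward-Euler step along the gradient flow that
  minimizes the KL divergence from the LOO target to the transformed
  proposal. For sigmoidal classifiers this reduces to
  $Q^{KL}_i = (-1)^{y_i}\,\pi(\theta\mid\mathcal D)\,
  e^{\mu_i(\theta)(1-2y_i)}\nabla\mu_i$, equivalently
  $\pi(\theta\mid\mathcal D)\nabla(1/\ell)$.
* **Var descent.** The analogous single step minimizing the variance of the
  importance-sampling estimator of the complement outcome probability; the
  same closed form with the exponent doubled. The general composite form
  (density × ratio × gradient of ratio) is used only as a finite-difference
  test oracle; the sigmoidal closed form is canonical in the code.
* **LL descent.** A comparison baseline: a step down the held-out point's
  negative log-likelihood gradient, $Q^{LL}_i = (\sigma(\mu_i)-y_i)\nabla\mu_i$,
  with the same step-size rule. Its original derivation is reproduced here
  only as this plain gradient step, and it is flagged as a baseline, not a
  recommended method.

### Step size

All gradient fields use the rule
$h_i = \bar h\,\min_{k,\alpha} \mathrm{sd}_\alpha / |Q_i(\theta_k)_\alpha|$,
which guarantees that no component of any draw moves more than $\bar h$
marginal posterior standard deviations. The standard deviations are the
plain (unweighted) marginal standard deviations of the draws — the only
posterior available before adaptation. Components with zero variance are
excluded from the minimum and pass through every transformation unchanged.
The whole grid $\bar h = 4^{-r}$, $r = 0,\dots,10$, is scanned per method,
with all magnitudes carried in log space: the unnormalized posterior factor
inside $Q$ can exceed double range by hundreds of orders of magnitude, but
only the products $h\,Q$ and $h\,\pi$ are ever exponentiated, and those are
bounded by the step-size rule. A consequence exercised in the tests is that
the realized steps and Jacobians are exactly invariant to the unknown
posterior normalizer.

### Jacobian determinants

* **Logistic regression, KL/Var:** the Jacobian of $Q$ is rank one, so the
  determinant has the closed form
  $1 + h(-1)^{y}\pi(\theta\mid\mathcal D)e^{c\mu(1-2y)}
  x^\top[\nabla\log\pi(\theta\mid\mathcal D) + c(1-2y)x]$, $c \in \{1,2\}$.
* **One-hidden-layer ReLU network, KL/Var:** the mean-function Hessian has
  at most $2d$ nonzero eigenpairs with closed forms
  ($\lambda_k^\pm = \pm[a'((z_1)_k)\sum_j x_j^2]^{1/2}$, eigenvectors built
  from $a'((z_1)_k)x$ in the W1 row-$k$ slot and $\pm e_k$ in the W2 slot);
  the determinant is evaluated in the invariant subspace spanned by those
  eigenvectors plus the two rank-one factor vectors, a dense matrix of
  dimension at most $2d+2$, with the orthogonal complement contributing
  exactly 1. We verified the printed eigenvalue formula against a dense
  finite-difference Hessian: no extra $|W_2|$ factor is required, because
  the ReLU derivative satisfies $a'^2 = a'$.
* **Everything else (including LL):** the first-order rule
  $|1 + h\,\nabla\!\cdot\!Q|$. For rank-one Jacobians this rule is *exact*
  (the second and higher elementary symmetric functions vanish), so for
  logistic regression it coincides with the closed form to machine
  precision; against the exact ReLU rule its error decays as $O(h^2)$,
  which the test suite verifies by a log–log slope fit. For both model
  kinds the Laplacian of $\mu$ is identically zero, so
  $\nabla\!\cdot\!Q^{LL} = \sigma'(\mu)\lVert\nabla\mu\rVert^2$.

### Moment-matching weights

PMM1/PMM2 need a weight vector $\nu$; the orchestrator feeds them the
Pareto-smoothed raw weights rather than the unsmoothed ones. The weighted
moments are exactly the quantities the raw weights estimate worst when the
tail is unstable; smoothing first makes the targets finite-variance at the
cost of some bias, which the $\hat k$ re-check after transformation keeps
honest. The exported `pmm1()`/`pmm2()` accept any simplex vector, so the
unsmoothed choice remains available.

## PSIS implementation

The GPD shape is estimated by the Zhang–Stephens profile-posterior point
estimate with the usual weak shape regularization toward 0.5 (prior weight
10), stable down to tails of 5 excesses. The tail size is
$M = \lceil\min(0.2s,\,3\sqrt s)\rceil$, the threshold is the $(s{-}M)$-th
order statistic of the weights, and the replacement uses rank quantiles
$(j-0.5)/M$ of the fitted GPD, capped at the largest raw weight. $\hat k$
is taken from the fit itself — fit first, smooth second, the only order
consistent with replacing weights by quantiles of an already-fitted
distribution. Degenerate tails (no variation above the threshold) report
$\hat k = -\infty$ and are treated as *stable*: constant weights are the
best case, not a failure. Tails with fewer than 5 positive excesses, or
samples with fewer than 25 draws, report `NA` and skip smoothing.

One subtlety: "smoothing never increases the largest weight" is a theorem
about the order-statistic replacement (each replaced value is capped at the
raw maximum) but not about the renormalized simplex output — on extremely
heavy inputs the replaced tail can lose enough mass that renormalization
raises the maximum. The `is_weights` container therefore keeps the
unnormalized replacement in `log_ratios` alongside the renormalized
`weights`, and the tests assert the guaranteed form.

## The per-observation procedure

For each observation: compute raw ratios, smooth, read $\hat k$; if
$\hat k \le 0.7$, stop — stable observations are never transformed, even if
a transformation could do better. Otherwise loop over methods × step-size
grid, recompute $\eta$, smooth, re-read $\hat k$, and stop at the first
success. No multiplicity correction is applied across the scanned pairs;
"any transformation under the threshold" is adopted as the success
criterion deliberately, since the purpose is screening for refits, not
hypothesis testing. Observations are processed independently — records
depend only on (draws, data, index, config) — so permuting the dataset
permutes the report. When nothing succeeds the report records the failure
and downstream metrics (LOO predictive probability, elpd, LOO-IC, ROC/PRC)
use the globally minimizing pair's weights as the best available estimate;
by default adapted observations use the *winner's* weights, with
`use_best_khat = TRUE` switching to the global-minimum-$\hat k$ weights via
an exhaustive scan (which of the two a published ROC curve should use is
genuinely underdetermined; the winner is cheaper and is the default).

Metrics use the transformed draws where a transformation won: the LOO
predictive probability is $\sum_k w_k\,\sigma(\mu(\phi_k,x_i))$ and
$\mathrm{elpd}_i = \log\sum_k w_k\,\ell(\phi_k\mid d_i)$, with
LOO-IC $= -2\sum_i \mathrm{elpd}_i$. Draws from a variational
approximation can instead be corrected through the
density-ratio weights of `variational_corrected_log_weights()`, which
cancel both unknown constants against the variational density.

## The synthetic study conditions

The generator emulates the regime in which $1/\ell$ LOO importance sampling
is known to break: many more predictors than observations with a few strong
sparse effects, as in expression-array classification. Defaults are
$n = 50$ observations, $p_x = 300$ standard-normal predictors (optionally
equicorrelated through a single common-factor knob), 5 true coefficients of
magnitude 2 and alternating sign, and Bernoulli labels through the logistic
link. These sizes keep a full 20-replicate experiment with the complete
method suite and the 11-point step grid in the minutes range on one CPU
while preserving the defining $n \ll p$ character of microarray-scale
benchmarks (typically tens of samples against a thousand or more probes);
with the simplified Student-t shrinkage prior
(df 3, scale 0.5) on a logistic model fitted by adaptive random-walk
Metropolis (1000 retained draws), 60–70% of observations typically show raw
$\hat k > 0.7$, and the transformation suite rescues essentially all of
them — the qualitative ordering the method claims.

What the generator does *not* emulate: realistic gene–gene correlation
structure beyond equicorrelation, the regularized horseshoe prior (its
latent scales are not part of the flat draw format; the Student-t marginal
is the documented stand-in), and converged high-dimensional MCMC — the
Metropolis sampler mixes slowly at $p = 300$ and its draws should be read
as "a posterior-shaped sample that produces realistic weight instability",
not as a trustworthy posterior. Passing tests therefore demonstrate the
adaptive machinery, not end-to-end inferential validity on real microarray
data.

Quadrature ("grid") posteriors at $p \le 2$ are the exact-truth channel:
brute-force LOO by refitting on each fold is computed by quadrature and
treated as exact, and IS-LOO must agree within three importance-sampling
standard errors per observation. At $3 \le p \le 5$ the Metropolis sampler
plays the refit role and comparisons use combined Monte Carlo bands.

## Numerical choices and degenerate inputs

* Log-space everywhere: weights and densities are only exponentiated at the
  self-normalization boundary or after the step-size rule has bounded them.
* ReLU derivative at exactly 0 is 0 (left-continuous step); Hessian
  eigenpairs of dead units are reported as eigenvalue 0 with zero vectors.
* PMM2 refuses step sizes that make any diagonal factor non-positive
  ("transformation not bijective"); gradient transforms with an identically
  zero field return the identity with method label `"identity"`.
* A degenerate Jacobian (determinant exactly 0) in any scanned pair is
  recorded and skipped, never fatal to the run.
* Zero-variance parameter components are excluded from the step-size
  minimum and pass through all transformations unchanged.
* GPD fitting on tails with tied weights drops zero excesses (they carry no
  tail information); an all-tied tail is the degenerate stable case.
* Child seeds for every stochastic operation derive deterministically from
  (global seed, observation index, operation label), so per-observation
  results do not depend on iteration order.

## Known limitations

* Exact Jacobians cover logistic regression and one hidden ReLU layer;
  deeper networks fall back to the first-order rule (accurate to $O(h^2)$,
  which is usually ample at the step sizes the rule selects, but unverified
  against an exact form there).
* The Metropolis sampler is a convenience, not a production MCMC; for real
  analyses bring draws from your own sampler via `read_draws()`.
* Multi-step gradient-flow integration and learned transformations are out
  of scope, as are survival-model heads and softmax/multiclass outputs
  (softmax reduces to the sigmoid under a change of variables and is not
  separately implemented).
* The ROC/PRC module requires both classes present and groups tied scores;
  AUPRC uses the step-wise (average-precision style) area, which does not
  interpolate.
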