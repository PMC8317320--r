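---
title: "Ridge-penalized mixed-effects logistic regression: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ridge-penalized mixed-effects logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmelm)
```

## The problem and the model

Clustered binary responses $y_{ij}$ (observation $j$ of subject $i$,
$i = 1,\dots,n$) are modelled with a subject-level random effect:

$$\operatorname{logit} P(y_{ij} = 1 \mid b_i)
  = \mathbf{x}_{ij}^\top \boldsymbol\beta + \mathbf{z}_{ij}^\top \mathbf{b}_i,
  \qquad \mathbf{b}_i \sim N_q(0, Q).$$

When columns of $X$ are nearly collinear, the weighted cross-product
$X^\top W X$ is ill-conditioned and the ML estimator of $\boldsymbol\beta$
has inflated variance: estimates swap signs between nearly equivalent
linear combinations, confidence intervals widen, and tests lose power. The
ridge remedy adds an L2 penalty on the fixed effects. Working on the
Breslow–Clayton (penalized quasi-likelihood) approximation to the marginal
likelihood, the fitted criterion is

$$\ell^\lambda(\boldsymbol\beta, \mathbf b) =
  \sum_{ij}\left[ y_{ij}\eta_{ij} - \log(1 + e^{\eta_{ij}}) \right]
  - \lambda\,\boldsymbol\beta^\top\boldsymbol\beta
  - \tfrac12\,\mathbf b^\top (I_n \otimes Q^{-1})\,\mathbf b .$$

$\lambda = 0$ is the unpenalized mixed-effects logistic fit used as the
comparison baseline throughout. Only the canonical logit link and a single
grouping factor are supported; crossed or nested random effects and
quadrature-based marginal likelihoods are out of scope.

Two conventions worth noting. First, the penalty is
$\lambda \beta^\top \beta$ (not $\lambda/2$), so its gradient is
$-2\lambda\beta$ and its curvature contributes $2\lambda$ to the
fixed-effect information diagonal; `estimate_lambda()` and all reported
$\lambda$ values are on this scale. Second, the gradient of the
random-effect term is $-Q^{-1}\mathbf b_i$, consistent with the $\tfrac12$
in the criterion; a `b_score_factor = 2` compatibility switch reproduces the
doubled factor that appears in part of the literature, at the cost of the
score no longer being the exact gradient (the default is verified against
numeric differentiation in the test suite).

## Estimation

The stacked coefficient vector $\boldsymbol\delta = (\boldsymbol\beta,
\mathbf b_1, \dots, \mathbf b_n)$ is updated by a hybrid of two classical
steps, which in practice converges faster than either alone:

1. a gradient-ascent step $\boldsymbol\delta \leftarrow \boldsymbol\delta +
   \vartheta\, \mathbf s^\lambda$ with the quadratic-model step size
   $\vartheta = \mathbf s^\top\mathbf s / \mathbf s^\top F^\lambda \mathbf s$;
2. a Fisher-scoring step $\boldsymbol\delta \leftarrow \boldsymbol\delta +
   (F^\lambda)^{-1}\mathbf s^\lambda$, with score and information recomputed
   after step 1.

$F^\lambda = A^\top \Psi A + U + 2\lambda\,\mathrm{diag}(\text{penalized})$
with $A = [X, Z]$, $\Psi = \mathrm{diag}(\pi(1-\pi))$ and $U$ the
block-diagonal matrix of $p$ zeros followed by $n$ copies of $Q^{-1}$, has
an arrowhead structure: dense $p \times p$ fixed-effect block, $n$ small
$q \times q$ subject blocks, zero subject–subject blocks. All solves go
through the $p \times p$ Schur complement
$S = F_{\beta\beta} - \sum_i F_{\beta i} F_{ii}^{-1} F_{i\beta}$, so one
iteration costs $O(Np^2)$ and the dense $(p + nq)$ matrix is never formed
(fitting 2000 subjects takes a couple of seconds). Both half-steps are
guarded by step halving (up to 10 halvings, then the step is dropped), so
the criterion trace is non-decreasing; the bare updates can overshoot from
poor starts. Initialization: $\boldsymbol\beta$ from a pooled logistic GLM,
$\mathbf b = 0$, $Q = I$. Fitting is deterministic.

The variance component is updated by EM,

$$\hat Q \leftarrow \frac1n \sum_i \left( \hat v_{ii} +
  \hat{\mathbf b}_i \hat{\mathbf b}_i^\top \right),$$

where $v_{ii}$ is subject $i$'s diagonal block of $(F^\lambda)^{-1}$,
computed through the same Schur complement. The result is symmetrized and
its eigenvalues floored at `variance_floor` ($10^{-8}$).

### Convergence and the zero-variance boundary

The fit stops when $\max_k |\Delta\delta_k| / (1 + |\delta_k|) <
10^{-6}$ and the relative Frobenius change of $Q$ drops below $10^{-6}$,
capped at 200 outer iterations. The mixed-relative denominator $1 +
|\delta_k|$ matters: random effects sit numerically at zero in many fits,
where a purely relative criterion would never trigger.

With two binary observations per subject the within-cluster information is
weak and the EM sequence for a scalar $Q$ frequently drifts toward the zero
boundary — the analogue of a singular fit in other mixed-model software.
Near the boundary the EM map behaves like $Q' \approx Q - cQ^2$, a
*sub-geometric* decay that no iteration cap accommodates. Two numerical
devices handle this (random-intercept models only): Aitken extrapolation of
the scalar EM sequence every fourth iteration (accepted only for a stable
contraction estimate and a finite, positive target), and boundary
detection — if $Q$ falls below $10^{-4}$, or decreases for 25 consecutive
iterations while below $0.05$, it is snapped to the floor and the fit is
flagged `boundary`. Boundary fits are converged fits: their fixed effects
coincide with the pooled logistic GLM, which the test suite asserts. These
devices change the path, not the fixed point; without them roughly half the
low-ICC simulation fits would exhaust the iteration cap.

## The shrinkage parameter

With weights $\hat W$ at the pilot fit, eigendecompose
$X^\top \hat W X = \gamma^\top \Lambda \gamma$ (rows of $\gamma$ are
eigenvectors; only ridge-penalized columns enter) and rotate
$\hat\alpha = \gamma\hat\beta$. With $m_k = \sqrt{\hat\sigma^2 /
\hat\alpha_k^2}$, the default plug-in is the geometric mean

$$\hat\lambda = \Big( \prod_{k=1}^{p} m_k \Big)^{1/p}
             = \hat\sigma \Big/ \Big(\prod_k |\hat\alpha_k|\Big)^{1/p},$$

one member of the Hoerl–Kennard/Kibria family of closed-form ridge rules.
$\hat\sigma^2 = 1$ by default (the Bernoulli dispersion convention for
logistic ridge); a Pearson-statistic estimate $\chi^2/(N-p)$ is available.
Because $\lambda$ depends only on $|\hat\alpha_k|$, it is invariant to
eigenvector ordering and sign, which the tests assert. Two design choices
deserve explanation:

* **Geometric mean of $m_k$, not of $1/m_k$.** Both variants circulate in
  the ridge literature. The reciprocal, $(\prod_k 1/m_k)^{1/p} =
  (\prod_k|\hat\alpha_k|)^{1/p}/\hat\sigma$, *weakens* the penalty exactly
  when coefficients are small relative to their noise — the strong
  collinearity, weak signal regime that motivates ridge in the first place.
  In the simulation design below it yields $\lambda \approx 0.3$ against
  information diagonals around 15, i.e. a numerically void penalty and a
  ridge fit indistinguishable from the unpenalized one. The $m_k$ form
  yields $\lambda \approx 3$–$4$ and the variance reduction ridge exists to
  deliver. The reciprocal remains available as `rule = "printed"`.
* **A plug-in from the unpenalized pilot, not a fixed-point iteration.**
  Rules of this family are defined on *unpenalized* rotated coefficients
  (as Hoerl–Kennard-type rules are on OLS estimates). Re-estimating
  $\lambda$ from the current penalized $\hat\beta$ at every outer iteration
  (`lambda = "iterative"`, provided as an option) creates a feedback loop —
  shrinkage reduces $|\hat\alpha|$, which raises $\lambda$, which shrinks
  further — whose fixed point over-penalizes by roughly a factor of four in
  the settings studied here. The default `"auto"` therefore computes
  $\lambda$ once, from the pooled-GLM pilot that also initializes
  $\boldsymbol\beta$, and holds it fixed.

## Inference

The coefficient covariance is the sandwich
$\big[(F^\lambda)^{-1} F^0 (F^\lambda)^{-1}\big]_{\beta\beta}$, where $F^0$
is the information with $\lambda = 0$ but the random-effect term retained,
both at the converged state and both evaluated blockwise. The chain
sometimes written "sandwich $= [I(\beta)]^{-1}$" holds only at
$\lambda = 0$; the naive form (the $\beta$ block of $(F^\lambda)^{-1}$
alone) is available as `variance_mode = "naive"`, and the two are verified
to coincide at $\lambda = 0$. Tests are non-exact t statistics $t_k =
\hat\beta_k / SE(\hat\beta_k)$: under penalization the statistic has no
exact t-distribution, and the p-values (t reference with $N - p$ degrees of
freedom; a normal reference is available via `df_mode`) should be read as
approximate. A global likelihood-ratio test compares nested fits on the
unpenalized criterion at their own estimates. Collinearity diagnostics
standardize columns to unit length *without centering* (the Belsley
convention — conventions differ and condition numbers are not comparable
across them), report condition indices $\sqrt{\mu_1/\mu_j}$, and return the
plain correlation matrix alongside.

```{r example}
cell  <- simulation_cell(n = 40, icc = 0.2, rho = 0.9, seed = 7)
d     <- simulate_dataset(cell, 1)
plain <- rmelm(d, lambda = "zero")
ridge <- rmelm(d, lambda = "auto")
round(cbind(plain = plain$se_beta, ridge = ridge$se_beta), 3)
collinearity_diagnostics(d$X)$condition_number
```

## The simulation harness

`simulation_cell()` / `run_cell()` / `run_grid()` implement a Monte Carlo
design for clustered binary data under controllable collinearity: $n \in
\{30, 50, 100\}$ subjects, two observations each, true
$\boldsymbol\beta = (0.2, 0.4, -0.3)$, random intercept only ($q = 1$; all
structure studied here is consistent with that choice, which is the
package default).

* **Collinear predictors.** Per row, $x_1 = \sqrt{1-\rho}\,a_1 +
  \sqrt\rho\,c$ and $x_2 = \sqrt{1-\rho}\,a_2 + \sqrt\rho\,c$ with
  independent standard normals $a_1, a_2, c$: unit variances and
  $\operatorname{cor}(x_1, x_2) = \rho \in \{0.7, 0.8, 0.9, 0.95\}$ by the
  shared common factor. A degenerate variant that rescales a single draw
  per predictor — and therefore produces *uncorrelated* predictors — is
  kept behind `generator = "printed"` for comparison only. $x_3$ is
  independent: its estimator should be, and is, insensitive to $\rho$.
* **Response correlation.** ICC $\in \{0.2, 0.5, 0.8\}$ is mapped to the
  random-intercept variance on the latent-logistic scale,
  $\sigma_b^2 = \mathrm{ICC}\,(\pi^2/3)/(1-\mathrm{ICC})$, i.e. about
  0.82, 3.29 and 13.2. No other mapping reproduces itself from the fitted
  model, and the round trip is tested.
* **Metrics.** Per coefficient and model: MSE (with Monte Carlo standard
  error), relative bias $100(\overline{\hat\beta}_k - \beta_k)/\beta_k$,
  and empirical power at $\alpha = 0.05$ using the same test machinery as
  ordinary fits. Replicates whose fit errors or fails to converge are
  excluded and counted; above 5 % lost, the cell warns. Replicate seeds
  are pure functions of (master seed, cell index, replicate index), so
  grids are reproducible at any parallelism level and any replicate can be
  regenerated alone.
* **Sizes.** `reps = 1000` by default; the acceptance script uses 500 for
  the reference cell and 200 per grid cell, sizes at which the Monte Carlo
  standard error of a cell MSE is a few percent of its value.

## What the simulations do and do not show

The generator emulates balanced two-visit data with Gaussian predictors, a
correctly specified random intercept and no missingness. Real cohort data
(ordinal exposure scores, unbalanced visits, informative dropout,
misspecified random-effect distributions) can behave differently; passing
the simulation suite shows the estimator does what it claims under the
stated design, not that it is robust beyond it.

Two limitations of the $\lambda = 0$ baseline deserve emphasis. First,
penalized quasi-likelihood attenuates fixed effects for binary data with
few observations per cluster, increasingly so as the random-effect variance
grows; at ICC = 0.8 ($\sigma_b^2 \approx 13$) the attenuation reaches tens
of percent, so this baseline is *not* interchangeable with
quadrature-or-Laplace ML fits (e.g. `glmer`) at high ICC — grid-median
absolute relative bias lands near 28 % here where an ML fit would sit
around 8 %. The ridge estimator inherits the same approximation; its
comparisons with the baseline are internally consistent. Second, there is
an information ceiling: 60 Bernoulli observations carry Fisher information
of order $N\bar w \approx 12$ per unit-variance predictor, so any honest
standard error for a coefficient of 0.2 exceeds 0.25 and no test of it can
approach 80 % power at $n = 30$ — power figures of that size at such sample
sizes can only arise from variance formulas dominated by the penalty rather
than the data (the naive mode here, with large $\lambda$, behaves exactly
so). The sandwich default keeps the standard errors tied to the data; the
corresponding empirical power gains of the ridge fit are real but modest at
small $n$, and its bias–variance trade is the primary benefit.

## Numerical choices, in one place

| Quantity | Value | Where |
|---|---|---|
| probability clamp $\epsilon$ | $10^{-10}$ | weights, log-likelihood |
| convergence tolerances | $10^{-6}$ (coefficients and $Q$) | `rmelm_control()` |
| outer iteration cap | 200 | `rmelm_control()` |
| step halvings | 10, then the step is dropped | hybrid update |
| $Q$ eigenvalue floor | $10^{-8}$ | EM update |
| boundary snap | $Q < 10^{-4}$, or 25 decreasing iterations below 0.05 | fit loop |
| zero rotated coefficient | floored at $10^{-8}$, warned | `estimate_lambda()` |
| default dispersion | $\hat\sigma^2 = 1$ | `estimate_lambda()` |
| t-test degrees of freedom | $N - p$ | `coefficient_tests()` |

Subjects need not be contiguous in input files: rows are grouped by subject
identifier on construction. For user data read from CSV an intercept is
added by default and excluded from the penalty (standard ridge practice);
the simulation design carries no intercept.
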