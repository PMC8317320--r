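# rmelm — ridge mixed-effects logistic models for correlated binary responses

Longitudinal and clustered studies with binary outcomes are routinely
analyzed with mixed-effects logistic regression. When the fixed-effect
predictors are collinear — as often happens with batteries of related
exposure scores — the determinant of the weighted cross-product `X'WX`
collapses, the variance of the maximum-likelihood coefficients inflates, and
tests lose power. **rmelm** fits the mixed-effects logistic model with an
optional ridge (L2) penalty on the fixed effects to trade a controlled bias
for a large variance reduction, together with the inference and diagnostic
machinery needed around it. It is aimed at biostatisticians analyzing
clustered binary data with correlated covariates, and at methodologists who
want a transparent, fully scriptable penalized-GLMM baseline.

## The model

For observation *j* of subject *i*,

    logit P(y_ij = 1 | b_i) = x_ij' beta + z_ij' b_i,   b_i ~ N_q(0, Q)

Estimation maximizes the Breslow–Clayton penalized quasi-likelihood with a
ridge term:

    l_lambda(beta, b) = sum_ij [ y_ij eta_ij - log(1 + exp(eta_ij)) ]
                        - lambda * beta' beta  - (1/2) b' (I_n ⊗ Q^{-1}) b

Each outer iteration performs a hybrid coefficient update — one
gradient-ascent step with step size `theta = s's / s'Fs` followed by one
Fisher-scoring step `delta + F^{-1} s`, both step-halved — and one EM update
of `Q` from the posterior blocks of the arrowhead Fisher matrix, solved
through its Schur complement (the dense `(p + nq)` matrix is never formed).
The shrinkage parameter is a closed-form plug-in: with
`X'WX = gamma' Lambda gamma` and rotated coefficients `alpha = gamma beta`,

    lambda = ( prod_k m_k )^(1/p),   m_k = sqrt(sigma^2 / alpha_k^2),

estimated once from the unpenalized pooled-logistic pilot. Standard errors
come from the sandwich `(F^lambda)^{-1} F^0 (F^lambda)^{-1}` (fixed-effect
block), tested with non-exact t statistics `beta_k / SE(beta_k)`. `lambda =
"zero"` gives the unpenalized mixed-effects logistic fit, the natural
baseline. See the methods vignette (`vignettes/ridge-mixed-logistic.Rmd`)
for assumptions, parameter conventions and limitations.

## Worked example

Simulate 40 subjects, two observations each, with two predictors correlated
at 0.9, and compare the unpenalized and ridge fits:

```r
library(rmelm)
cell  <- simulation_cell(n = 40, icc = 0.2, rho = 0.9, seed = 7)
d     <- simulate_dataset(cell, 1)
plain <- rmelm(d, lambda = "zero")
ridge <- rmelm(d, lambda = "auto")
print(plain)
print(ridge)
```

```
Mixed-effects logistic fit: 80 obs, 40 subjects | lambda = 0 (zero) | converged after 30 iter
   estimate     se odds_ratio t_value p_value
x1  -0.3277 0.5797     0.7206 -0.5653  0.5735
x2   0.3888 0.5824     1.4752  0.6676  0.5064
x3  -0.2835 0.2382     0.7532 -1.1902  0.2376
Random-effects covariance (diagonal): 0.14

Ridge mixed-effects logistic fit: 80 obs, 40 subjects | lambda = 8.563 (auto) | converged after 34 iter
   estimate      se odds_ratio t_value p_value
x1 -0.01697 0.09227     0.9832 -0.1839  0.8546
x2  0.04140 0.09224     1.0423  0.4488  0.6548
x3 -0.13749 0.12036     0.8715 -1.1424  0.2568
Random-effects covariance (diagonal): 1e-08  [boundary]
```

The collinear pair (`x1`, `x2`, true effects 0.2 and 0.4) gets wildly
unstable unpenalized estimates — note the flipped sign on `x1` and standard
errors near 0.6 — while the ridge fit shrinks the pair toward zero and cuts
their standard errors by a factor of six. `[boundary]` flags a
random-intercept variance estimated at the zero boundary (a singular fit,
common with two binary observations per subject). Monte Carlo comparisons
over a grid of sample sizes, intraclass correlations and predictor
correlations:

```r
grid <- run_grid(n = c(30, 50, 100), icc = c(0.2, 0.5, 0.8),
                 rho = c(0.7, 0.8, 0.9, 0.95), reps = 500, seed = 1)
grid$coefficients   # tidy: n, icc, rho, model, coefficient, mse, relbias, power
```

A thin command-line wrapper is included (`inst/scripts/rmelm`) with `fit`,
`simulate` and `diagnose` subcommands over the same functions.

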