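#' Control parameters for the penalized fit
#'
#' @param max_outer_iter maximum number of outer iterations (each outer
#'   iteration is one hybrid coefficient update plus one EM covariance
#'   update). Default 200.
#' @param tol_delta convergence tolerance on the coefficient vector: the fit
#'   stops when `max |delta_new - delta_old| / (1 + |delta_old|)` falls below
#'   it. Default 1e-6.
#' @param tol_Q convergence tolerance on the relative Frobenius change of the
#'   random-effects covariance. Default 1e-6.
#' @param step_halving_max halvings allowed per update step when the
#'   penalized log-likelihood would decrease. Default 10.
#' @param lambda_rule shrinkage plug-in rule passed to [estimate_lambda()]:
#'   `"gm"` (default) or `"printed"`.
#' @param sigma2_mode dispersion estimate for the shrinkage rule: `"fixed"`
#'   (sigma^2 = 1, the Bernoulli convention) or `"pearson"`.
#' @param variance_mode coefficient covariance: `"sandwich"` (default) or
#'   `"naive"`; see [sandwich_cov_beta()].
#' @param df_mode reference distribution for coefficient tests: `"t"` with
#'   N - p degrees of freedom (default) or `"normal"`.
#' @param b_score_factor see [model_state()]. Default 1.
#' @param accelerate_Q use Aitken extrapolation on the scalar EM variance
#'   sequence (random-intercept models only)? Default `TRUE`.
#' @param variance_floor lower floor applied to eigenvalues of the EM
#'   covariance update. Default 1e-8.
#' @param fix_Q keep Q at its initial value (skip the EM step)? Default
#'   `FALSE`.
#' @param fix_b keep all random effects at zero (pooled logistic fit)?
#'   Default `FALSE`.
#' @param seed optional integer; fitting itself is deterministic, the seed is
#'   only recorded into results for provenance.
#' @return list of class `"rmelm_control"`.
#' @export
rmelm_control <- function(max_outer_iter = 200L, tol_delta = 1e-6,
                          tol_Q = 1e-6, step_halving_max = 10L,
                          lambda_rule = c("gm", "printed"),
                          sigma2_mode = c("fixed", "pearson"),
                          variance_mode = c("sandwich", "naive"),
                          df_mode = c("t", "normal"),
                          b_score_factor = 1, accelerate_Q = TRUE,
                          variance_floor = 1e-8, fix_Q = FALSE,
                          fix_b = FALSE, seed = NULL) {
  stopifnot(max_outer_iter >= 1L, tol_delta > 0, tol_Q > 0)
  structure(list(max_outer_iter = as.integer(max_outer_iter),
                 tol_delta = tol_delta, tol_Q = tol_Q,
                 step_halving_max = as.integer(step_halving_max),
                 lambda_rule = match.arg(lambda_rule),
                 sigma2_mode = match.arg(sigma2_mode),
                 variance_mode = match.arg(variance_mode),
                 df_mode = match.arg(df_mode),
                 b_score_factor = b_score_factor,
                 accelerate_Q = accelerate_Q,
                 variance_floor = variance_floor,
                 fix_Q = fix_Q, fix_b = fix_b, seed = seed),
            class = "rmelm_control")
}

#' Gradient-ascent step size
#'
#' The scalar step `theta = (s's) / (s' F s)` used for the gradient-ascent
#' half of the hybrid update, evaluated through the block structure without
#' forming the dense Fisher matrix.
#'
#' @param score_vec score vector of length p + n q.
#' @param fisher an [fisher_information()] object.
#' @return scalar step size.
#' @export
step_size <- function(score_vec, fisher) {
  denom <- sum(score_vec * fisher_times(fisher, score_vec))
  if (!is.finite(denom) || denom <= 0) {
    stop("s' F s <= 0: penalized Fisher matrix is not positive definite")
  }
  sum(score_vec^2) / denom
}

state_replace_delta <- function(state, delta, n, p, q) {
  state$beta <- delta[seq_len(p)]
  state$b <- matrix(delta[-seq_len(p)], nrow = n, ncol = q, byrow = TRUE)
  state
}

state_delta <- function(state) {
  c(state$beta, as.vector(t(state$b)))
}

#' One hybrid coefficient update
#'
#' Performs one gradient-ascent step `delta + theta s` followed by one
#' Fisher-scoring step `delta + F^{-1} s`, recomputing the score and the
#' Fisher blocks in between. The Fisher solve uses the arrowhead structure
#' ([arrowhead_solve()]). Each step is guarded by step-halving: if the
#' penalized log-likelihood would decrease, the increment is halved up to
#' `step_halving_max` times and dropped entirely if it still decreases, so
#' the criterion never moves downhill.
#'
#' @inheritParams linear_predictor
#' @param fisher optional precomputed [fisher_information()] at `state`.
#' @param control an [rmelm_control()] object.
#' @return the updated `"rmelm_state"`, with attribute `"pll"` holding the
#'   penalized log-likelihood after the update.
#' @export
hybrid_update <- function(design, state, fisher = NULL,
                          control = rmelm_control()) {
  p <- design$p; q <- design$q; n <- design$n
  pll0 <- penalized_loglik(design, state)

  advance <- function(state, pll_now, newton) {
    s <- rmelm_score(design, state)
    if (control$fix_b) {
      # pooled path: Newton / gradient ascent in beta alone
      s_b <- s[seq_len(p)]
      if (max(abs(s_b)) < 1e-12) return(list(state = state, pll = pll_now))
      fb <- if (newton || is.null(fisher)) fisher_information(design, state)
            else fisher
      step_beta <- if (newton) {
        solve(fb$F_bb, s_b)
      } else {
        denom <- sum(s_b * drop(fb$F_bb %*% s_b))
        if (denom <= 0) stop("s' F s <= 0 in pooled step")
        sum(s_b^2) / denom * s_b
      }
      step <- c(step_beta, rep(0, n * q))
    } else {
      if (max(abs(s)) < 1e-12) return(list(state = state, pll = pll_now))
      fb <- if (newton || is.null(fisher)) fisher_information(design, state)
            else fisher
      step <- if (newton) arrowhead_solve(fb, s) else step_size(s, fb) * s
    }
    delta <- state_delta(state)
    for (h in 0:control$step_halving_max) {
      cand <- state_replace_delta(state, delta + step / 2^h, n, p, q)
      pll <- penalized_loglik(design, cand)
      if (is.finite(pll) && pll >= pll_now - 1e-12) {
        return(list(state = cand, pll = pll))
      }
    }
    list(state = state, pll = pll_now)  # no uphill step found: keep position
  }

  ga <- advance(state, pll0, newton = FALSE)
  fs <- advance(ga$state, ga$pll, newton = TRUE)
  out <- fs$state
  attr(out, "pll") <- fs$pll
  out
}

#' EM update of the random-effects covariance
#'
#' One expectation-maximization step for Q given the current coefficients:
#' `Q_new = (1/n) sum_i (v_ii + b_i b_i')`, where `v_ii` is subject i's
#' diagonal block of the inverse penalized Fisher matrix (computed through
#' the arrowhead Schur complement, see [posterior_blocks()]'s role in the
#' source). The result is symmetrized and its eigenvalues floored at
#' `variance_floor`.
#'
#' @param state an [model_state()] object (supplies the current `b`).
#' @param fisher an [fisher_information()] object current for `state`.
#' @param variance_floor eigenvalue floor, default 1e-8.
#' @return q x q covariance matrix.
#' @export
em_update_Q <- function(state, fisher, variance_floor = 1e-8) {
  v <- posterior_blocks(fisher)
  n <- fisher$n; q <- fisher$q
  Qn <- matrix(0, q, q)
  for (i in seq_len(n)) {
    Qn <- Qn + v[, , i] + tcrossprod(state$b[i, ])
  }
  Qn <- Qn / n
  Qn <- (Qn + t(Qn)) / 2
  ev <- eigen(Qn, symmetric = TRUE)
  if (any(ev$values < variance_floor)) {
    ev$values <- pmax(ev$values, variance_floor)
    Qn <- ev$vectors %*% (ev$values * t(ev$vectors))
    Qn <- (Qn + t(Qn)) / 2
    attr(Qn, "floored") <- TRUE
  }
  Qn
}

init_beta <- function(design) {
  beta <- tryCatch(
    suppressWarnings(stats::coef(stats::glm.fit(design$X, design$y,
                                                family = stats::binomial()))),
    error = function(e) rep(0, design$p))
  beta[!is.finite(beta)] <- 0
  beta
}

#' Fit a (ridge) mixed-effects logistic model
#'
#' Fits the mixed-effects logistic model by maximizing the Breslow-Clayton
#' penalized quasi-likelihood, with an optional ridge penalty on the fixed
#' effects. Each outer iteration updates the stacked coefficient vector with
#' the hybrid gradient-ascent / Fisher-scoring step ([hybrid_update()]) and
#' the random-effects covariance with an EM step ([em_update_Q()]), until the
#' relative changes in both fall below tolerance.
#'
#' @param design an [long_design()] object.
#' @param lambda one of `"auto"` (default: shrinkage parameter estimated once
#'   from the unpenalized pooled-logistic pilot via [estimate_lambda()]),
#'   `"iterative"` (re-estimated from the current fit at every outer
#'   iteration), `"zero"` (the unpenalized mixed-effects logistic model), or
#'   a fixed numeric value >= 0.
#' @param control an [rmelm_control()] object.
#' @return An object of class `"rmelm_fit"` with components `beta_hat`,
#'   `se_beta`, `t_stats`, `p_values`, `odds_ratios`, `cov_beta`, `b_hat`,
#'   `Q_hat`, `lambda`, `loglik_penalized`, `loglik_unpenalized`,
#'   `converged`, `boundary`, `n_iter`, `trace` (penalized log-likelihood per
#'   iteration), plus the design and control used.
#' @examples
#' cell <- simulation_cell(n = 40, icc = 0.2, rho = 0.9, seed = 7)
#' d <- simulate_dataset(cell, 1)
#' ridge <- rmelm(d, lambda = "auto")
#' plain <- rmelm(d, lambda = "zero")
#' cbind(ridge = ridge$se_beta, plain = plain$se_beta)
#' @export
rmelm <- function(design, lambda = "auto", control = rmelm_control()) {
  stopifnot(inherits(design, "rmelm_design"))
  if (design$n < 2L) stop("need at least 2 subjects")
  p <- design$p; q <- design$q; n <- design$n

  beta <- init_beta(design)
  pilot_pi <- clamp_prob(stats::plogis(drop(design$X %*% beta)))
  lambda_mode <- if (is.numeric(lambda)) "fixed" else match.arg(
    lambda, c("auto", "iterative", "zero"))
  lam <- switch(lambda_mode,
    fixed = as.numeric(lambda),
    zero = 0,
    auto = estimate_lambda(design$X, beta, pilot_pi,
                           sigma2_mode = control$sigma2_mode,
                           y = design$y, penalize = design$penalize,
                           rule = control$lambda_rule),
    iterative = 0)
  if (control$fix_b) {
    # pooled fit: freeze the random effects at zero and keep Q fixed
    control$fix_Q <- TRUE
  }

  state <- model_state(beta = beta, b = matrix(0, n, q), Q = diag(q),
                       lambda = lam, penalize = design$penalize,
                       b_score_factor = control$b_score_factor)
  trace <- numeric(0)
  converged <- FALSE
  boundary <- FALSE
  Q_prev2 <- NULL
  n_decreasing <- 0L
  it <- 0L

  for (it in seq_len(control$max_outer_iter)) {
    if (lambda_mode == "iterative") {
      eta <- linear_predictor(design, state)
      state$lambda <- estimate_lambda(design$X, state$beta,
                                      clamp_prob(stats::plogis(eta)),
                                      sigma2_mode = control$sigma2_mode,
                                      y = design$y,
                                      penalize = design$penalize,
                                      rule = control$lambda_rule)
    }
    delta_old <- state_delta(state)
    Q_old <- state$Q

    state <- hybrid_update(design, state, control = control)
    trace <- c(trace, attr(state, "pll"))

    if (!control$fix_Q) {
      fb <- fisher_information(design, state)
      Qn <- em_update_Q(state, fb, variance_floor = control$variance_floor)
      if (q == 1L && control$accelerate_Q) {
        # Aitken extrapolation on the scalar EM sequence; near the zero
        # boundary the plain sequence converges sub-geometrically
        if (it %% 4L == 0L && !is.null(Q_prev2)) {
          d_new <- Qn[1, 1] - Q_old[1, 1]
          d_prev <- Q_old[1, 1] - Q_prev2
          if (abs(d_prev) > 0) {
            r <- d_new / d_prev
            if (is.finite(r) && r > 0 && r < 0.9995) {
              qx <- Qn[1, 1] + r / (1 - r) * d_new
              if (is.finite(qx) && qx < 1e6) {
                Qn[1, 1] <- max(qx, control$variance_floor)
              }
            }
          }
        }
        Q_prev2 <- Q_old[1, 1]
        n_decreasing <- if (Qn[1, 1] < Q_old[1, 1]) n_decreasing + 1L else 0L
        if (Qn[1, 1] < 1e-4 || (n_decreasing >= 25L && Qn[1, 1] < 0.05)) {
          # EM drifting to the zero-variance boundary: snap to the floor
          Qn[1, 1] <- control$variance_floor
          boundary <- TRUE
        }
      }
      state$Q <- Qn
    }

    d_delta <- max(abs(state_delta(state) - delta_old) / (1 + abs(delta_old)))
    d_Q <- norm(state$Q - Q_old, "F") / (1 + norm(Q_old, "F"))
    if (d_delta < control$tol_delta && d_Q < control$tol_Q) {
      converged <- TRUE
      break
    }
  }

  eta <- linear_predictor(design, state)
  if (max(abs(eta)) > 30) {
    warning("very large linear predictor (|eta| > 30): possible complete ",
            "separation")
  }

  fisher_pen <- fisher_information(design, state)
  state0 <- state
  state0$lambda <- 0
  fisher_unpen <- fisher_information(design, state0)
  cov_beta <- sandwich_cov_beta(fisher_pen, fisher_unpen,
                                mode = control$variance_mode)
  se <- sqrt(pmax(diag(cov_beta), 0))
  tstat <- ifelse(se > 0, state$beta / se, NA_real_)
  df <- design$N - p
  pvals <- if (control$df_mode == "t") {
    2 * stats::pt(-abs(tstat), df = df)
  } else {
    2 * stats::pnorm(-abs(tstat))
  }

  ll_pen <- penalized_loglik(design, state)
  ll_unpen <- penalized_loglik(design, state0)

  nm <- colnames(design$X)
  out <- structure(list(
    beta_hat = stats::setNames(state$beta, nm),
    b_hat = state$b,
    Q_hat = state$Q,
    lambda = state$lambda,
    lambda_mode = lambda_mode,
    cov_beta = `dimnames<-`(cov_beta, list(nm, nm)),
    se_beta = stats::setNames(se, nm),
    t_stats = stats::setNames(tstat, nm),
    df = if (control$df_mode == "t") df else Inf,
    p_values = stats::setNames(pvals, nm),
    odds_ratios = stats::setNames(exp(state$beta), nm),
    loglik_penalized = ll_pen,
    loglik_unpenalized = ll_unpen,
    converged = converged,
    boundary = boundary,
    n_iter = it,
    trace = trace,
    design = design,
    control = control),
    class = "rmelm_fit")
  out
}

#' @export
print.rmelm_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit: %d obs, %d subjects | lambda = %.4g (%s) | %s after %d iter\n",
    if (x$lambda > 0) "Ridge mixed-effects logistic" else
      "Mixed-effects logistic",
    x$design$N, x$design$n, x$lambda, x$lambda_mode,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(coefficient_table(x), digits = 4)
  cat(sprintf("Random-effects covariance (diagonal): %s%s\n",
              paste(format(diag(x$Q_hat), digits = 4), collapse = ", "),
              if (x$boundary) "  [boundary]" else ""))
  invisible(x)
}

#' @export
summary.rmelm_fit <- function(object, ...) print(object, ...)

#' @export
coef.rmelm_fit <- function(object, ...) object$beta_hat

#' @export
vcov.rmelm_fit <- function(object, ...) object$cov_beta

#' @export
logLik.rmelm_fit <- function(object, penalized = FALSE, ...) {
  structure(if (penalized) object$loglik_penalized else
              object$loglik_unpenalized,
            df = object$design$p + 1L, class = "logLik")
}

coefficient_table <- function(fit) {
  data.frame(estimate = fit$beta_hat,
             se = fit$se_beta,
             odds_ratio = fit$odds_ratios,
             t_value = fit$t_stats,
             p_value = fit$p_values,
             row.names = names(fit$beta_hat))
}
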