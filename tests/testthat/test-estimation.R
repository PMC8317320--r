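fake_fisher <- function(F_bb, F_bi, F_ii, Qinv = diag(dim(F_ii)[1])) {
  structure(list(F_bb = F_bb, F_bi = F_bi, F_ii = F_ii, Qinv = Qinv,
                 lambda = 0, penalize = rep(TRUE, nrow(F_bb)),
                 p = nrow(F_bb), q = dim(F_ii)[1], n = dim(F_ii)[3]),
            class = "rmelm_fisher")
}

test_that("gradient step size is s's / s'Fs", {
  # identity Fisher matrix: theta = 1; scaled identity: theta = 1/c
  fb <- fake_fisher(diag(2), array(0, c(2, 1, 3)), array(1, c(1, 1, 3)))
  s <- c(0.3, -1, 2, 0.5, -0.2)
  expect_equal(step_size(s, fb), 1)
  fb4 <- fake_fisher(4 * diag(2), array(0, c(2, 1, 3)),
                     array(4, c(1, 1, 3)))
  expect_equal(step_size(s, fb4), 0.25)

  # random SPD instance vs dense evaluation
  d <- random_design(n = 4, p = 3, seed = 31)
  st <- random_state(d, seed = 32, lambda = 0.7)
  fb <- fisher_information(d, st)
  set.seed(33)
  s <- rnorm(d$p + d$n * d$q)
  Fm <- assemble_fisher(fb)
  expect_equal(step_size(s, fb),
               sum(s^2) / drop(t(s) %*% Fm %*% s))
})

test_that("arrowhead solve equals the dense solve", {
  for (q in 1:2) {
    d <- random_design(n = 3, p = 2, q = q, seed = 40 + q)
    st <- random_state(d, seed = 42 + q, lambda = 0.5)
    fb <- fisher_information(d, st)
    set.seed(44)
    rhs <- rnorm(d$p + d$n * q)
    expect_equal(arrowhead_solve(fb, rhs),
                 drop(solve(assemble_fisher(fb), rhs)), tolerance = 1e-10)
  }
  fb <- fisher_information(random_design(3, 2, seed = 41),
                           random_state(random_design(3, 2, seed = 41), 1))
  expect_error(arrowhead_solve(fb, 1:3), "shape")
})

test_that("hybrid update is a fixed point at stationarity and never moves downhill", {
  d <- random_design(n = 6, p = 2, seed = 50)
  fit <- rmelm(d, lambda = 0.5)
  st <- model_state(fit$beta_hat, fit$b_hat, fit$Q_hat, fit$lambda)
  new <- hybrid_update(d, st)
  expect_equal(state_delta_vec(new), state_delta_vec(st), tolerance = 1e-5)
  # at a converged fit the score is numerically zero
  expect_lt(max(abs(rmelm_score(d, st))), 1e-4)

  # from rough starting points the criterion never decreases
  for (k in 1:10) {
    st0 <- random_state(d, seed = 60 + k, lambda = 0.2)
    new <- hybrid_update(d, st0)
    expect_gte(attr(new, "pll"), penalized_loglik(d, st0) - 1e-12)
  }
})

test_that("pooled-path iteration reproduces the reference IRLS fit", {
  set.seed(70)
  N <- 80
  X <- cbind(1, rnorm(N), rnorm(N))
  y <- rbinom(N, 1, plogis(X %*% c(-0.3, 0.8, -0.5)))
  d <- long_design(y, X, subject = seq_len(N) %% 10 + 1)
  fit <- rmelm(d, lambda = "zero",
               control = rmelm_control(fix_b = TRUE))
  ref <- suppressWarnings(glm.fit(d$X, d$y, family = binomial()))
  expect_equal(unname(fit$beta_hat), unname(coef(ref)), tolerance = 1e-6)
})

test_that("EM covariance update follows the posterior-block formula", {
  # n = 1, scalar blocks: v = 1/F_ii = 0.5, b = 1 -> Q = v + b^2 = 1.5
  fb <- fake_fisher(matrix(1), array(0, c(1, 1, 1)), array(2, c(1, 1, 1)))
  st <- model_state(beta = 0, b = 1, Q = diag(1))
  expect_equal(em_update_Q(st, fb), matrix(1.5))

  # with zero cross blocks v_ii is just F_ii^{-1}
  d <- random_design(n = 3, p = 2, seed = 80)
  st <- random_state(d, seed = 81)
  fb <- fisher_information(d, st)
  fb0 <- fb; fb0$F_bi[] <- 0
  v <- rmelm:::posterior_blocks(fb0)
  expect_equal(v[1, 1, ], 1 / fb$F_ii[1, 1, ], tolerance = 1e-12)

  # v_ii equals the subject-diagonal blocks of the dense inverse
  for (q in 1:2) {
    d <- random_design(n = 3, p = 2, q = q, seed = 82 + q)
    st <- random_state(d, seed = 84 + q, lambda = 0.3)
    fb <- fisher_information(d, st)
    v <- rmelm:::posterior_blocks(fb)
    Finv <- solve(assemble_fisher(fb))
    for (i in 1:3) {
      rows <- d$p + (i - 1) * q + seq_len(q)
      expect_equal(matrix(v[, , i], q, q), Finv[rows, rows, drop = FALSE],
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }

  # symmetry and the eigenvalue floor
  Qn <- em_update_Q(model_state(0, matrix(0, 1, 1), diag(1)),
                    fake_fisher(matrix(1), array(0, c(1, 1, 1)),
                                array(1e12, c(1, 1, 1))))
  expect_gte(Qn[1, 1], 1e-8)
})

test_that("ridge shrinkage: coefficient norm is non-increasing in lambda", {
  set.seed(90)
  n <- 40
  X <- generate_predictors(n, rho = 0.9)
  y <- rbinom(2 * n, 1, plogis(X %*% c(0.2, 0.4, -0.3)))
  d <- long_design(y, X, rep(1:n, each = 2))
  norms <- vapply(c(0, 0.5, 1, 2, 5, 10, 50), function(l) {
    f <- rmelm(d, lambda = l, control = rmelm_control(fix_b = TRUE))
    sqrt(sum(f$beta_hat^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("boundary fits on independent data reduce to the pooled GLM", {
  # data generated with NO subject effect: the variance estimate frequently
  # lands on the zero boundary (a singular fit), and whenever it does the
  # fixed effects must agree with the pooled logistic regression
  hits <- 0L
  for (s in 1:8) {
    set.seed(910 + s)
    n <- 40
    X <- generate_predictors(n, 0.5)
    y <- rbinom(2 * n, 1, plogis(X %*% c(0.2, 0.4, -0.3)))
    d <- long_design(y, X, rep(1:n, each = 2))
    fit <- suppressWarnings(rmelm(d, lambda = "zero"))
    if (fit$boundary) {
      hits <- hits + 1L
      ref <- suppressWarnings(glm.fit(d$X, d$y, family = binomial()))
      expect_equal(unname(fit$beta_hat), unname(coef(ref)),
                   tolerance = 1e-3)
      expect_lt(max(abs(fit$b_hat)), 1e-4)
    }
  }
  expect_gte(hits, 1L)
})

test_that("fit reports convergence state and trace honestly", {
  d <- simulate_dataset(simulation_cell(30, 0.5, 0.8, seed = 92), 1)
  fit <- rmelm(d, lambda = "auto")
  expect_true(fit$converged)
  expect_equal(length(fit$trace), fit$n_iter)
  f2 <- suppressWarnings(
    rmelm(d, lambda = "auto", control = rmelm_control(max_outer_iter = 2)))
  expect_false(f2$converged)
  expect_equal(f2$n_iter, 2L)
})
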