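test_that("linear predictor matches row-by-row dot products", {
  # zero parameters give eta = 0, pi = 0.5 everywhere
  d <- random_design(n = 5, p = 3, seed = 2)
  st0 <- model_state(beta = rep(0, 3), b = matrix(0, 5, 1), Q = diag(1))
  expect_equal(linear_predictor(d, st0), rep(0, d$N))

  # one subject, one row: eta = x beta + z b
  d1 <- long_design(1, matrix(1), subject = 1, Z = matrix(1))
  st1 <- model_state(beta = 0.5, b = 0.25, Q = diag(1))
  expect_equal(linear_predictor(d1, st1), 0.75)

  # random design and state vs an elementwise oracle (q = 2)
  d2 <- random_design(n = 4, p = 3, q = 2, seed = 3)
  st2 <- random_state(d2, seed = 4)
  eta <- linear_predictor(d2, st2)
  oracle <- vapply(seq_len(d2$N), function(r) {
    i <- d2$group[r]
    sum(d2$X[r, ] * st2$beta) + sum(d2$Z[r, ] * st2$b[i, ])
  }, numeric(1))
  expect_equal(eta, oracle)

  expect_error(linear_predictor(d2, random_state(random_design(4, 2), 1)),
               "shape")
})

test_that("penalized log-likelihood evaluates the joint criterion", {
  d <- random_design(n = 6, p = 2, seed = 5)
  st0 <- model_state(beta = c(0, 0), b = matrix(0, 6, 1), Q = diag(1),
                     lambda = 3)
  # all penalties vanish at zero: -N log 2
  expect_equal(penalized_loglik(d, st0), -d$N * log(2))

  # scalar evaluation: one row, y = 1, beta = 0.5, lambda = 0
  d1 <- long_design(1, matrix(1), subject = 1)
  st1 <- model_state(beta = 0.5, b = 0, Q = diag(1), lambda = 0)
  expect_equal(penalized_loglik(d1, st1), -0.474076984, tolerance = 1e-8)

  # lambda = 2 subtracts the ridge term lambda beta^2 = 0.5
  st2 <- st1; st2$lambda <- 2
  expect_equal(penalized_loglik(d1, st2),
               penalized_loglik(d1, st1) - 0.5)

  # numerically stable at extreme linear predictors
  stb <- model_state(beta = 500, b = 0, Q = diag(1), lambda = 0)
  expect_true(is.finite(penalized_loglik(d1, stb)))
  stb$beta <- -500
  expect_true(is.finite(penalized_loglik(d1, stb)))
})

test_that("pooled criterion equals ordinary logistic log-likelihood", {
  d <- random_design(n = 8, p = 2, seed = 6)
  st <- model_state(beta = c(0.4, -0.7), b = matrix(0, 8, 1), Q = diag(1),
                    lambda = 0)
  eta <- drop(d$X %*% st$beta)
  expect_equal(penalized_loglik(d, st),
               sum(dbinom(d$y, 1, plogis(eta), log = TRUE)))
})

test_that("increasing lambda never increases the criterion at beta != 0", {
  d <- random_design(n = 5, p = 3, seed = 7)
  st <- random_state(d, seed = 8, lambda = 0)
  vals <- vapply(c(0, 0.5, 1, 2, 8), function(l) {
    st$lambda <- l
    penalized_loglik(d, st)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("score equals the numeric gradient of the criterion", {
  # balanced-response example at beta = 0, b = 0: sum (y - 1/2) a = 0
  d1 <- long_design(c(1, 0), matrix(c(1, 1)), subject = c(1, 1))
  st1 <- model_state(beta = 0, b = 0, Q = diag(1), lambda = 4)
  expect_equal(rmelm_score(d1, st1), rep(0, 2))

  # 100 random states across designs, including q = 2, rel. tol 1e-5
  for (k in 1:100) {
    q <- if (k %% 3 == 0) 2 else 1
    d <- random_design(n = 3 + k %% 3, p = 2, q = q, seed = 100 + k)
    st <- random_state(d, seed = 200 + k, lambda = 0.3 * (k %% 4))
    s <- rmelm_score(d, st)
    g <- num_grad(pll_of_delta(d, st), state_delta_vec(st))
    expect_equal(s, g, tolerance = 1e-5)
  }
})

test_that("compatibility b-score factor doubles the random-effect penalty term", {
  d <- random_design(n = 4, p = 2, seed = 11)
  st <- random_state(d, seed = 12)
  st2 <- st; st2$b_score_factor <- 2
  s1 <- rmelm_score(d, st)
  s2 <- rmelm_score(d, st2)
  Qinv <- solve(st$Q)
  expect_equal(s2[-(1:2)] - s1[-(1:2)], -drop(st$b %*% Qinv))
  expect_equal(s2[1:2], s1[1:2])
})

test_that("psi weights equal pi (1 - pi) with boundary clamping", {
  expect_equal(psi_weights(0.5), 0.25)
  expect_equal(psi_weights(0.1), 0.09)
  expect_warning(w <- psi_weights(c(0, 1)), "clamped")
  expect_true(all(w > 0))
  # chain-rule oracle: d(expit)/d(eta) via numeric differentiation
  eta <- c(-3, -0.4, 0, 1.7)
  dnum <- vapply(eta, function(e) num_grad(plogis, e, h = 1e-6), numeric(1))
  expect_equal(psi_weights(plogis(eta)), dnum, tolerance = 1e-6)
})

test_that("Fisher blocks match hand values and the numeric Hessian", {
  # single subject, X = Z = ones, eta = 0: weights 0.25 per row
  d <- long_design(c(0, 1), matrix(c(1, 1)), subject = c(1, 1))
  st <- model_state(beta = 0, b = 0, Q = diag(1), lambda = 0)
  fb <- fisher_information(d, st)
  expect_equal(fb$F_bb, matrix(0.5), ignore_attr = TRUE)
  expect_equal(drop(fb$F_bi), 0.5)
  expect_equal(drop(fb$F_ii), 1.5)

  # assembled matrix equals the negative Hessian of the criterion
  for (k in 1:5) {
    q <- if (k > 3) 2 else 1
    d <- random_design(n = 3, p = 2, q = q, seed = 300 + k)
    st <- random_state(d, seed = 400 + k, lambda = 0.4 * (k - 1))
    Fm <- assemble_fisher(fisher_information(d, st))
    H <- num_hess(pll_of_delta(d, st), state_delta_vec(st))
    expect_equal(Fm, -H, tolerance = 1e-4)
    expect_equal(Fm, t(Fm))
    expect_true(all(eigen(Fm, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("penalty-free limit of the Fisher matrix is A' Psi A", {
  d <- random_design(n = 3, p = 2, q = 1, seed = 21)
  st <- random_state(d, seed = 22, lambda = 0)
  st$Q <- diag(1) * 1e12      # Q^{-1} -> 0
  Fm <- assemble_fisher(fisher_information(d, st))
  w <- psi_weights(plogis(linear_predictor(d, st)), warn = FALSE)
  A <- cbind(d$X, sapply(1:d$n, function(i) d$Z[, 1] * (d$group == i)))
  expect_equal(Fm, crossprod(A * sqrt(w)), tolerance = 1e-10,
               ignore_attr = TRUE)
})
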