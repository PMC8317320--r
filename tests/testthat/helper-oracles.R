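# numeric differentiation oracles and small random-instance builders

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

num_hess <- function(f, x, h = 1e-4) {
  m <- length(x)
  H <- matrix(0, m, m)
  for (i in seq_len(m)) {
    xp <- xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    H[i, i] <- (f(xp) - 2 * f(x) + f(xm)) / h^2
    for (j in seq_len(m)[-seq_len(i)]) {
      xpp <- xpm <- xmp <- xmm <- x
      xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
      xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
      xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
      xmm[i] <- xmm[i] - h; xmm[j] <- xmm[j] - h
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
    }
  }
  H
}

# small random clustered design: n subjects, 2 obs each, p fixed effects,
# q random-effect columns (first is an intercept)
random_design <- function(n = 4, p = 2, q = 1, seed = 1) {
  set.seed(seed)
  N <- 2L * n
  X <- matrix(rnorm(N * p), N, p)
  Z <- matrix(1, N, 1)
  if (q > 1) Z <- cbind(Z, matrix(rnorm(N * (q - 1)), N, q - 1))
  y <- rbinom(N, 1, 0.5)
  long_design(y, X, rep(seq_len(n), each = 2L), Z = Z)
}

random_state <- function(design, seed = 1, lambda = 0.5) {
  set.seed(seed)
  q <- design$q
  A <- matrix(rnorm(q * q, sd = 0.3), q, q)
  Q <- crossprod(A) + diag(q)
  model_state(beta = rnorm(design$p, sd = 0.7),
              b = matrix(rnorm(design$n * q, sd = 0.5), design$n, q),
              Q = Q, lambda = lambda)
}

state_delta_vec <- function(st) c(st$beta, as.vector(t(st$b)))

# pll as a function of the stacked coefficient vector, Q and lambda fixed
pll_of_delta <- function(design, state) {
  p <- design$p; q <- design$q; n <- design$n
  function(delta) {
    st <- state
    st$beta <- delta[seq_len(p)]
    st$b <- matrix(delta[-seq_len(p)], n, q, byrow = TRUE)
    penalized_loglik(design, st)
  }
}
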