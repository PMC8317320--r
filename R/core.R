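#' Bundle a parameter state for the penalized mixed-effects logistic model
#'
#' @param beta fixed-effect vector, length p.
#' @param b random-effect coefficients: an n x q matrix (or a vector when
#'   q = 1) holding one row per subject.
#' @param Q q x q symmetric positive-definite random-effects covariance.
#' @param lambda ridge shrinkage parameter, a scalar >= 0. `lambda = 0`
#'   reproduces the unpenalized mixed-effects logistic model.
#' @param penalize logical length-p mask of ridge-penalized fixed effects.
#'   Default: all.
#' @param b_score_factor multiplier on the `Q^{-1} b_i` term of the
#'   random-effect score. The default 1 is the gradient of the
#'   `-b' Q^{-1} b / 2` penalty; 2 reproduces a factor sometimes printed in
#'   the literature (compatibility only - with 2 the score is no longer the
#'   gradient of the penalized log-likelihood).
#'
#' @return An object of class `"rmelm_state"`.
#' @export
model_state <- function(beta, b, Q, lambda = 0, penalize = NULL,
                        b_score_factor = 1) {
  beta <- as.numeric(beta)
  Q <- as.matrix(Q)
  q <- nrow(Q)
  if (!isSymmetric(unname(Q), tol = 1e-8)) stop("Q must be symmetric")
  if (any(eigen(Q, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("Q must be positive definite (all eigenvalues > 0)")
  }
  if (lambda < 0) stop("lambda must be >= 0")
  b <- if (is.matrix(b)) b else matrix(as.numeric(b), ncol = q)
  if (ncol(b) != q) stop("shape error: b has ", ncol(b), " columns but Q is ",
                         q, "x", q)
  if (is.null(penalize)) penalize <- rep(TRUE, length(beta))
  structure(list(beta = beta, b = b, Q = Q, lambda = lambda,
                 penalize = as.logical(penalize),
                 b_score_factor = b_score_factor),
            class = "rmelm_state")
}

check_dims <- function(design, state) {
  if (length(state$beta) != design$p) {
    stop("shape error: beta has length ", length(state$beta),
         " but X has ", design$p, " columns")
  }
  if (nrow(state$b) != design$n || ncol(state$b) != design$q) {
    stop("shape error: b is ", nrow(state$b), "x", ncol(state$b),
         " but design has n = ", design$n, ", q = ", design$q)
  }
}

qinv_of <- function(Q) {
  Qi <- tryCatch(solve(Q), error = function(e) {
    stop("random-effects covariance Q is singular: ", conditionMessage(e))
  })
  (Qi + t(Qi)) / 2
}

clamp_prob <- function(p, eps = 1e-10) pmin(pmax(p, eps), 1 - eps)

#' Linear predictor of the mixed-effects logistic model
#'
#' Returns `eta`, with row r for subject i equal to `x_r' beta + z_r' b_i`.
#' The response probability is `plogis(eta)`.
#'
#' @param design an [long_design()] object.
#' @param state an [model_state()] object.
#' @return numeric vector of length N.
#' @export
linear_predictor <- function(design, state) {
  check_dims(design, state)
  eta <- design$X %*% state$beta
  if (design$q == 1L) {
    eta <- eta + design$Z[, 1L] * state$b[design$group, 1L]
  } else {
    eta <- eta + rowSums(design$Z * state$b[design$group, , drop = FALSE])
  }
  drop(eta)
}

# numerically stable log(1 + exp(x))
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Penalized log-likelihood (Breslow-Clayton joint criterion)
#'
#' Evaluates the working criterion maximized by the fit: the Bernoulli
#' log-likelihood given the random effects, minus the ridge penalty
#' `lambda * sum(beta[penalized]^2)`, minus the random-effects quadratic form
#' `b' (I_n o Q^{-1}) b / 2`. Numerically stable for large `|eta|`.
#'
#' @inheritParams linear_predictor
#' @return scalar.
#' @export
penalized_loglik <- function(design, state) {
  eta <- linear_predictor(design, state)
  ll <- sum(design$y * eta - softplus(eta))
  pen_b <- state$lambda * sum(state$beta[state$penalize]^2)
  Qinv <- qinv_of(state$Q)
  pen_u <- 0.5 * sum(state$b * (state$b %*% Qinv))
  ll - pen_b - pen_u
}

#' Score (gradient) of the penalized log-likelihood
#'
#' Stacked gradient in `delta = (beta, b_1, ..., b_n)`. The beta-part is
#' `sum (y - pi) x - 2 lambda beta` (penalized entries only); each b_i part is
#' `sum_j (y_ij - pi_ij) z_ij - Q^{-1} b_i`.
#'
#' @inheritParams linear_predictor
#' @return numeric vector of length p + n*q, ordered beta first then subject
#'   blocks.
#' @export
rmelm_score <- function(design, state) {
  eta <- linear_predictor(design, state)
  r <- design$y - clamp_prob(stats::plogis(eta))
  s_beta <- drop(crossprod(design$X, r))
  s_beta[state$penalize] <- s_beta[state$penalize] -
    2 * state$lambda * state$beta[state$penalize]
  Qinv <- qinv_of(state$Q)
  if (design$q == 1L) {
    s_b <- drop(rowsum(r * design$Z[, 1L], design$group, reorder = FALSE)) -
      state$b_score_factor * drop(Qinv) * state$b[, 1L]
    return(unname(c(s_beta, s_b)))
  }
  s_b <- rowsum(r * design$Z, design$group, reorder = FALSE) -
    state$b_score_factor * state$b %*% Qinv
  unname(c(s_beta, as.vector(t(s_b))))
}

#' Logistic GLM weights pi (1 - pi)
#'
#' Diagonal of the weight matrix `Psi = D nu^{-1} D'` which, for the
#' canonical logit link, collapses to `diag(pi (1 - pi))`. Probabilities at
#' the boundary are clamped to `[eps, 1 - eps]`.
#'
#' @param pi_hat vector of fitted probabilities.
#' @param eps clamping constant, default 1e-10.
#' @param warn warn when clamping occurs? Default `TRUE`.
#' @return vector of weights.
#' @export
psi_weights <- function(pi_hat, eps = 1e-10, warn = TRUE) {
  out_of_range <- pi_hat <= 0 | pi_hat >= 1
  if (any(out_of_range) && warn) {
    warning("fitted probabilities at 0 or 1 clamped to [",
            format(eps), ", 1 - ", format(eps), "]")
  }
  pi_hat <- clamp_prob(pi_hat, eps)
  pi_hat * (1 - pi_hat)
}

#' Block Fisher information of the penalized model
#'
#' Builds the arrowhead-structured penalized expected information: the dense
#' fixed-effect block `F_bb = X' Psi X + 2 lambda diag(penalize)`, the
#' cross blocks `F_bi = X_i' Psi_i Z_i`, and the subject blocks
#' `F_ii = Z_i' Psi_i Z_i + Q^{-1}`. Subject-subject off-diagonal blocks are
#' identically zero and never stored.
#'
#' @inheritParams linear_predictor
#' @return An object of class `"rmelm_fisher"`: list with `F_bb` (p x p),
#'   `F_bi` (p x q x n array), `F_ii` (q x q x n array), `Qinv`, `lambda`,
#'   `penalize`, and dimensions `p`, `q`, `n`.
#' @export
fisher_information <- function(design, state) {
  eta <- linear_predictor(design, state)
  w <- psi_weights(stats::plogis(eta), warn = FALSE)
  Qinv <- qinv_of(state$Q)
  p <- design$p; q <- design$q; n <- design$n
  F_bb <- crossprod(design$X * sqrt(w))
  idx <- which(state$penalize)
  F_bb[cbind(idx, idx)] <- F_bb[cbind(idx, idx)] + 2 * state$lambda

  # per-subject cross and diagonal blocks via grouped row sums:
  # entry (a, c) of F_bi is sum_j w_j X[j, a] Z[j, c] over subject i's rows
  F_bi <- array(0, c(p, q, n))
  for (cc in seq_len(q)) {
    wz <- w * design$Z[, cc]
    F_bi[, cc, ] <- t(rowsum(design$X * wz, design$group, reorder = FALSE))
  }
  F_ii <- array(0, c(q, q, n))
  for (a in seq_len(q)) {
    for (cc in a:q) {
      s <- drop(rowsum(w * design$Z[, a] * design$Z[, cc], design$group,
                       reorder = FALSE))
      F_ii[a, cc, ] <- F_ii[a, cc, ] + s + Qinv[a, cc]
      if (cc > a) F_ii[cc, a, ] <- F_ii[a, cc, ]
    }
  }
  structure(list(F_bb = F_bb, F_bi = F_bi, F_ii = F_ii, Qinv = Qinv,
                 lambda = state$lambda, penalize = state$penalize,
                 p = p, q = q, n = n),
            class = "rmelm_fisher")
}

#' Assemble the block Fisher information into a dense matrix
#'
#' Intended for small problems and cross-checks; the fitting path never forms
#' this matrix.
#'
#' @param fisher an [fisher_information()] object.
#' @return dense symmetric (p + n q) x (p + n q) matrix.
#' @export
assemble_fisher <- function(fisher) {
  p <- fisher$p; q <- fisher$q; n <- fisher$n
  m <- p + n * q
  out <- matrix(0, m, m)
  out[1:p, 1:p] <- fisher$F_bb
  for (i in seq_len(n)) {
    rows <- p + (i - 1L) * q + seq_len(q)
    out[1:p, rows] <- fisher$F_bi[, , i]
    out[rows, 1:p] <- t(fisher$F_bi[, , i, drop = TRUE])
    out[rows, rows] <- fisher$F_ii[, , i]
  }
  out
}

# F %*% v exploiting the arrowhead structure; v length p + n q
fisher_times <- function(fisher, v) {
  p <- fisher$p; q <- fisher$q; n <- fisher$n
  vb <- v[seq_len(p)]
  if (q == 1L) {
    vi <- v[-seq_len(p)]
    B <- matrix(fisher$F_bi, p, n)
    f <- fisher$F_ii[1, 1, ]
    top <- drop(fisher$F_bb %*% vb) + drop(B %*% vi)
    bot <- drop(crossprod(B, vb)) + f * vi
    return(c(top, bot))
  }
  vi <- matrix(v[-seq_len(p)], nrow = q)      # q x n, column i = v_i
  top <- drop(fisher$F_bb %*% vb)
  bot <- matrix(0, q, n)
  for (i in seq_len(n)) {
    Bi <- matrix(fisher$F_bi[, , i], p, q)
    top <- top + drop(Bi %*% vi[, i])
    bot[, i] <- drop(crossprod(Bi, vb)) + drop(fisher$F_ii[, , i] %*% vi[, i])
  }
  c(top, as.vector(bot))
}

# inverse of each q x q subject block, as a q x q x n array
invert_subject_blocks <- function(fisher) {
  q <- fisher$q; n <- fisher$n
  if (q == 1L) {
    f <- fisher$F_ii[1, 1, ]
    if (any(f <= 0)) stop("subject Fisher block not positive definite")
    return(array(1 / f, c(1, 1, n)))
  }
  out <- array(0, c(q, q, n))
  for (i in seq_len(n)) out[, , i] <- solve(fisher$F_ii[, , i])
  out
}

# Schur complement of the subject blocks: F_bb - sum_i F_bi F_ii^{-1} F_ib
schur_beta <- function(fisher, Minv = invert_subject_blocks(fisher)) {
  p <- fisher$p; q <- fisher$q; n <- fisher$n
  if (q == 1L) {
    B <- matrix(fisher$F_bi, p, n)
    m <- Minv[1, 1, ]
    return(fisher$F_bb - tcrossprod(B * rep(m, each = p), B))
  }
  S <- fisher$F_bb
  for (i in seq_len(n)) {
    Bi <- matrix(fisher$F_bi[, , i], p, q)
    S <- S - Bi %*% Minv[, , i] %*% t(Bi)
  }
  S
}

#' Solve a linear system in the arrowhead Fisher matrix
#'
#' Solves `F x = rhs` without forming the dense matrix: the n small q x q
#' subject systems are solved first, then the p x p Schur complement of the
#' fixed-effect block.
#'
#' @param fisher an [fisher_information()] object.
#' @param rhs numeric vector of length p + n q.
#' @return the solution vector.
#' @export
arrowhead_solve <- function(fisher, rhs) {
  p <- fisher$p; q <- fisher$q; n <- fisher$n
  if (length(rhs) != p + n * q) {
    stop("shape error: rhs has length ", length(rhs), ", expected ",
         p + n * q)
  }
  Minv <- invert_subject_blocks(fisher)
  S <- schur_beta(fisher, Minv)
  rb <- rhs[seq_len(p)]
  if (q == 1L) {
    ri <- rhs[-seq_len(p)]
    B <- matrix(fisher$F_bi, p, n)
    m <- Minv[1, 1, ]
    u <- ri * m
    xb <- tryCatch(solve(S, rb - drop(B %*% u)), error = function(e) {
      stop("penalized Fisher matrix is singular; consider a larger lambda ",
           "or check for complete separation (", conditionMessage(e), ")")
    })
    xi <- u - m * drop(crossprod(B, xb))
    return(unname(c(xb, xi)))
  }
  ri <- matrix(rhs[-seq_len(p)], nrow = q)
  u <- matrix(0, q, n)
  rb_adj <- rb
  for (i in seq_len(n)) {
    Bi <- matrix(fisher$F_bi[, , i], p, q)
    u[, i] <- drop(Minv[, , i] %*% ri[, i])
    rb_adj <- rb_adj - drop(Bi %*% u[, i])
  }
  xb <- tryCatch(solve(S, rb_adj), error = function(e) {
    stop("penalized Fisher matrix is singular; consider a larger lambda ",
         "or check for complete separation (", conditionMessage(e), ")")
  })
  xi <- matrix(0, q, n)
  for (i in seq_len(n)) {
    Bi <- matrix(fisher$F_bi[, , i], p, q)
    xi[, i] <- u[, i] - drop(Minv[, , i] %*% crossprod(Bi, xb))
  }
  unname(c(xb, as.vector(xi)))
}

# posterior covariance blocks v_ii = [F^{-1}]_ii for each subject:
# v_ii = M_i + M_i F_ib S^{-1} F_bi M_i with M_i = F_ii^{-1},
# S the fixed-effect Schur complement.  Returns q x q x n array.
posterior_blocks <- function(fisher) {
  p <- fisher$p; q <- fisher$q; n <- fisher$n
  Minv <- invert_subject_blocks(fisher)
  S <- schur_beta(fisher, Minv)
  if (q == 1L) {
    B <- matrix(fisher$F_bi, p, n)
    m <- Minv[1, 1, ]
    Cm <- tryCatch(solve(S, B), error = function(e) {
      stop("fixed-effect Schur complement is singular: ",
           conditionMessage(e))
    })
    v <- m + m^2 * colSums(B * Cm)
    return(array(v, c(1, 1, n)))
  }
  Sinv <- tryCatch(solve(S), error = function(e) {
    stop("fixed-effect Schur complement is singular: ", conditionMessage(e))
  })
  out <- array(0, c(q, q, n))
  for (i in seq_len(n)) {
    Bi <- matrix(fisher$F_bi[, , i], p, q)
    Mi <- Minv[, , i]
    out[, , i] <- Mi + Mi %*% t(Bi) %*% Sinv %*% Bi %*% Mi
  }
  out
}
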