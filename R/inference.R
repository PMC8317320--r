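#' Sandwich covariance of the fixed effects under the ridge penalty
#'
#' Marginal fixed-effect block of `(F^lambda)^{-1} F^0 (F^lambda)^{-1}`,
#' where `F^lambda` is the penalized Fisher matrix and `F^0` the same matrix
#' with `lambda = 0` (the random-effects term `Q^{-1}` retained), both at the
#' converged state. Shrinkage biases the estimator but reduces this
#' covariance; at `lambda = 0` the sandwich collapses to the usual inverse
#' Fisher block. The `"naive"` mode returns the fixed-effect block of
#' `(F^lambda)^{-1}` alone, the expression some of the penalized-likelihood
#' literature reports; the two agree only at `lambda = 0`.
#'
#' Everything is evaluated through the arrowhead Schur complement; the dense
#' `(p + nq)` matrix is never formed.
#'
#' @param fisher_penalized [fisher_information()] at the converged state.
#' @param fisher_unpenalized the same with `lambda = 0`.
#' @param mode `"sandwich"` (default) or `"naive"`.
#' @return p x p covariance matrix.
#' @export
sandwich_cov_beta <- function(fisher_penalized, fisher_unpenalized,
                              mode = c("sandwich", "naive")) {
  mode <- match.arg(mode)
  fl <- fisher_penalized
  p <- fl$p; q <- fl$q; n <- fl$n
  Minv <- invert_subject_blocks(fl)
  Sl <- schur_beta(fl, Minv)
  Sl_inv <- tryCatch(solve(Sl), error = function(e) {
    stop("penalized Fisher matrix is singular: ", conditionMessage(e))
  })
  Sl_inv <- (Sl_inv + t(Sl_inv)) / 2
  if (mode == "naive") return(Sl_inv)

  f0 <- fisher_unpenalized
  if (q == 1L) {
    B <- matrix(fl$F_bi, p, n)
    f <- fl$F_ii[1, 1, ]
    # column beta-block T of (F^lambda)^{-1}: top Sl_inv, subject rows Tn
    Tn <- -(t(B) / f) %*% Sl_inv                    # n x p
    top <- f0$F_bb %*% Sl_inv + B %*% Tn            # (F^0 T) beta rows
    Rn <- t(B) %*% Sl_inv + f * Tn                  # (F^0 T) subject rows
    V <- t(Sl_inv) %*% top + t(Tn) %*% Rn
    return((V + t(V)) / 2)
  }

  # general q: same triple product, subject blocks handled one at a time
  top <- f0$F_bb %*% Sl_inv
  V <- matrix(0, p, p)
  Tn <- vector("list", n)
  for (i in seq_len(n)) {
    Bi <- matrix(fl$F_bi[, , i], p, q)
    Tn[[i]] <- -Minv[, , i] %*% crossprod(Bi, Sl_inv)   # q x p
    top <- top + Bi %*% Tn[[i]]
  }
  for (i in seq_len(n)) {
    Bi <- matrix(fl$F_bi[, , i], p, q)
    Ri <- crossprod(Bi, Sl_inv) + f0$F_ii[, , i] %*% Tn[[i]]
    V <- V + t(Tn[[i]]) %*% Ri
  }
  V <- t(Sl_inv) %*% top + V
  (V + t(V)) / 2
}

#' Per-coefficient non-exact t-tests
#'
#' Wald-type statistics `t_k = beta_k / SE(beta_k)` for the fixed effects.
#' Under the ridge penalty the statistic does not follow an exact
#' t-distribution; p-values use a t reference with `N - p` degrees of freedom
#' (or the normal when the fit was run with `df_mode = "normal"`).
#'
#' @param fit an [rmelm()] fit, or any list carrying `beta_hat`, `se_beta`
#'   and `df` (Inf for a normal reference).
#' @param alpha two-sided significance level for the rejection flag.
#' @return data frame with one row per fixed effect: `estimate`, `se`,
#'   `t_value`, `df`, `p_value`, `odds_ratio`, `reject`.
#' @export
coefficient_tests <- function(fit, alpha = 0.05) {
  se <- fit$se_beta
  if (any(se == 0)) {
    stop("zero standard error for: ",
         paste(names(se)[se == 0], collapse = ", "))
  }
  tstat <- fit$beta_hat / se
  pval <- if (is.finite(fit$df)) 2 * stats::pt(-abs(tstat), df = fit$df)
          else 2 * stats::pnorm(-abs(tstat))
  data.frame(
    estimate = fit$beta_hat,
    se = se,
    t_value = tstat,
    df = fit$df,
    p_value = pval,
    odds_ratio = exp(fit$beta_hat),
    reject = pval < alpha,
    row.names = names(fit$beta_hat))
}

#' Global likelihood-ratio test
#'
#' Tests the full model against a nested null (typically intercept plus
#' random effects only) with `2 (l_full - l_null)` evaluated on the
#' *unpenalized* criterion at each model's own estimates, against a
#' chi-squared reference with `p_full - p_null` degrees of freedom.
#'
#' @param fit_full,fit_null [rmelm()] fits on the same data.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt_global <- function(fit_full, fit_null) {
  stopifnot(inherits(fit_full, "rmelm_fit"), inherits(fit_null, "rmelm_fit"))
  if (fit_full$design$N != fit_null$design$N ||
      !isTRUE(all.equal(fit_full$design$y, fit_null$design$y))) {
    stop("the two fits are not on the same data")
  }
  df <- fit_full$design$p - fit_null$design$p
  if (df < 0) stop("fit_null has more fixed effects than fit_full")
  stat <- 2 * (fit_full$loglik_unpenalized - fit_null$loglik_unpenalized)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Collinearity diagnostics: condition indices and correlations
#'
#' Columns are standardized to unit length (no centering, the Belsley
#' convention); the condition indices are `sqrt(mu_1 / mu_j)` for the ordered
#' eigenvalues of the standardized cross-product, and the condition number is
#' the largest index. Exact collinearity (a zero eigenvalue) yields an
#' infinite condition number with a warning.
#'
#' @param X numeric matrix with at least two columns.
#' @return list with `condition_number`, `condition_indices`, `eigenvalues`,
#'   and `correlations` (the plain correlation matrix of the columns).
#' @export
collinearity_diagnostics <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("X must have at least 2 columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  norms <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, norms, "/")
  mu <- eigen(crossprod(Xs), symmetric = TRUE, only.values = TRUE)$values
  mu <- pmax(mu, 0)
  tol <- max(mu) * 1e-12
  idx <- ifelse(mu > tol, sqrt(max(mu) / mu), Inf)
  if (any(!is.finite(idx))) {
    warning("exactly collinear columns: condition number is infinite")
  }
  list(condition_number = max(idx),
       condition_indices = idx,
       eigenvalues = mu,
       correlations = stats::cor(X))
}
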