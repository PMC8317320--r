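#' Closed-form plug-in estimate of the ridge shrinkage parameter
#'
#' Eigen-rotates the fixed-effect estimate through the weighted cross-product
#' `X' W X = gamma' Lambda gamma` (rows of `gamma` are eigenvectors), forming
#' rotated coefficients `alpha = gamma beta` and the per-component quantities
#' `m_k = sqrt(sigma^2 / alpha_k^2)`. The default rule is the geometric mean
#' of the `m_k`,
#' `lambda = (prod_k m_k)^(1/p) = sigma / (prod_k |alpha_k|)^(1/p)`,
#' a Kibria/Muniz-type estimator: the smaller the rotated coefficients, the
#' stronger the shrinkage. The alternative `rule = "printed"` is its
#' reciprocal, `lambda = (prod_k 1/m_k)^(1/p)`, kept for compatibility with
#' part of the ridge literature; it shrinks *less* as coefficients shrink and
#' produces a near-null penalty in the settings this package targets (see the
#' methods vignette).
#'
#' Only columns flagged in `penalize` enter the rotation, and `p` in the
#' exponent is the number of penalized columns. Rotated coefficients equal to
#' zero are floored at 1e-8 in absolute value (with a warning).
#'
#' @param X fixed-effect matrix.
#' @param beta_hat current fixed-effect estimate.
#' @param pi_hat fitted probabilities defining the weights `W = diag(pi(1-pi))`.
#' @param sigma2_mode `"fixed"` (sigma^2 = 1, Bernoulli dispersion, default)
#'   or `"pearson"` (`chi^2 / (N - p)`, requires `y`).
#' @param y response vector; needed only for `sigma2_mode = "pearson"`.
#' @param penalize logical mask of penalized columns; default all.
#' @param rule `"gm"` (default) or `"printed"`; see Details.
#' @param sigma2 explicit dispersion value overriding `sigma2_mode`.
#' @return scalar `lambda >= 0`.
#' @export
estimate_lambda <- function(X, beta_hat, pi_hat,
                            sigma2_mode = c("fixed", "pearson"), y = NULL,
                            penalize = NULL, rule = c("gm", "printed"),
                            sigma2 = NULL) {
  sigma2_mode <- match.arg(sigma2_mode)
  rule <- match.arg(rule)
  X <- as.matrix(X)
  if (is.null(penalize)) penalize <- rep(TRUE, ncol(X))
  Xp <- X[, penalize, drop = FALSE]
  bp <- beta_hat[penalize]
  p <- ncol(Xp)
  if (p < 1L) stop("no penalized columns")

  w <- psi_weights(pi_hat, warn = FALSE)
  XtWX <- crossprod(Xp * sqrt(w))
  ed <- eigen(XtWX, symmetric = TRUE)
  gamma <- t(ed$vectors)               # rows are eigenvectors
  alpha <- drop(gamma %*% bp)
  if (any(alpha == 0)) {
    warning("zero rotated coefficient(s); floored at 1e-8")
  }
  abs_alpha <- pmax(abs(alpha), 1e-8)

  sigma2 <- if (!is.null(sigma2)) {
    sigma2
  } else if (sigma2_mode == "fixed") {
    1
  } else {
    if (is.null(y)) stop("y is required for sigma2_mode = \"pearson\"")
    pc <- clamp_prob(pi_hat)
    sum((y - pc)^2 / (pc * (1 - pc))) / (length(y) - p)
  }
  m <- sqrt(sigma2 / abs_alpha^2)
  lam <- switch(rule,
    gm = exp(mean(log(m))),
    printed = exp(-mean(log(m))))
  max(lam, 0)
}
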