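#' Map an intraclass correlation to a random-intercept variance
#'
#' Uses the latent logistic-scale convention: a random intercept with
#' variance `sigma_b^2` on top of a standard-logistic residual (variance
#' `pi^2/3`) induces `ICC = sigma_b^2 / (sigma_b^2 + pi^2/3)`, so
#' `sigma_b^2 = ICC (pi^2/3) / (1 - ICC)`.
#'
#' @param icc intraclass correlation in (0, 1).
#' @return the random-intercept variance `sigma_b^2`.
#' @export
icc_to_variance <- function(icc) {
  if (any(icc <= 0 | icc >= 1)) stop("icc must lie in (0, 1)")
  icc * (pi^2 / 3) / (1 - icc)
}

#' @rdname icc_to_variance
#' @param sigma_b2 random-intercept variance > 0.
#' @export
variance_to_icc <- function(sigma_b2) {
  sigma_b2 / (sigma_b2 + pi^2 / 3)
}

#' One configuration of the Monte Carlo study
#'
#' Describes a single simulation cell: clustered binary responses with a
#' subject random intercept, two observations per subject, and three
#' standard-normal fixed-effect predictors of which the first two share a
#' common factor inducing correlation `rho` (the third is independent).
#'
#' @param n number of subjects.
#' @param icc intraclass correlation of the latent responses, in (0, 1);
#'   mapped to the random-intercept variance by [icc_to_variance()].
#' @param rho target correlation between the two collinear predictors.
#' @param beta true fixed-effect vector, default `c(0.2, 0.4, -0.3)`.
#' @param reps Monte Carlo replicates, default 1000.
#' @param seed master seed for the cell.
#' @param alpha test level for empirical power, default 0.05.
#' @param n_per_subject observations per subject, default 2.
#' @param generator `"shared"` (default) for the shared-common-factor
#'   construction, `"printed"` for the degenerate variant in which each
#'   predictor is a rescaled single normal draw (yielding *uncorrelated*
#'   predictors; compatibility only).
#' @return list of class `"rmelm_simcell_spec"`.
#' @export
simulation_cell <- function(n, icc, rho, beta = c(0.2, 0.4, -0.3),
                            reps = 1000L, seed = 1L, alpha = 0.05,
                            n_per_subject = 2L,
                            generator = c("shared", "printed")) {
  stopifnot(rho >= 0, rho < 1 || rho == 1, icc > 0, icc < 1, reps >= 1)
  structure(list(n = as.integer(n), icc = icc, rho = rho, beta = beta,
                 reps = as.integer(reps), seed = as.integer(seed),
                 alpha = alpha, n_per_subject = as.integer(n_per_subject),
                 generator = match.arg(generator)),
            class = "rmelm_simcell_spec")
}

#' Generate collinear standard-normal predictors
#'
#' Draws `x1 = sqrt(1-rho) a1 + sqrt(rho) c` and
#' `x2 = sqrt(1-rho) a2 + sqrt(rho) c` with independent standard normals
#' `a1, a2, c` per row, so each has unit variance and `cor(x1, x2) = rho` in
#' expectation; `x3` is an independent standard normal. The `"printed"`
#' generator instead sets `x_k = (sqrt(1-rho) + sqrt(rho)) a_k` for k = 1, 2,
#' which leaves the predictors uncorrelated whatever `rho`.
#'
#' @param n number of subjects (rows generated: `n * n_per_subject`).
#' @param rho target correlation in `[0, 1]`.
#' @param n_per_subject rows per subject, default 2.
#' @param generator `"shared"` (default) or `"printed"`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return numeric matrix with `n * n_per_subject` rows and 3 columns.
#' @export
generate_predictors <- function(n, rho, n_per_subject = 2L,
                                generator = c("shared", "printed"),
                                seed = NULL) {
  generator <- match.arg(generator)
  stopifnot(rho >= 0, rho <= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- n * n_per_subject
  a1 <- stats::rnorm(N)
  a2 <- stats::rnorm(N)
  if (generator == "shared") {
    cf <- stats::rnorm(N)
    x1 <- sqrt(1 - rho) * a1 + sqrt(rho) * cf
    x2 <- sqrt(1 - rho) * a2 + sqrt(rho) * cf
  } else {
    x1 <- (sqrt(1 - rho) + sqrt(rho)) * a1
    x2 <- (sqrt(1 - rho) + sqrt(rho)) * a2
  }
  x3 <- stats::rnorm(N)
  cbind(x1 = x1, x2 = x2, x3 = x3)
}

# deterministic replicate seed from (master seed, cell index, rep), < 2^31
derive_seed <- function(seed, cell_index, rep_index) {
  raw <- (as.double(seed) %% 65011 + 1) * 29989 +
    as.double(cell_index) * 999983 + as.double(rep_index) * 7919
  as.integer(raw %% 2147483629)
}

#' Simulate one clustered binary dataset from a simulation cell
#'
#' Draws predictors via [generate_predictors()], subject random intercepts
#' `b_i ~ N(0, sigma_b^2)` with `sigma_b^2` implied by the cell's ICC, forms
#' `eta = X beta + b` and `y ~ Bernoulli(plogis(eta))`. The RNG seed is
#' derived deterministically from the cell's master seed, its `cell_index`
#' and `rep_index`, so any replicate is reproducible in isolation.
#'
#' @param cell a [simulation_cell()].
#' @param rep_index replicate number, >= 1.
#' @param cell_index index of the cell within a grid (1 for a lone cell).
#' @return an [long_design()] with attribute `"truth"` recording `beta`,
#'   `sigma_b2`, the drawn intercepts and the seed used.
#' @export
simulate_dataset <- function(cell, rep_index = 1L, cell_index = 1L) {
  seed <- derive_seed(cell$seed, cell_index, rep_index)
  set.seed(seed)
  n <- cell$n
  X <- generate_predictors(n, cell$rho, cell$n_per_subject, cell$generator)
  sb2 <- icc_to_variance(cell$icc)
  b <- stats::rnorm(n, 0, sqrt(sb2))
  g <- rep(seq_len(n), each = cell$n_per_subject)
  eta <- drop(X %*% cell$beta) + b[g]
  y <- stats::rbinom(length(eta), 1L, stats::plogis(eta))
  d <- long_design(y, X, g)
  attr(d, "truth") <- list(beta = cell$beta, sigma_b2 = sb2, b = b,
                           seed = seed)
  d
}

fit_quietly <- function(design, lambda, control) {
  tryCatch(suppressWarnings(rmelm(design, lambda = lambda,
                                  control = control)),
           error = function(e) NULL)
}

#' Run all replicates of one simulation cell
#'
#' Fits the unpenalized (`melm`, `lambda = "zero"`) and ridge (`rmelm`,
#' `lambda = "auto"`) models to every replicate and summarizes per
#' coefficient: mean squared error (with its Monte Carlo standard error),
#' relative bias in percent, and empirical power at the cell's `alpha`.
#' Replicates in which a fit errors out or fails to converge are excluded
#' from that model's summaries and counted; a warning is issued when more
#' than 5 percent are lost.
#'
#' @param cell a [simulation_cell()].
#' @param control an [rmelm_control()] used for both fits.
#' @param cell_index seed offset index, see [simulate_dataset()].
#' @param keep_estimates keep the per-replicate estimate matrices? Default
#'   `TRUE`.
#' @return list of class `"rmelm_simcell"` with `metrics` (data frame:
#'   model x coefficient rows), `cells` (one row per model: mean Q, failure
#'   count), and optionally `estimates` / `pvalues` matrices per model.
#' @export
run_cell <- function(cell, control = rmelm_control(), cell_index = 1L,
                     keep_estimates = TRUE) {
  stopifnot(inherits(cell, "rmelm_simcell_spec"))
  reps <- cell$reps
  p <- length(cell$beta)
  models <- c("melm", "rmelm")
  est <- pv <- lapply(models, function(m) matrix(NA_real_, reps, p))
  names(est) <- names(pv) <- models
  Qh <- matrix(NA_real_, reps, 2L, dimnames = list(NULL, models))
  lam <- rep(NA_real_, reps)

  for (r in seq_len(reps)) {
    d <- simulate_dataset(cell, r, cell_index)
    fm <- fit_quietly(d, "zero", control)
    fr <- fit_quietly(d, "auto", control)
    if (!is.null(fm) && fm$converged) {
      est$melm[r, ] <- fm$beta_hat
      pv$melm[r, ] <- fm$p_values
      Qh[r, "melm"] <- fm$Q_hat[1, 1]
    }
    if (!is.null(fr) && fr$converged) {
      est$rmelm[r, ] <- fr$beta_hat
      pv$rmelm[r, ] <- fr$p_values
      Qh[r, "rmelm"] <- fr$Q_hat[1, 1]
      lam[r] <- fr$lambda
    }
  }

  bt <- cell$beta
  coef_names <- paste0("beta", seq_len(p))
  metrics <- do.call(rbind, lapply(models, function(m) {
    E <- est[[m]]
    ok <- stats::complete.cases(E)
    sq <- sweep(E[ok, , drop = FALSE], 2, bt)^2
    data.frame(n = cell$n, icc = cell$icc, rho = cell$rho, model = m,
               coefficient = coef_names,
               true = bt,
               mse = colMeans(sq),
               mcse_mse = apply(sq, 2, stats::sd) / sqrt(sum(ok)),
               relbias = 100 * (colMeans(E[ok, , drop = FALSE]) - bt) / bt,
               power = colMeans(pv[[m]][ok, , drop = FALSE] < cell$alpha),
               row.names = NULL)
  }))
  n_fail <- vapply(models, function(m) sum(!stats::complete.cases(est[[m]])),
                   integer(1))
  if (any(n_fail > 0.05 * reps)) {
    warning(sprintf("cell (n=%d, icc=%g, rho=%g): %s replicate(s) excluded",
                    cell$n, cell$icc, cell$rho,
                    paste(sprintf("%s=%d", models, n_fail), collapse = ", ")))
  }
  if (all(n_fail == reps)) {
    stop("all replicates failed in cell (n=", cell$n, ", icc=", cell$icc,
         ", rho=", cell$rho, ")")
  }
  cells <- data.frame(n = cell$n, icc = cell$icc, rho = cell$rho,
                      model = models,
                      mean_Q = colMeans(Qh, na.rm = TRUE),
                      n_fail = n_fail, reps = reps,
                      mean_lambda = c(NA_real_, mean(lam, na.rm = TRUE)),
                      row.names = NULL)
  out <- list(cell = cell, metrics = metrics, cells = cells)
  if (keep_estimates) {
    out$estimates <- est
    out$pvalues <- pv
  }
  structure(out, class = "rmelm_simcell")
}

#' @export
print.rmelm_simcell <- function(x, ...) {
  cat(sprintf("Simulation cell: n=%d, ICC=%g, rho=%g, %d replicates\n",
              x$cell$n, x$cell$icc, x$cell$rho, x$cell$reps))
  print(x$metrics, digits = 3)
  invisible(x)
}

#' Run a grid of simulation cells
#'
#' Crosses the supplied `n`, `icc` and `rho` values, runs every cell through
#' [run_cell()], and returns tidy summaries: one row per (cell, model,
#' coefficient) with MSE, relative bias and power, and one row per (cell,
#' model) with the mean estimated random-intercept variance and failure
#' counts. Per-cell seeds are fixed functions of the master seed and the
#' cell's index, so results are identical whatever `cores` is.
#'
#' @param n,icc,rho vectors of grid values.
#' @param beta true coefficient vector.
#' @param reps replicates per cell.
#' @param seed master seed.
#' @param alpha test level.
#' @param control an [rmelm_control()].
#' @param cores cells fitted in parallel via `parallel::mclapply` when > 1.
#' @return list of class `"rmelm_simgrid"` with data frames `coefficients`
#'   and `cells`.
#' @export
run_grid <- function(n = c(30, 50, 100), icc = c(0.2, 0.5, 0.8),
                     rho = c(0.7, 0.8, 0.9, 0.95),
                     beta = c(0.2, 0.4, -0.3), reps = 1000L, seed = 1L,
                     alpha = 0.05, control = rmelm_control(), cores = 1L) {
  grid <- expand.grid(n = n, icc = icc, rho = rho,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) stop("empty grid")
  one <- function(ci) {
    cell <- simulation_cell(grid$n[ci], grid$icc[ci], grid$rho[ci],
                            beta = beta, reps = reps, seed = seed,
                            alpha = alpha)
    run_cell(cell, control = control, cell_index = ci,
             keep_estimates = FALSE)
  }
  res <- if (cores > 1L && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(seq_len(nrow(grid)), one, mc.cores = cores)
  } else {
    lapply(seq_len(nrow(grid)), one)
  }
  structure(list(
    coefficients = do.call(rbind, lapply(res, `[[`, "metrics")),
    cells = do.call(rbind, lapply(res, `[[`, "cells")),
    seed = seed, reps = reps),
    class = "rmelm_simgrid")
}

#' @export
print.rmelm_simgrid <- function(x, ...) {
  cat(sprintf("Simulation grid: %d cells x %d replicates (seed %d)\n",
              nrow(x$cells) / 2L, x$reps, x$seed))
  agg <- stats::aggregate(cbind(mse, power) ~ model, x$coefficients, median)
  cat("median over grid:\n")
  print(agg, digits = 3)
  invisible(x)
}
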