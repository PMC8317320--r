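#' Serialize a fit to JSON
#'
#' Writes estimates, standard errors, test statistics, odds ratios, the
#' shrinkage parameter, the random-effects covariance, the convergence trace
#' and the control settings (including any seed) needed to regenerate the
#' fit.
#'
#' @param fit an [rmelm()] fit.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "rmelm_fit"))
  ctl <- fit$control
  ctl <- ctl[!vapply(ctl, is.null, logical(1))]
  payload <- list(
    package = "rmelm",
    version = as.character(utils::packageVersion("rmelm")),
    coefficients = coefficient_table(fit),
    lambda = fit$lambda,
    lambda_mode = fit$lambda_mode,
    Q_hat = fit$Q_hat,
    loglik_penalized = fit$loglik_penalized,
    loglik_unpenalized = fit$loglik_unpenalized,
    converged = fit$converged,
    boundary = fit$boundary,
    n_iter = fit$n_iter,
    trace = fit$trace,
    control = ctl)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write the coefficient table as CSV
#'
#' One row per fixed effect with estimate, standard error, odds ratio, test
#' statistic and p-value.
#'
#' @inheritParams write_fit_json
#' @export
write_coef_csv <- function(fit, path) {
  stopifnot(inherits(fit, "rmelm_fit"))
  tab <- coefficient_table(fit)
  utils::write.csv(cbind(term = rownames(tab), tab), path, row.names = FALSE)
  invisible(path)
}
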