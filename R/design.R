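#' Construct a longitudinal design for clustered binary responses
#'
#' Bundles the stacked fixed-effect matrix `X`, random-effect matrix `Z`,
#' binary response `y` and the subject grouping into the design object used by
#' all model evaluation and fitting functions. Rows are reordered so that each
#' subject's observations are contiguous; subjects need not be contiguous (or
#' even sorted) in the input.
#'
#' @param y binary response vector (each entry exactly 0 or 1), length N.
#' @param X numeric fixed-effect matrix, N x p. Column names are kept for
#'   reporting; unnamed columns are labelled `x1, x2, ...`.
#' @param subject subject identifier per row (integer, character or factor).
#' @param Z numeric random-effect matrix, N x q. The default (`NULL`) is an
#'   intercept-only random design, a single column of ones.
#' @param penalize logical vector of length p marking which fixed-effect
#'   columns the ridge penalty applies to. Default: all of them.
#'
#' @return An object of class `"rmelm_design"`: a list with elements `y`,
#'   `X`, `Z`, `subject` (original labels, reordered), `group` (integer
#'   subject index 1..n per row), `n`, `N`, `p`, `q`, `n_i` (observations per
#'   subject) and `penalize`.
#' @seealso [read_long_csv()] to build a design from a long-format CSV file.
#' @export
long_design <- function(y, X, subject, Z = NULL, penalize = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  N <- length(y)
  if (nrow(X) != N) {
    stop("shape error: X has ", nrow(X), " rows but y has length ", N)
  }
  if (length(subject) != N) {
    stop("shape error: subject has length ", length(subject),
         " but y has length ", N)
  }
  bad <- which(!(y %in% c(0, 1)))
  if (length(bad)) {
    stop("y must be binary (0/1); offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (ncol(X) < 1L) stop("X must have at least one column")
  if (any(colSums(abs(X)) == 0)) {
    stop("X has an all-zero column: ",
         paste(colnames(X)[colSums(abs(X)) == 0], collapse = ", "))
  }
  if (is.null(Z)) {
    Z <- matrix(1, N, 1L, dimnames = list(NULL, "(Intercept)"))
  }
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  if (nrow(Z) != N) {
    stop("shape error: Z has ", nrow(Z), " rows but y has length ", N)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  q <- ncol(Z)
  if (is.null(penalize)) penalize <- rep(TRUE, p)
  if (length(penalize) != p) {
    stop("penalize must have one entry per column of X")
  }

  # group rows by subject, keeping first-appearance order of subjects
  fac <- factor(subject, levels = unique(subject))
  ord <- order(as.integer(fac))
  y <- y[ord]
  X <- X[ord, , drop = FALSE]
  Z <- Z[ord, , drop = FALSE]
  group <- as.integer(fac)[ord]
  n_i <- tabulate(group)

  structure(
    list(y = y, X = X, Z = Z,
         subject = subject[ord], group = group,
         n = nlevels(fac), N = N, p = p, q = q, n_i = n_i,
         penalize = as.logical(penalize)),
    class = "rmelm_design")
}

#' @export
print.rmelm_design <- function(x, ...) {
  cat("Longitudinal design:", x$N, "observations on", x$n, "subjects\n")
  cat("  fixed effects  (p =", x$p, "):",
      paste(colnames(x$X), collapse = ", "), "\n")
  cat("  random effects (q =", x$q, "):",
      paste(colnames(x$Z), collapse = ", "), "\n")
  cat("  obs per subject:", paste(range(x$n_i), collapse = "-"), "\n")
  invisible(x)
}

#' Read a long-format CSV into a longitudinal design
#'
#' Expects one row per observation with a `subject` column, a binary response
#' column `y`, fixed-effect covariate columns, and optionally random-effect
#' columns prefixed `z_`. When no `z_` columns are present the random design
#' defaults to a subject-level random intercept (a column of ones). An
#' intercept column is prepended to the fixed effects by default and excluded
#' from the ridge penalty, the usual ridge convention.
#'
#' @param path path to a CSV file (comma separated, header row, `.` decimal).
#' @param response,subject names of the response and subject columns.
#' @param intercept add a fixed-effect intercept column? Default `TRUE`.
#' @param penalize_intercept should the intercept be ridge-penalized?
#'   Default `FALSE`.
#' @return an [long_design()] object.
#' @export
read_long_csv <- function(path, response = "y", subject = "subject",
                          intercept = TRUE, penalize_intercept = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("empty file: ", path)
  missing_cols <- setdiff(c(response, subject), names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  y <- df[[response]]
  bad <- which(!(y %in% c(0, 1)))
  if (length(bad)) {
    stop("non-binary response in ", path, " at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  zcols <- grep("^z_", names(df), value = TRUE)
  xcols <- setdiff(names(df), c(response, subject, zcols))
  if (length(xcols) == 0L && !intercept) stop("no fixed-effect columns found")
  X <- as.matrix(df[xcols])
  penalize <- rep(TRUE, length(xcols))
  if (intercept) {
    X <- cbind("(Intercept)" = 1, X)
    penalize <- c(penalize_intercept, penalize)
  }
  Z <- if (length(zcols)) as.matrix(df[zcols]) else NULL
  long_design(y, X, df[[subject]], Z = Z, penalize = penalize)
}

#' Write a longitudinal design back to long-format CSV
#'
#' Inverse of [read_long_csv()] up to row order (rows are written grouped by
#' subject) and the intercept column, which is dropped when present.
#'
#' @param design an [long_design()] object.
#' @param path output path.
#' @export
write_long_csv <- function(design, path) {
  X <- design$X
  keep <- !(colnames(X) %in% "(Intercept)")
  df <- data.frame(subject = design$subject, y = design$y,
                   X[, keep, drop = FALSE], check.names = FALSE)
  # intercept-only Z is implicit; other random-effect columns get z_ prefix
  if (!(design$q == 1L && all(design$Z == 1))) {
    Zdf <- as.data.frame(design$Z)
    names(Zdf) <- paste0("z_", seq_len(ncol(Zdf)))
    df <- cbind(df, Zdf)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
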