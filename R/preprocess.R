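# Expression preprocessing: rank-based inverse normal transformation and
# covariate adjustment. Applied per gene per tissue before model training.

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their Blom-offset ranks,
#' `qnorm((rank - c) / (N - 2c + 1))` with `c = 3/8`. Ties get average
#' ranks. Strictly monotone for untied input.
#'
#' @param x Numeric vector, length >= 2, not constant.
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 values")
  if (anyNA(x)) stop("missing values not allowed")
  if (max(x) == min(x)) stop("constant vector carries no rank information")
  n <- length(x)
  c0 <- 3 / 8
  r <- rank(x, ties.method = "average")
  qnorm((r - c0) / (n - 2 * c0 + 1))
}

#' Residualize a vector on covariates
#'
#' Least-squares residuals of `y` on an intercept plus the covariate
#' columns; the residuals are orthogonal to every covariate.
#'
#' @param y Numeric vector.
#' @param covariates `data.frame` or matrix of numeric covariates aligned
#'   with `y` (rows = samples). `NULL` or zero columns means intercept-only
#'   (centering).
#' @return Residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  if (is.null(covariates) || NCOL(covariates) == 0L) return(y - mean(y))
  cm <- as.matrix(covariates)
  if (nrow(cm) != length(y)) stop("covariate rows must match length(y)")
  X <- cbind(`(Intercept)` = 1, cm)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("covariate design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  as.numeric(qr.resid(qr_x, y))
}

#' Prepare a per-tissue expression vector for training
#'
#' Convenience wrapper: inverse-normal transform the observed entries of a
#' tissue column, then residualize on covariates.
#'
#' @param values Numeric vector (one tissue's expression over samples).
#' @param covariates Optional covariate table aligned with `values`.
#' @return Processed vector.
#' @export
normalize_expression <- function(values, covariates = NULL) {
  residualize(inverse_normal_transform(values), covariates)
}
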