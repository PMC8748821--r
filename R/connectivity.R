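#' Ridge-regularized partial correlation
#'
#' Estimates the partial-correlation matrix of a multivariate time series:
#' the correlation between every pair of regions after removing the linear
#' influence of all other regions. Columns are z-scored, the sample
#' covariance `S` of the standardized columns is ridge-regularized as
#' `S + rho * I` (or `S + rho * mean(diag(S)) * I` with
#' `ridge = "scaled"`), and partial correlations are read off the
#' precision matrix `P = (S + rho I)^-1` as
#' `r_ij = -P_ij / sqrt(P_ii P_jj)`. The ridge keeps the estimate
#' well-conditioned when the number of regions approaches the number of
#' timepoints; `rho = 0.5` is the conventional default for parcellated
#' resting-state data.
#'
#' @param timeseries Numeric T x R matrix (timepoints by regions). Column
#'   names, if present, are carried to the result.
#' @param rho Ridge regularization parameter, >= 0. Default 0.5.
#' @param ridge `"plain"` adds `rho * I` to the standardized covariance
#'   (default); `"scaled"` adds `rho * mean(diag(S)) * I` (identical for
#'   z-scored columns, provided for unstandardized dialects).
#' @return A symmetric R x R matrix of class `sfc_connectivity` with zero
#'   diagonal and off-diagonal entries in `[-1, 1]`.
#' @examples
#' ts <- matrix(rnorm(600), 100, 6)
#' pc <- partial_correlation(ts, rho = 0.5)
#' range(pc[upper.tri(pc)])
#' @export
partial_correlation <- function(timeseries, rho = 0.5,
                                ridge = c("plain", "scaled")) {
  ridge <- match.arg(ridge)
  x <- as.matrix(timeseries)
  if (!is.numeric(x)) abort_input("timeseries must be numeric")
  check_finite(x, "timeseries")
  if (nrow(x) < 3L) abort_input("need at least 3 timepoints")
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0) {
    abort_input("rho must be a single number >= 0")
  }
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    abort_input(sprintf("constant time series in region(s): %s",
                        paste(bad, collapse = ", ")))
  }
  z <- scale(x)
  s <- crossprod(z) / (nrow(z) - 1L)
  lambda <- if (ridge == "plain") rho else rho * mean(diag(s))
  p <- tryCatch(solve(s + diag(lambda, ncol(s))),
                error = function(e) abort_input(
                  "covariance not invertible; increase rho"))
  d <- sqrt(diag(p))
  r <- -p / tcrossprod(d)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  r <- pmin(pmax(r, -1), 1)
  dimnames(r) <- list(colnames(x), colnames(x))
  class(r) <- c("sfc_connectivity", class(r))
  attr(r, "rho") <- rho
  r
}

#' Weighted degree centrality
#'
#' Total connection strength of each region: the row sum of edge weights.
#' With `mode = "absolute"` (default) negative partial correlations
#' contribute their magnitude; with `"positive_only"` they are ignored.
#'
#' @param fc Symmetric connectivity matrix (e.g. from
#'   [partial_correlation()]).
#' @param mode `"absolute"` or `"positive_only"`.
#' @return Numeric vector of length R, named if `fc` has dimnames.
#' @export
degree_centrality <- function(fc, mode = c("absolute", "positive_only")) {
  mode <- match.arg(mode)
  w <- unclass(as.matrix(fc))
  check_finite(w, "connectivity matrix")
  diag(w) <- 0
  w <- if (mode == "absolute") abs(w) else pmax(w, 0)
  rowSums(w)
}

#' Residualize values on nuisance covariates
#'
#' Per-column ordinary-least-squares regression on an intercept plus the
#' covariates; returns residuals with the original column means added back
#' (so downstream thresholds on the values' scale remain comparable).
#' Used for the sensitivity analyses that control degree or edge values for
#' age, sex, and eating-behavior scores.
#'
#' @param values Numeric subjects x K matrix (or data frame) of degrees or
#'   edge weights.
#' @param covariates Numeric subjects x C matrix or data frame; factors and
#'   character columns are expanded via [stats::model.matrix()] (sex coded
#'   0/1).
#' @param keep_mean Add the original column mean back to the residuals
#'   (default `TRUE`).
#' @return Matrix of residualized values, same shape and dimnames as
#'   `values`.
#' @export
regress_out <- function(values, covariates, keep_mean = TRUE) {
  y <- as.matrix(values)
  check_finite(y, "values")
  cv <- as.data.frame(covariates)
  if (nrow(cv) != nrow(y)) abort_input("values and covariates disagree on subjects")
  x <- stats::model.matrix(~ ., data = cv)
  if (nrow(y) <= ncol(x)) {
    abort_input("need more subjects than covariates (plus intercept)")
  }
  if (qr(x)$rank < ncol(x)) abort_input("covariate design is rank-deficient")
  fit <- stats::lm.fit(x, y)
  res <- as.matrix(fit$residuals)
  if (keep_mean) res <- sweep(res, 2L, colMeans(y), `+`)
  dimnames(res) <- dimnames(y)
  res
}
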