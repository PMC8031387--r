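# Model assessment: leave-one-out cross-validation, R-squared, Monte-Carlo
# relative efficiency, and leverage diagnostics.

fit_estimator <- function(data, estimator, k, d, scores, scaling) {
  switch(estimator,
    ridge_ls   = ridge_ls(data, k, scaling),
    rank       = fit_rank(data, scores)$beta,
    rank_ridge = ridge_rank(data, k, scores, scaling)$coef,
    sse        = sse(data, k, d, scores, scaling)$beta,
    stop_input("unknown estimator '%s'", estimator)
  )
}

#' Leave-one-out cross-validation
#'
#' For each sample `s` the chosen estimator is refitted on the remaining
#' `n - 1` samples (tuning parameters held fixed at their full-data values --
#' one CV number per estimator at its selected tuning) and the held-out
#' response is predicted; the criterion is the mean squared prediction error
#' \eqn{n^{-1}\sum_s (y_s - \hat y_{-s})^2}.  Standardization is redone
#' inside every fold and coefficients are back-transformed, so predictions
#' are on the raw response scale.
#'
#' A fold whose refit fails is marked and excluded; more than 10 percent failed
#' folds aborts with an error.
#'
#' @param X Raw design matrix (n x p).
#' @param y Raw response (length n, n >= 3).
#' @param estimator `"ridge_ls"`, `"rank_ridge"`, `"sse"` or `"rank"`.
#' @param k,d Tuning parameters (held fixed across folds).
#' @param scores_name Score system name (default `"wilcoxon"`).
#' @param standardize,scaling Passed to [prepare_data()] / the estimator.
#' @return Nonnegative scalar; attribute `n_failed` counts failed folds.
#' @export
loo_cv <- function(X, y, estimator = c("sse", "rank_ridge", "ridge_ls", "rank"),
                   k = NULL, d = 0, scores_name = "wilcoxon",
                   standardize = TRUE,
                   scaling = c("calibrated", "literal")) {
  estimator <- match.arg(estimator)
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop_input("leave-one-out CV needs n >= 3 (got %d)", n)
  if (estimator != "rank" && is.null(k)) {
    stop_input("estimator '%s' needs a ridge parameter k", estimator)
  }
  err2 <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    err2[s] <- tryCatch({
      dtr <- prepare_data(X[-s, , drop = FALSE], y[-s], standardize)
      sc <- make_scores(dtr$n, scores_name)
      beta_std <- fit_estimator(dtr, estimator, k, d, sc, scaling)
      beta_raw <- beta_std / dtr$column_scales
      pred <- dtr$y_center +
        sum((X[s, ] - dtr$column_centers) * beta_raw)
      (y[s] - pred)^2
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(err2))
  if (n_failed > 0.1 * n) {
    stop_numeric("leave-one-out CV aborted: %d of %d folds failed", n_failed, n)
  }
  out <- mean(err2, na.rm = TRUE)
  attr(out, "n_failed") <- n_failed
  out
}

#' R-squared goodness of fit
#'
#' Two variants are computed because two formulas circulate:
#' \describe{
#'   \item{`standard`}{\eqn{1 - \sum_i (y_i - \hat y_i)^2 / S_{yy}} (residual
#'     sum of squares in the numerator; always \eqn{\le 1}).}
#'   \item{`printed`}{\eqn{1 - \sum_i (\hat y_i - \bar y)^2 / S_{yy}}
#'     (fitted-value spread in the numerator, a formula sometimes printed
#'     under the same name; equal to the standard variant only for
#'     projection fits).}
#' }
#' with \eqn{S_{yy} = \sum_i (y_i - \bar y)^2}.
#'
#' @param y Observed response.
#' @param fitted Fitted values (same length, same scale as `y`).
#' @param variant `"standard"` (default) or `"printed"`.
#' @return Scalar.
#' @export
r_squared <- function(y, fitted, variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  if (length(y) != length(fitted)) {
    stop_input("'y' and 'fitted' must have equal length")
  }
  syy <- sum((y - mean(y))^2)
  if (syy <= 0) stop_numeric("degenerate response: Syy = 0")
  switch(variant,
    standard = 1 - sum((y - fitted)^2) / syy,
    printed  = 1 - sum((fitted - mean(y))^2) / syy
  )
}

#' Monte-Carlo relative efficiency
#'
#' For per-replicate coefficient estimates
#' \eqn{\hat\beta_i^{(m)}, m = 1, \dots, M} of several methods, the
#' efficiency of method i relative to the reference (first) method is the
#' ratio of mean squared estimation risks
#' \deqn{\mathrm{eff}(\hat\beta_i, \hat\beta_1) =
#'   \frac{M^{-1}\sum_m \|\hat\beta_1^{(m)} - \beta\|^2}
#'        {M^{-1}\sum_m \|\hat\beta_i^{(m)} - \beta\|^2};}
#' values above 1 mean method i beats the reference.
#'
#' @param estimates Named list of M x p matrices (one row per replicate);
#'   the first element is the reference method.
#' @param beta_true True coefficient vector (length p).
#' @return Named numeric vector of efficiencies (reference itself maps to 1).
#' @export
efficiency <- function(estimates, beta_true) {
  if (!is.list(estimates) || length(estimates) < 1L) {
    stop_input("'estimates' must be a nonempty list of replicate matrices")
  }
  p <- length(beta_true)
  mses <- vapply(estimates, function(B) {
    B <- as.matrix(B)
    if (ncol(B) != p) stop_input("estimate matrix has %d columns, expected %d",
                                 ncol(B), p)
    mean(rowSums(sweep(B, 2L, beta_true, "-")^2))
  }, 0)
  if (any(mses <= 0)) {
    stop_numeric("degenerate efficiency: a method has zero estimation risk")
  }
  out <- mses[[1L]] / mses
  names(out) <- names(estimates) %||% paste0("method", seq_along(estimates))
  out
}

#' Leverage of the design points
#'
#' The diagonal \eqn{h_{iin}} of the projection
#' \eqn{H = X(X^\top X)^{-1}X^\top} for full-column-rank designs: each entry
#' lies in \eqn{[0, 1]} and they sum to p.  For rank-deficient designs a
#' ridge-regularized leverage \eqn{h_i(k) = n^{-1} x_i^\top A_k^{-1} x_i}
#' (which tends to the projection diagonal as \eqn{k \to 0} in the full-rank
#' case) is returned when `k` is supplied; otherwise an error asks for it.
#'
#' @param data An [prepare_data()] object.
#' @param k Optional ridge parameter for the regularized variant.
#' @return Length-n vector of leverages.
#' @export
leverage <- function(data, k = NULL) {
  if (!inherits(data, "rr_data")) stop_input("'data' must be an rr_data object")
  if (is.null(k)) {
    if (data$rank < data$p) {
      stop_numeric(paste("design is rank-deficient; supply a ridge parameter",
                         "k for regularized leverage"))
    }
    return(rowSums(data$u^2))
  }
  check_scalar(k, "k")
  if (k <= 0) stop_input("ridge parameter k must be > 0 (got %g)", k)
  rowSums(sweep(data$u^2, 2L, data$lambda / (data$lambda + k), "*"))
}
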