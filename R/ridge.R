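#' Ridge least-squares estimator
#'
#' The classical ridge comparator
#' \deqn{\hat\beta(k) = s\,(n^{-1}X^\top X + k I_p)^{-1} X^\top y,}
#' where the scaling factor is \eqn{s = 1/n} in the default `"calibrated"`
#' convention -- chosen so that \eqn{k \to 0} recovers the least-squares
#' solution when \eqn{\mathrm{rank}(X) = p} -- and \eqn{s = 1} in the
#' `"literal"` convention that matches the un-normalized form of the
#' estimator.  Both conventions are exposed because they are used in different
#' places of the methodology (see the package vignette).
#'
#' @param data An [prepare_data()] object.
#' @param k Ridge parameter, `k > 0` (`k = 0` allowed only for full
#'   column rank).
#' @param scaling `"calibrated"` (default) or `"literal"`.
#' @return Named coefficient vector of length p.
#' @export
ridge_ls <- function(data, k, scaling = c("calibrated", "literal")) {
  if (!inherits(data, "rr_data")) stop_input("'data' must be an rr_data object")
  scaling <- match.arg(scaling)
  check_scalar(k, "k", min = 0)
  if (k == 0 && data$rank < data$p) {
    stop_numeric("k = 0 requires a full-column-rank design; got rank %d < p = %d",
                 data$rank, data$p)
  }
  s <- if (scaling == "calibrated") 1 / data$n else 1
  w <- crossprod(data$X, data$y)
  stats::setNames(drop(s * ak_solve(data, k, w)), data$colnames)
}

# TRUE when the dispersion minimum is degenerate: with centred columns the
# rank-(n-1) column space already contains the centred response.
is_saturated <- function(data) data$rank >= data$n - 1L

# tau-hat when no exact rank fit exists (saturated designs): pilot ridge fit
# tuned by 1-D GCV on the least-squares smoother L1 -- restricted to fits
# keeping at least 25% residual degrees of freedom, since GCV degenerates in
# the interpolation regime when p > n -- then the Koul-Sievers-McKean
# estimator on the pilot residuals with effective-df correction.
pilot_tau <- function(data, scores, n_k = 25L) {
  lam <- data$lambda
  n <- data$n
  uy <- crossprod(data$u, data$y)
  y2 <- sum(data$y^2)
  kmax <- 0.999 * (1 + if (data$rank < data$p) 0 else min(lam))
  ks <- exp(seq(log(1e-4), log(kmax), length.out = n_k))
  gcvs <- vapply(ks, function(k) {
    cj <- lam / (lam + k)
    den <- 1 - sum(cj) / n
    if (den <= 0.25) return(NA_real_)
    num <- (y2 - 2 * sum(cj * uy^2) + sum(cj^2 * uy^2)) / n
    num / den^2
  }, 0)
  if (all(is.na(gcvs))) stop_numeric("pilot ridge GCV undefined on the whole grid")
  kstar <- ks[which.min(gcvs)]
  cj <- lam / (lam + kstar)
  resid <- data$y - drop(data$u %*% (cj * uy))
  edf <- min(round(sum(cj)), n - 2L)
  estimate_tau(resid, scores, p = edf)
}

# Shared tau: exact rank-fit residuals when available, pilot otherwise.
tau_for <- function(data, scores, rank_fit = NULL) {
  if (!is.null(rank_fit)) return(rank_fit$tau_hat)
  if (!is_saturated(data)) fit_rank(data, scores)$tau_hat
  else pilot_tau(data, scores)
}

#' Rank ridge regression estimator
#'
#' The robust ridge estimator
#' \deqn{\hat\beta_\psi(k) = s\,(n^{-1}X^\top X + k I_p)^{-1} X^\top
#'   \hat{y}_\psi,}
#' where \eqn{\hat y_\psi} is the rank-fit prediction \eqn{X\hat\beta_\psi}
#' from [fit_rank()] when \eqn{\mathrm{rank}(X) < n}.  In the saturated case
#' (\eqn{\mathrm{rank}(X) = n}, e.g. \eqn{p > n}) the dispersion minimum over
#' the column space degenerates to \eqn{\hat y_\psi = y}; there the linearized
#' surrogate \eqn{X^\top \hat y_\psi \to 2\hat\tau_\psi X^\top y} is used, so
#' that the fitted values equal \eqn{L_2(k) y} with
#' \eqn{L_2(k) = 2\hat\tau_\psi\, s\, X (n^{-1}X^\top X + kI)^{-1} X^\top}
#' (see [hat_matrix()]).  The mode used is recorded on the result.
#'
#' @inheritParams ridge_ls
#' @param scores Score system; default Wilcoxon.
#' @param rank_fit Optional precomputed [fit_rank()] result (avoids refitting).
#' @param tau Optional \eqn{\hat\tau_\psi} override.
#' @return Object of class `rank_ridge_fit` with `coef`, `fitted`, `k`,
#'   `tau_hat`, `mode` (`"rank_fit"` or `"saturated"`) and `scaling`.
#' @export
ridge_rank <- function(data, k, scores = NULL,
                       scaling = c("calibrated", "literal"),
                       rank_fit = NULL, tau = NULL) {
  if (!inherits(data, "rr_data")) stop_input("'data' must be an rr_data object")
  scaling <- match.arg(scaling)
  check_scalar(k, "k")
  if (k <= 0) stop_input("ridge parameter k must be > 0 (got %g)", k)
  scores <- scores %||% make_scores(data$n)
  s <- if (scaling == "calibrated") 1 / data$n else 1
  if (!is_saturated(data)) {
    rf <- rank_fit %||% fit_rank(data, scores)
    tau <- tau %||% rf$tau_hat
    target <- crossprod(data$X, rf$fitted)
    mode <- "rank_fit"
  } else {
    tau <- tau %||% pilot_tau(data, scores)
    target <- 2 * tau * crossprod(data$X, data$y)
    mode <- "saturated"
  }
  beta <- drop(s * ak_solve(data, k, target))
  structure(
    list(coef = stats::setNames(beta, data$colnames),
         fitted = drop(data$X %*% beta),
         k = k, tau_hat = tau, mode = mode, scaling = scaling),
    class = "rank_ridge_fit"
  )
}

#' @export
print.rank_ridge_fit <- function(x, ...) {
  cat(sprintf("<rank_ridge_fit> k = %g, tau_hat = %.4f, mode = %s (%s scaling)\n",
              x$k, x$tau_hat, x$mode, x$scaling))
  invisible(x)
}

#' Stein-type shrinkage estimator (SSE)
#'
#' Shrinks the rank ridge coefficients toward the origin using the ridge
#' rank-based test statistic:
#' \deqn{\hat\beta_\psi^{(S)}(k, d) = \Big(1 - \frac{d}{R_n(k)}\Big)
#'   \hat\beta_\psi(k), \qquad d \ge 0.}
#' At \eqn{d = 0} the SSE equals the rank ridge estimator exactly; at
#' \eqn{d = R_n(k)} it is the zero vector.  No positive-part truncation is
#' applied by default, so for \eqn{d > R_n(k)} the coefficient signs flip;
#' set `positive_part = TRUE` to truncate the shrinkage factor at zero.
#'
#' @inheritParams ridge_rank
#' @param d Shrinkage parameter, `d >= 0`.
#' @param positive_part Truncate the factor \eqn{1 - d/R_n(k)} at 0?
#'   Default `FALSE`.
#' @param rn Optional precomputed \eqn{R_n(k)} (see [rn_statistic()]).
#' @return Object of class `shrinkage_estimate` with `k`, `d`, `rn`, `beta`,
#'   `fitted`, `tau_hat`, `factor`, `mode`, `scaling`.
#' @export
sse <- function(data, k, d, scores = NULL,
                scaling = c("calibrated", "literal"),
                positive_part = FALSE, rank_fit = NULL, rn = NULL,
                tau = NULL) {
  scaling <- match.arg(scaling)
  check_scalar(d, "d", min = 0)
  scores <- scores %||% make_scores(data$n)
  rr <- ridge_rank(data, k, scores, scaling, rank_fit = rank_fit, tau = tau)
  rn <- rn %||% rn_statistic(data, k, scores)
  if (rn < 0) {
    stop_numeric("R_n(k) = %g is negative at k = %g: X(k) lost positive definiteness",
                 rn, k)
  }
  if (rn == 0 && d > 0) {
    stop_numeric("untestable shrinkage: R_n(k) = 0 with d = %g > 0", d)
  }
  fac <- if (d == 0) 1 else 1 - d / rn
  if (positive_part) fac <- max(fac, 0)
  structure(
    list(k = k, d = d, rn = rn,
         beta = fac * rr$coef, fitted = fac * rr$fitted,
         tau_hat = rr$tau_hat, factor = fac,
         mode = rr$mode, scaling = scaling),
    class = "shrinkage_estimate"
  )
}

#' @export
print.shrinkage_estimate <- function(x, ...) {
  cat(sprintf(
    "<shrinkage_estimate> k = %g, d = %g, R_n(k) = %.4f, shrink factor = %.4f\n",
    x$k, x$d, x$rn, x$factor))
  invisible(x)
}
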