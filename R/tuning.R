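# Hat matrices, the GCV criterion, risk decomposition and joint (k, d)
# selection.  All traces and residual norms are computed from the stored SVD,
# so no n x n matrix is formed unless the user explicitly asks for one.

# Eigenvalues of the ridge least-squares smoother L1 = s X A_k^{-1} X'
# on the left singular directions: s * n * lambda / (lambda + k).
l1_factors <- function(data, k, scaling) {
  s <- if (scaling == "calibrated") 1 / data$n else 1
  s * data$n * data$lambda / (data$lambda + k)
}

#' Hat matrices of the ridge, rank ridge and shrinkage smoothers
#'
#' The three linear smoothers mapping `y` to fitted values:
#' \deqn{L_1(k) = s\,X A_k^{-1} X^\top, \quad
#'       L_2(k) = 2\hat\tau_\psi L_1(k), \quad
#'       L(k, d) = \Big(1 - \frac{d}{R_n(k)}\Big) L_2(k),}
#' with \eqn{A_k = n^{-1}X^\top X + k I_p} and scaling factor
#' \eqn{s \in \{1/n, 1\}} per the `scaling` convention.  \eqn{L_1} is the hat
#' matrix of [ridge_ls()], \eqn{L_2} of [ridge_rank()] in the saturated mode,
#' and \eqn{L(k,d)} of the shrinkage estimator [sse()].
#'
#' @inheritParams ridge_rank
#' @param d Shrinkage parameter (used by `which = "L"`).
#' @param which `"L"` (default), `"L1"` or `"L2"`.
#' @param tau Optional \eqn{\hat\tau_\psi} override.
#' @return n x n matrix.
#' @export
hat_matrix <- function(data, k, d = 0, scores = NULL,
                       which = c("L", "L1", "L2"),
                       scaling = c("calibrated", "literal"),
                       tau = NULL, rank_fit = NULL) {
  if (!inherits(data, "rr_data")) stop_input("'data' must be an rr_data object")
  which <- match.arg(which)
  scaling <- match.arg(scaling)
  check_scalar(k, "k")
  if (k <= 0) stop_input("ridge parameter k must be > 0 (got %g)", k)
  scores <- scores %||% make_scores(data$n)
  cf <- l1_factors(data, k, scaling)
  U <- data$u
  L1 <- U %*% (cf * t(U))
  if (which == "L1") return(L1)
  tau <- tau %||% tau_for(data, scores, rank_fit)
  L2 <- 2 * tau * L1
  if (which == "L2") return(L2)
  check_scalar(d, "d", min = 0)
  rn <- rn_statistic(data, k, scores)
  if (rn == 0 && d > 0) stop_numeric("R_n(k) = 0 with d > 0: L(k,d) undefined")
  (1 - if (d == 0) 0 else d / rn) * L2
}

#' Generalized cross-validation score of a linear smoother
#'
#' \deqn{\mathrm{GCV}(L) = \frac{n^{-1}\|(I - L)y\|^2}
#'   {\big(1 - n^{-1}\,\mathrm{tr}\,L\big)^2}.}
#' Returns `NA` (flagged, not thrown) when the denominator degenerates
#' (\eqn{1 - n^{-1}\mathrm{tr}\,L \le 10^{-6}}), which happens when the
#' smoother saturates -- routine in \eqn{p > n} regimes at small `k`.
#'
#' @param L n x n hat matrix.
#' @param y Response vector of length n.
#' @return Positive scalar, or `NA_real_` when undefined.
#' @examples
#' gcv(matrix(0, 2, 2), c(1, 1))        # ||y||^2 / n = 1
#' gcv(diag(2), c(1, 1))                # NA: saturated smoother
#' @export
gcv <- function(L, y) {
  if (!is.matrix(L) || nrow(L) != ncol(L)) stop_input("'L' must be square")
  n <- length(y)
  if (nrow(L) != n) {
    stop_input("dim(L) = %d does not match length(y) = %d", nrow(L), n)
  }
  den <- 1 - sum(diag(L)) / n
  if (den <= 1e-6) return(NA_real_)
  (sum((y - L %*% y)^2) / n) / den^2
}

# Fast GCV through the eigen route: the smoother is U diag(cl) U' with
# cl = mult * l1_factors.  uy = U'y and y2 = ||y||^2 are precomputed.
# min_den guards the near-interpolation regime where GCV degenerates.
gcv_fast <- function(cl, uy, y2, n, min_den = 1e-6) {
  tr <- sum(cl)
  den <- 1 - tr / n
  if (den <= min_den) return(NA_real_)
  num <- (y2 - 2 * sum(cl * uy^2) + sum(cl^2 * uy^2)) / n
  num / den^2
}

# Largest k keeping X(k) positive definite (printed form): k < 1 + lambda_min
# over the full spectrum (lambda_min = 0 for rank-deficient designs).
k_valid_max <- function(data) {
  lam_min <- if (data$rank < data$p) 0 else min(data$lambda)
  0.999 * (1 + lam_min)
}

#' Joint selection of the ridge and shrinkage parameters by GCV
#'
#' Evaluates the GCV criterion over a grid and selects the minimizer.  For
#' `estimator = "sse"` the search is two-dimensional over \eqn{(k, d)} with
#' the smoother \eqn{L(k, d)}; for `"rank_ridge"` and `"ridge"` it is
#' one-dimensional over `k` with \eqn{L_2(k)} and \eqn{L_1(k)} respectively.
#' The best grid cell is then refined by a derivative-free Nelder-Mead search
#' in log-parameters (relative tolerance 1e-8) unless `refine = FALSE`.
#'
#' Default grids: `k` log-spaced over \eqn{[10^{-4}, k_{\max}]} with
#' `n_k` points, where \eqn{k_{\max}} is the largest `k` keeping \eqn{X(k)}
#' positive definite; `d` is parameterized as a fraction of \eqn{R_n(k)},
#' log-spaced over \eqn{[10^{-6}, 1]} with `n_d` points, so the grid always
#' spans the full shrinkage range from "no shrinkage" to "shrink to zero".
#' Cells where the GCV denominator degenerates or \eqn{X(k)} is invalid are
#' flagged `NA` and skipped.  With centred data the denominator
#' \eqn{1 - \mu_1} cannot fall below about \eqn{1/n} even for interpolating
#' fits, so a tiny threshold never activates in \eqn{p > n} regimes; the
#' guard is therefore an effective-degrees-of-freedom cap: cells keeping less
#' than `min_resid_frac` (default 10 percent) residual degrees of freedom are
#' invalid, which excludes the near-interpolation regime where GCV
#' degenerates toward zero.
#'
#' @inheritParams ridge_rank
#' @param estimator `"sse"` (default), `"rank_ridge"` or `"ridge"`.
#' @param k_grid Optional increasing vector of positive ridge parameters.
#' @param d_grid Optional vector of shrinkage fractions in (0, 1] of
#'   \eqn{R_n(k)} (SSE only).
#' @param n_k,n_d Default grid sizes (40 each).
#' @param refine Run the local continuous refinement? Default `TRUE`.
#' @param min_resid_frac Minimum residual-degrees-of-freedom fraction for a
#'   cell to be valid (default 0.1).
#' @return Object of class `tuning_result`: `k_opt`, `d_opt` (absolute),
#'   `gcv_min`, the `gcv_surface` (k by d matrix, `NA` = undefined cell),
#'   `k_grid`, `d_frac_grid`, `mu1` and `mu2` (trace fractions of the
#'   selected smoother), `rn_opt`, `tau_hat`, `refined`, `estimator`,
#'   `scaling`.
#' @export
optimize_gcv <- function(data, scores = NULL,
                         estimator = c("sse", "rank_ridge", "ridge"),
                         k_grid = NULL, d_grid = NULL,
                         n_k = 40L, n_d = 40L,
                         scaling = c("calibrated", "literal"),
                         refine = TRUE, min_resid_frac = 0.1,
                         rank_fit = NULL, tau = NULL) {
  if (!inherits(data, "rr_data")) stop_input("'data' must be an rr_data object")
  estimator <- match.arg(estimator)
  scaling <- match.arg(scaling)
  scores <- scores %||% make_scores(data$n)
  n <- data$n

  kmax <- k_valid_max(data)
  if (is.null(k_grid)) {
    k_grid <- exp(seq(log(1e-4), log(kmax), length.out = n_k))
  } else {
    if (any(k_grid <= 0)) stop_input("k_grid must be strictly positive")
    k_grid <- sort(k_grid)
  }
  need_tau <- estimator != "ridge"
  tau <- if (need_tau) (tau %||% tau_for(data, scores, rank_fit)) else NA_real_

  uy <- drop(crossprod(data$u, data$y))
  y2 <- sum(data$y^2)

  if (estimator == "sse") {
    if (is.null(d_grid)) {
      d_frac <- exp(seq(log(1e-6), 0, length.out = n_d))
    } else {
      if (any(d_grid <= 0 | d_grid > 1)) {
        stop_input("d_grid must contain shrinkage fractions in (0, 1]")
      }
      d_frac <- sort(d_grid)
    }
  } else {
    d_frac <- 0
  }

  nk <- length(k_grid)
  nd <- length(d_frac)
  surface <- matrix(NA_real_, nk, nd,
                    dimnames = list(signif(k_grid, 6), signif(d_frac, 6)))
  rn_k <- rep(NA_real_, nk)

  min_den <- max(1e-6, min_resid_frac)
  cell_gcv <- function(k, frac) {
    base <- l1_factors(data, k, scaling)
    mult <- switch(estimator,
      ridge = 1,
      rank_ridge = 2 * tau,
      sse = (1 - frac) * 2 * tau
    )
    gcv_fast(mult * base, uy, y2, n, min_den)
  }

  for (i in seq_len(nk)) {
    k <- k_grid[i]
    if (estimator == "sse") {
      rn_k[i] <- tryCatch(rn_statistic(data, k, scores),
                          rr_numeric_error = function(e) NA_real_)
      if (is.na(rn_k[i])) next
    }
    for (j in seq_len(nd)) {
      surface[i, j] <- cell_gcv(k, d_frac[j])
    }
  }

  if (all(is.na(surface))) {
    stop_numeric(paste(
      "no valid (k, d) cell: either X(k) is indefinite on the whole grid or",
      "the GCV denominator degenerates everywhere"))
  }
  best <- arrayInd(which.min(surface), dim(surface))
  k_opt <- k_grid[best[1]]
  frac_opt <- d_frac[best[2]]
  gcv_min <- surface[best[1], best[2]]

  refined <- FALSE
  if (refine && (nk > 1L || nd > 1L)) {
    if (estimator == "sse" && nd > 1L) {
      obj <- function(par) {
        k <- exp(par[1]); frac <- exp(par[2])
        if (k >= kmax || k <= 0 || frac > 1) return(1e300)
        val <- cell_gcv(k, frac)
        if (is.na(val)) 1e300 else val
      }
      op <- stats::optim(c(log(k_opt), log(frac_opt)), obj,
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-8, maxit = 400))
      if (op$value < gcv_min) {
        k_opt <- exp(op$par[1]); frac_opt <- exp(op$par[2])
        gcv_min <- op$value
      }
      refined <- TRUE
    } else if (nk > 1L) {
      i <- best[1]
      lo <- k_grid[max(1L, i - 1L)]
      hi <- k_grid[min(nk, i + 1L)]
      op <- stats::optimize(function(lk) {
        val <- cell_gcv(exp(lk), frac_opt)
        if (is.na(val)) 1e300 else val
      }, interval = c(log(lo), log(hi)), tol = 1e-8)
      if (op$objective < gcv_min) {
        k_opt <- exp(op$minimum)
        gcv_min <- op$objective
      }
      refined <- TRUE
    }
  }

  rn_opt <- if (estimator == "sse") rn_statistic(data, k_opt, scores) else NA_real_
  d_opt <- if (estimator == "sse") frac_opt * rn_opt else 0
  mult_opt <- switch(estimator,
    ridge = 1, rank_ridge = 2 * tau, sse = (1 - frac_opt) * 2 * tau)
  cl_opt <- mult_opt * l1_factors(data, k_opt, scaling)

  structure(
    list(k_opt = k_opt, d_opt = d_opt, d_frac_opt = frac_opt,
         gcv_min = gcv_min, gcv_surface = surface,
         k_grid = k_grid, d_frac_grid = d_frac,
         mu1 = sum(cl_opt) / n, mu2 = sum(cl_opt^2) / n,
         rn_opt = rn_opt, tau_hat = tau,
         refined = refined, estimator = estimator, scaling = scaling),
    class = "tuning_result"
  )
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %s: k_opt = %.6g", x$estimator, x$k_opt))
  if (x$estimator == "sse") cat(sprintf(", d_opt = %.6g", x$d_opt))
  cat(sprintf(", min GCV = %.6g%s\n", x$gcv_min,
              if (x$refined) " (refined)" else ""))
  invisible(x)
}

#' Risk decomposition of the shrinkage smoother
#'
#' For known true coefficients (simulation use), decomposes the expected
#' estimation risk of the fitted values into squared bias and variance terms:
#' \deqn{b^2(k,d) = n^{-1}\|(I - L(k,d)) X\beta\|^2, \quad
#'       \mu_1 = n^{-1}\mathrm{tr}\,L, \quad
#'       \mu_2 = n^{-1}\mathrm{tr}\,L^2,}
#' and the plug-in risk estimate \eqn{b^2 + \hat\tau_\psi^2 \mu_2}.
#'
#' @inheritParams ridge_rank
#' @param beta_true True coefficient vector (length p).
#' @param d Shrinkage parameter.
#' @return Named list `b2`, `mu1`, `mu2`, `risk_estimate`, `tau_hat`.
#' @export
risk_components <- function(data, beta_true, k, d = 0, scores = NULL,
                            scaling = c("calibrated", "literal"),
                            tau = NULL, rank_fit = NULL) {
  if (!inherits(data, "rr_data")) stop_input("'data' must be an rr_data object")
  scaling <- match.arg(scaling)
  check_scalar(k, "k")
  if (k <= 0) stop_input("ridge parameter k must be > 0 (got %g)", k)
  check_scalar(d, "d", min = 0)
  if (length(beta_true) != data$p) {
    stop_input("beta_true must have length p = %d", data$p)
  }
  scores <- scores %||% make_scores(data$n)
  tau <- tau %||% tau_for(data, scores, rank_fit)
  rn <- rn_statistic(data, k, scores)
  if (rn == 0 && d > 0) stop_numeric("R_n(k) = 0 with d > 0")
  fac <- if (d == 0) 1 else 1 - d / rn
  cl <- fac * 2 * tau * l1_factors(data, k, scaling)
  uxb <- data$d * drop(crossprod(data$v, beta_true))  # U' X beta
  b2 <- sum(((1 - cl) * uxb)^2) / data$n
  mu1 <- sum(cl) / data$n
  mu2 <- sum(cl^2) / data$n
  list(b2 = b2, mu1 = mu1, mu2 = mu2,
       risk_estimate = b2 + tau^2 * mu2, tau_hat = tau)
}

#' Export a GCV surface in long format
#'
#' @param tr A [optimize_gcv()] result.
#' @return A data frame with columns `k`, `d_frac`, `gcv`, `valid`, suitable
#'   for contour plotting or TSV export.
#' @export
gcv_surface_long <- function(tr) {
  if (!inherits(tr, "tuning_result")) stop_input("'tr' must be a tuning_result")
  grid <- expand.grid(k = tr$k_grid, d_frac = tr$d_frac_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$gcv <- as.vector(tr$gcv_surface)
  grid$valid <- !is.na(grid$gcv)
  grid
}
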