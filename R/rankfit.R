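#' Rank (R-) estimation of regression coefficients
#'
#' Minimizes the Jaeckel dispersion \eqn{D_\psi(\beta) = \|y - X\beta\|_\psi}
#' over \eqn{\beta}, a convex piecewise-linear objective whose minimizer is
#' the rank regression estimate \eqn{\hat\beta_\psi}.  At the solution the
#' rank normal equations \eqn{X^\top a(R(y - X\beta)) = 0} hold up to the
#' subgradient tolerance.
#'
#' The optimizer takes scored Gauss-Newton steps: from the current residuals
#' \eqn{e} it forms the negative gradient \eqn{X^\top a(R(e))}, maps it
#' through \eqn{(X^\top X)^{-1}} (via the stored SVD) and performs an exact
#' line search on the convex dispersion along that direction.  Iteration stops
#' when the relative dispersion decrease falls below `tol_disp` or the
#' gradient norm below `tol_grad` (relative to its initial magnitude), with at
#' most `max_iter` steps.  Initialization is at the minimum-norm least-squares
#' solution.
#'
#' The unpenalized dispersion minimum is degenerate when the design has full
#' row rank (the fitted values can reproduce `y` exactly); in that case an
#' error directs the user to [ridge_rank()].
#'
#' @param data An [prepare_data()] object.
#' @param scores Score system; defaults to Wilcoxon scores of matching size.
#' @param max_iter Maximum number of Gauss-Newton steps (default 200).
#' @param tol_disp Relative dispersion-decrease convergence tolerance
#'   (default 1e-10).
#' @param tol_grad Relative gradient-norm convergence tolerance (default 1e-8).
#' @return An object of class `rank_fit` with components `beta`, `fitted`,
#'   `residuals` (on the centred scale), `dispersion_value`, `tau_hat`
#'   (scale estimate, see [estimate_tau()]), `converged` and `iterations`.
#' @examples
#' set.seed(1)
#' x <- rnorm(10)
#' d <- prepare_data(cbind(x), 2 * x, standardize = FALSE)
#' fit_rank(d)$beta          # exactly 2: noise-free recovery
#' @export
fit_rank <- function(data, scores = NULL, max_iter = 200L,
                     tol_disp = 1e-10, tol_grad = 1e-8) {
  if (!inherits(data, "rr_data")) stop_input("'data' must be an rr_data object")
  scores <- scores %||% make_scores(data$n)
  if (scores$n != data$n) {
    stop_input("score system size (%d) does not match the data (n = %d)",
               scores$n, data$n)
  }
  if (data$rank >= data$n - 1L) {
    # with centred columns the column space at rank n-1 is the whole sum-zero
    # subspace, which contains the centred y: the dispersion minimum is y itself
    stop_numeric(paste(
      "design is saturated (rank >= n - 1): the unpenalized dispersion minimum",
      "is degenerate (the centred y is fitted exactly); use ridge_rank() instead"))
  }
  n <- data$n
  U <- data$u
  dd <- data$d
  V <- data$v
  y <- data$y

  # minimum-norm least-squares start
  beta <- drop(V %*% (crossprod(U, y) / dd))
  e <- y - drop(data$X %*% beta)

  disp_of <- function(e) sum(score_at_ranks(scores, e) * e)
  D <- disp_of(e)
  g0 <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ar <- score_at_ranks(scores, e)
    grad_norm <- {
      g <- dd * crossprod(U, ar)  # V' X' a(R(e)) has the same norm as X'a
      sqrt(sum(g^2))
    }
    if (is.null(g0)) g0 <- max(grad_norm, 1)
    if (grad_norm <= tol_grad * g0) {
      converged <- TRUE
      break
    }
    # direction u = (X'X)^{-1} X' a(R(e));  X u = U U' a (projection of a)
    dir <- drop(V %*% (crossprod(U, ar) / dd))
    step_resid <- drop(U %*% crossprod(U, ar))
    if (sum(step_resid^2) <= .Machine$double.eps * sum(ar^2)) {
      converged <- TRUE
      break
    }
    g <- function(t) disp_of(e - t * step_resid)
    hi <- 1
    while (hi < 1e6 && g(2 * hi) < g(hi)) hi <- 2 * hi
    opt <- stats::optimize(g, interval = c(0, 2 * hi), tol = 1e-12)
    Dnew <- opt$objective
    if (Dnew >= D - tol_disp * max(1, abs(D))) {
      converged <- TRUE
      break
    }
    beta <- beta + opt$minimum * dir
    e <- e - opt$minimum * step_resid
    D <- Dnew
  }
  if (!converged) {
    warning("fit_rank did not converge in ", max_iter,
            " iterations; returning best iterate")
  }
  tau <- estimate_tau(e, scores, p = data$rank)
  structure(
    list(beta = stats::setNames(beta, data$colnames),
         fitted = y - e, residuals = e,
         dispersion_value = D, tau_hat = tau,
         converged = converged, iterations = it,
         scores = scores$name),
    class = "rank_fit"
  )
}

#' @export
print.rank_fit <- function(x, ...) {
  cat(sprintf(
    "<rank_fit> %s scores, dispersion = %.6g, tau_hat = %.4f, %s (%d it.)\n",
    x$scores, x$dispersion_value, x$tau_hat,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Estimate the rank scale parameter tau
#'
#' Consistent estimation of \eqn{\tau_\psi}, the scale functional linking
#' rank-based and least-squares asymptotics,
#' \eqn{\tau_\psi^{-1} = \int \psi(u)\,\psi_f(u)\,du} with
#' \eqn{\psi_f(u) = -f'(F^{-1}(u))/f(F^{-1}(u))}.
#'
#' For Wilcoxon scores \eqn{\tau_\psi = (\sqrt{12}\int f^2)^{-1}} and the
#' density functional \eqn{\int f^2} is estimated by the Koul-Sievers-McKean
#' window estimator: the proportion of absolute pairwise residual differences
#' below a bandwidth \eqn{t_\delta} (the \eqn{\delta}-quantile of the sorted
#' differences divided by \eqn{\sqrt{n}}, \eqn{\delta = 0.8}, or 0.95 when
#' \eqn{n/p \le 5}) divided by \eqn{2 t_\delta}; the smallest `p` differences
#' are discarded and the estimate carries the degrees-of-freedom correction
#' \eqn{\sqrt{n/(n-p-1)}}.  For sign scores
#' \eqn{\tau_S = (2 f(\theta))^{-1}} is estimated from the length of the
#' distribution-free order-statistic confidence interval for the median.
#'
#' For Gaussian errors with standard deviation \eqn{\sigma} the Wilcoxon value
#' is \eqn{\tau = \sigma\sqrt{\pi/3} \approx 1.0233\,\sigma}; for Uniform(0,1)
#' errors \eqn{\tau = 1/\sqrt{12}}.
#'
#' @param residuals Numeric vector of at least 5 residuals.
#' @param scores Score system (`wilcoxon` or `sign`); defaults to Wilcoxon.
#' @param p Number of fitted regression parameters, used in the
#'   degrees-of-freedom correction (default 0).
#' @return Positive scalar \eqn{\hat\tau_\psi}.  Scale-equivariant:
#'   `estimate_tau(c * r) == c * estimate_tau(r)` for `c > 0`.
#' @examples
#' set.seed(1)
#' estimate_tau(rnorm(500))      # near sqrt(pi/3) = 1.0233
#' @export
estimate_tau <- function(residuals, scores = NULL, p = 0) {
  residuals <- as.numeric(residuals)
  n <- length(residuals)
  if (n < 5L) stop_input("need at least 5 residuals (got %d)", n)
  if (any(!is.finite(residuals))) stop_input("residuals contain NaN/Inf")
  check_scalar(p, "p", min = 0, integer = TRUE)
  if (p > n - 2L) p <- n - 2L
  if (diff(range(residuals)) <= .Machine$double.eps * max(1, abs(residuals[1]))) {
    stop_numeric("degenerate scale: all residuals are identical")
  }
  scores <- scores %||% make_scores(n)

  if (scores$name == "wilcoxon") {
    ad <- abs(outer(residuals, residuals, "-"))
    ad <- sort(ad[upper.tri(ad)])
    npairs <- length(ad)
    dropped <- min(p, npairs - 1L)
    kept <- ad[(dropped + 1L):npairs]
    delta <- if (p > 0 && n / p <= 5) 0.95 else 0.8
    td <- stats::quantile(kept, delta, names = FALSE) / sqrt(n)
    if (td <= 0) {
      pos <- kept[kept > 0]
      if (!length(pos)) stop_numeric("degenerate scale: tied residuals")
      td <- min(pos)
    }
    cnt <- sum(kept < td) + dropped
    int_f2 <- (cnt / npairs) / (2 * td)
    tau <- 1 / (sqrt(12) * int_f2)
  } else if (scores$name == "sign") {
    z <- stats::qnorm(0.975)
    cc <- max(floor(n / 2 - z * sqrt(n) / 2 - 0.5), 0L)
    e <- sort(residuals)
    len <- e[n - cc] - e[cc + 1L]
    if (len <= 0) stop_numeric("degenerate scale for sign-score tau")
    tau <- sqrt(n) * len / (2 * z)
  } else {
    stop_input("tau estimation is implemented for wilcoxon and sign scores")
  }
  tau * sqrt(n / (n - p - 1))
}
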