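#' Prepare a regression dataset
#'
#' Centres the response and the design columns (eliminating the intercept) and
#' optionally scales each column to unit Euclidean norm so that \eqn{X^\top X}
#' and \eqn{X^\top y} are in correlation form, the convention used by the
#' simulation design and by ridge-type estimators under multicollinearity.
#' The thin singular value decomposition of the prepared design is computed
#' once and stored; all estimators, test statistics and hat-matrix traces are
#' evaluated through it, which keeps the \eqn{p > n} case at
#' \eqn{O(n^2 p)} cost without materializing \eqn{p \times p} matrices.
#'
#' @param X Numeric matrix (n samples by p covariates) or data frame.
#' @param y Numeric response of length n.
#' @param standardize Scale centred columns to unit Euclidean norm?
#'   Default `TRUE`.
#' @return An object of class `rr_data`: the prepared `X` and `y`, the
#'   standardization metadata (`column_centers`, `column_scales`, `y_center`)
#'   for back-transforming coefficients and predictions, the thin SVD
#'   (`u`, `d`, `v`), the eigenvalues `lambda` of \eqn{n^{-1}X^\top X}, and
#'   the numerical `rank`.
#' @examples
#' d <- prepare_data(cbind(x = c(1, 2, 3)), c(4, 5, 6))
#' d$X                     # centred, unit-norm column
#' d$y_center              # 5
#' @export
prepare_data <- function(X, y, standardize = TRUE) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop_input("'X' must be numeric")
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop_input("need at least 2 samples (got %d)", n)
  if (p < 1L) stop_input("'X' must have at least one column")
  y <- as.numeric(y)
  if (length(y) != n) {
    stop_input("'y' must be numeric of length nrow(X) = %d", n)
  }
  if (any(!is.finite(X))) stop_input("'X' contains NaN/Inf entries")
  if (any(!is.finite(y))) stop_input("'y' contains NaN/Inf entries")

  cn <- colnames(X) %||% paste0("x", seq_len(p))
  y_center <- mean(y)
  yc <- y - y_center
  centers <- colMeans(X)
  Xc <- sweep(X, 2L, centers, "-")
  if (standardize) {
    scales <- sqrt(colSums(Xc^2))
    bad <- which(scales <= .Machine$double.eps * n)
    if (length(bad)) {
      stop_input("cannot standardize: column '%s' is constant (zero scale)",
                 cn[bad[1L]])
    }
    Xc <- sweep(Xc, 2L, scales, "/")
  } else {
    scales <- rep(1, p)
  }
  colnames(Xc) <- cn

  sv <- svd(Xc)
  tol <- max(n, p) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r == 0L) stop_numeric("design matrix is zero after centering")
  structure(
    list(
      X = Xc, y = yc, n = n, p = p,
      column_centers = centers, column_scales = scales,
      y_center = y_center, standardized = standardize,
      u = sv$u[, seq_len(r), drop = FALSE],
      d = sv$d[seq_len(r)],
      v = sv$v[, seq_len(r), drop = FALSE],
      lambda = sv$d[seq_len(r)]^2 / n,
      rank = r,
      colnames = cn
    ),
    class = "rr_data"
  )
}

#' @export
print.rr_data <- function(x, ...) {
  cat(sprintf(
    "<rr_data> n = %d, p = %d, rank = %d, %s\n",
    x$n, x$p, x$rank,
    if (x$standardized) "correlation form (centred, unit-norm columns)"
    else "centred"
  ))
  invisible(x)
}

# Apply A_k^{-1} = (n^{-1} X'X + k I_p)^{-1} to a p-vector in the row space
# of X (every internal use applies it to X'v vectors) through the stored SVD.
# The null-space component of such a w is pure rounding noise, and dividing
# it by a tiny k would amplify it, so it is dropped rather than propagated.
ak_solve <- function(data, k, w) {
  lam <- data$lambda
  V <- data$v
  vtw <- crossprod(V, w)
  if (k == 0 && data$rank < data$p) {
    stop_numeric("singular system: k = 0 with rank-deficient design")
  }
  V %*% (vtw / (lam + k))
}
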