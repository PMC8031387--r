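#' Score systems for rank-based estimation
#'
#' Builds the score vector used by all rank-based operations.  A score system
#' is defined by a nondecreasing, non-constant, square-integrable
#' score-generating function \eqn{\psi : (0,1) \to \mathbb{R}}; the scores are
#' its quantile evaluations \eqn{a(i) = \psi(i/(n+1))}, \eqn{i = 1, \dots, n}.
#'
#' Available systems:
#' \describe{
#'   \item{`wilcoxon`}{\eqn{\psi(u) = \sqrt{12}(u - 1/2)} (the default).
#'     Linear scores; the normalization makes
#'     \eqn{\sigma_a^2 = (n-1)^{-1}\sum_j a(j)^2 \to 1}.}
#'   \item{`sign`}{\eqn{\psi(u) = \mathrm{sign}(u - 1/2)} (median scores).}
#'   \item{`normal`}{\eqn{\psi(u) = \Phi^{-1}(u)} (van der Waerden scores).}
#' }
#'
#' All three systems are centred (\eqn{\sum_i a(i) = 0}) and nondecreasing.
#'
#' @param n Sample size (integer, at least 2).
#' @param score_name One of `"wilcoxon"`, `"sign"`, `"normal"`.
#' @return An object of class `score_system` with components `name`, `psi`
#'   (the score-generating function), `n`, `a` (length-`n` score vector) and
#'   `sigma_a_sq` \eqn{= (n-1)^{-1}\sum_j a(j)^2}.
#' @examples
#' sc <- make_scores(5)
#' sc$a
#' sum(sc$a)         # centred
#' @seealso [dispersion()], [fit_rank()]
#' @export
make_scores <- function(n, score_name = "wilcoxon") {
  check_scalar(n, "n", min = 2, integer = TRUE)
  if (!is.character(score_name) || length(score_name) != 1L) {
    stop_input("'score_name' must be a single string")
  }
  psi <- switch(score_name,
    wilcoxon = function(u) sqrt(12) * (u - 0.5),
    sign     = function(u) sign(u - 0.5),
    normal   = stats::qnorm,
    stop_input("unknown score system '%s' (available: wilcoxon, sign, normal)",
               score_name)
  )
  a <- psi(seq_len(n) / (n + 1))
  structure(
    list(name = score_name, psi = psi, n = as.integer(n), a = a,
         sigma_a_sq = sum(a^2) / (n - 1)),
    class = "score_system"
  )
}

#' @export
print.score_system <- function(x, ...) {
  cat(sprintf("<score_system> %s, n = %d, sigma_a^2 = %.6f\n",
              x$name, x$n, x$sigma_a_sq))
  invisible(x)
}

#' Mid-ranks of a numeric vector
#'
#' Ranks with ties resolved by averaging the tied positions (mid-ranks), the
#' convention used throughout the package: for centred scores it preserves
#' \eqn{\sum_i a(R(v_i)) = 0} in the presence of ties.
#'
#' @param v Nonempty numeric vector with finite entries.
#' @return Numeric vector of ranks in `1..length(v)` (non-integer at ties).
#' @examples
#' mid_ranks(c(10, 30, 20))
#' mid_ranks(c(2.1, 3.5, 2.1))
#' @export
mid_ranks <- function(v) {
  if (!is.numeric(v) || length(v) == 0L) {
    stop_input("'v' must be a nonempty numeric vector")
  }
  if (any(!is.finite(v))) stop_input("'v' contains NaN/Inf entries")
  rank(v, ties.method = "average")
}

# Scores evaluated at the mid-ranks of v: psi(R(v_i)/(n+1)).  For linear
# (Wilcoxon) psi this equals the average of the scores at the tied positions.
score_at_ranks <- function(scores, v) {
  scores$psi(mid_ranks(v) / (scores$n + 1))
}

#' Jaeckel rank dispersion (pseudo-norm)
#'
#' The dispersion of a residual vector,
#' \deqn{\|v\|_\psi = \sum_i a(R(v_i))\, v_i,}
#' the convex objective of rank regression.  For centred nondecreasing scores
#' it is a pseudo-norm: nonnegative, scale-equivariant, and invariant to
#' adding a constant to all entries.
#'
#' @param v Numeric vector of length `scores$n`.
#' @param scores A [make_scores()] score system matching `length(v)`.
#' @return Nonnegative scalar.
#' @examples
#' sc <- make_scores(3)
#' dispersion(c(1, 2, 3), sc)   # sqrt(3) for Wilcoxon scores
#' dispersion(c(7, 7, 7), sc)   # 0: constants are annihilated
#' @export
dispersion <- function(v, scores) {
  if (!inherits(scores, "score_system")) {
    stop_input("'scores' must be a score_system (see make_scores())")
  }
  if (length(v) != scores$n) {
    stop_input("length(v) = %d does not match the score system (n = %d)",
               length(v), scores$n)
  }
  if (any(!is.finite(v))) stop_input("'v' contains NaN/Inf entries")
  d <- sum(score_at_ranks(scores, v) * v)
  # clamp float dust: the pseudo-norm is >= 0 for centred nondecreasing scores
  if (d < 0 && d > -1e-10 * (1 + max(abs(v)))) d <- 0
  d
}
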