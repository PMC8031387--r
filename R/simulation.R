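# Monte-Carlo framework: collinear designs, sparse/non-sparse coefficient
# regimes, mixed Gaussian-AR / non-central chi-squared contaminated errors,
# and the experiment driver producing size/power and efficiency summaries.

#' Generate a multicollinear design in correlation form
#'
#' Columns are built as
#' \deqn{x_{ij} = (1 - \gamma^2)^{1/2} z_{ij} + \gamma z_{ip},}
#' with \eqn{z_{ij}} iid standard normal, so that the population correlation
#' between any two of the first \eqn{p - 1} columns is \eqn{\gamma^2}; the
#' rule is applied at \eqn{j = p} as well, making the last column
#' \eqn{((1-\gamma^2)^{1/2} + \gamma) z_{ip}} and hence more strongly
#' correlated with the others (a documented quirk of this construction).
#' Columns are then centred and scaled to unit Euclidean norm
#' ("correlation form").
#'
#' @param n,p Dimensions (both at least 2).
#' @param gamma Collinearity parameter in `[0, 1)`.
#' @param seed Optional RNG seed (deterministic output for a given seed).
#' @return n x p standardized matrix.
#' @export
gen_design <- function(n, p, gamma = 0.2, seed = NULL) {
  check_scalar(n, "n", min = 2, integer = TRUE)
  check_scalar(p, "p", min = 2, integer = TRUE)
  check_scalar(gamma, "gamma")
  if (gamma < 0 || gamma >= 1) stop_input("gamma must be in [0, 1)")
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p)
    X <- sqrt(1 - gamma^2) * Z + gamma * matrix(Z[, p], n, p)
    X <- sweep(X, 2L, colMeans(X), "-")
    X <- sweep(X, 2L, sqrt(colSums(X^2)), "/")
    colnames(X) <- paste0("x", seq_len(p))
    X
  })
}

#' Generate a sparse or non-sparse coefficient vector
#'
#' The first \eqn{\lceil 0.1 p \rceil} (sparse) or \eqn{\lceil 0.2 p \rceil}
#' (non-sparse) entries are iid standard normal, the remainder exactly zero.
#'
#' @param p Dimension.
#' @param sparsity `"sparse"` (10 percent nonzero) or `"nonsparse"` (20 percent).
#' @param seed Optional RNG seed.
#' @return Length-p numeric vector.
#' @export
gen_beta <- function(p, sparsity = c("sparse", "nonsparse"), seed = NULL) {
  check_scalar(p, "p", min = 1, integer = TRUE)
  sparsity <- match.arg(sparsity)
  m <- ceiling(switch(sparsity, sparse = 0.1, nonsparse = 0.2) * p)
  with_seed(seed, {
    beta <- numeric(p)
    beta[seq_len(m)] <- stats::rnorm(m)
    beta
  })
}

#' Generate contaminated regression errors
#'
#' The error vector stacks two blocks.  The first
#' \eqn{h = \mathrm{round}(n (1 - CS/100))} entries are multivariate normal
#' \eqn{N_h(0, \sigma^2 V)} with the rapidly-decaying autoregressive kernel
#' \eqn{v_{ij} = \exp(-9|i - j|)} (\eqn{\sigma^2 = 0.44} by default); the
#' remaining \eqn{n - h} entries are iid non-central chi-squared
#' \eqn{\chi^2_1(8)} -- mean \eqn{1 + 8 = 9}, NOT centred: the one-sided
#' contamination is deliberate, pulling non-robust fits toward the outliers.
#'
#' The normal block uses the symmetric eigenvalue square root of V for
#' \eqn{h \le 600}; above that the exact AR(1) recursion for this kernel
#' (autocorrelation \eqn{e^{-9}}) is used, which is distributionally
#' identical and O(n).
#'
#' @param n Sample size.
#' @param cs_percent Contamination share CS in `[0, 100]`
#'   (\eqn{CS = 100 (n - h)/n}).
#' @param sigma_sq Gaussian block variance (default 0.44).
#' @param seed Optional RNG seed.
#' @return Length-n error vector (first h entries Gaussian, rest outliers).
#' @export
gen_errors <- function(n, cs_percent = 0, sigma_sq = 0.44, seed = NULL) {
  check_scalar(n, "n", min = 1, integer = TRUE)
  check_scalar(cs_percent, "cs_percent", min = 0, max = 100)
  check_scalar(sigma_sq, "sigma_sq", min = 0)
  h <- as.integer(round(n * (1 - cs_percent / 100)))
  with_seed(seed, {
    e1 <- if (h > 0) {
      if (h <= 600L) {
        idx <- seq_len(h)
        V <- exp(-9 * abs(outer(idx, idx, "-")))
        eg <- eigen(V, symmetric = TRUE)
        if (any(eg$values < -1e-8)) {
          stop_numeric("error covariance V is not positive semi-definite")
        }
        S <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
        sqrt(sigma_sq) * drop(S %*% stats::rnorm(h))
      } else {
        rho <- exp(-9)
        z <- stats::rnorm(h)
        e <- numeric(h)
        e[1] <- z[1]
        for (i in 2:h) e[i] <- rho * e[i - 1] + sqrt(1 - rho^2) * z[i]
        sqrt(sigma_sq) * e
      }
    } else {
      numeric(0)
    }
    e2 <- if (n - h > 0) stats::rchisq(n - h, df = 1, ncp = 8) else numeric(0)
    c(e1, e2)
  })
}

#' Simulation configuration
#'
#' Bundles the Monte-Carlo study conditions: dimensions, collinearity,
#' sparsity regime, contamination share, error variance, replicate count and
#' master seed.  `h = round(n (1 - CS/100))` is recorded along with the
#' realized contamination share.
#'
#' @param n,p Dimensions.
#' @param gamma Collinearity parameter in `[0, 1)`; default 0.2.
#' @param sparsity `"sparse"` or `"nonsparse"`.
#' @param cs_percent Contamination share CS (default 0).
#' @param sigma_sq Gaussian error variance (default 0.44).
#' @param M Number of replicates (default 1000).
#' @param seed Master RNG seed (default 1).
#' @param under_null Force beta = 0 (size studies)? Default `FALSE`.
#' @param redraw_beta Redraw beta in every replicate (default `TRUE`) or fix
#'   one draw across replicates.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n, p, gamma = 0.2, sparsity = c("sparse", "nonsparse"),
                       cs_percent = 0, sigma_sq = 0.44, M = 1000L, seed = 1L,
                       under_null = FALSE, redraw_beta = TRUE) {
  check_scalar(n, "n", min = 2, integer = TRUE)
  check_scalar(p, "p", min = 2, integer = TRUE)
  check_scalar(gamma, "gamma")
  if (gamma < 0 || gamma >= 1) stop_input("gamma must be in [0, 1)")
  sparsity <- match.arg(sparsity)
  check_scalar(cs_percent, "cs_percent", min = 0, max = 100)
  check_scalar(sigma_sq, "sigma_sq", min = 0)
  check_scalar(M, "M", min = 1, integer = TRUE)
  check_scalar(seed, "seed", min = 0, max = 2147483646, integer = TRUE)
  h <- as.integer(round(n * (1 - cs_percent / 100)))
  structure(
    list(n = as.integer(n), p = as.integer(p), gamma = gamma,
         sparsity = sparsity, cs_percent = cs_percent, h = h,
         cs_actual = 100 * (n - h) / n, sigma_sq = sigma_sq,
         M = as.integer(M), seed = as.integer(seed),
         under_null = isTRUE(under_null), redraw_beta = isTRUE(redraw_beta)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> n = %d, p = %d, gamma = %.2f, %s, CS = %g%% (h = %d), sigma^2 = %g, M = %d, seed = %d%s\n",
    x$n, x$p, x$gamma, x$sparsity, x$cs_percent, x$h, x$sigma_sq, x$M, x$seed,
    if (x$under_null) ", under H0" else ""))
  invisible(x)
}

#' Simulate one dataset from a configuration
#'
#' Composes [gen_design()], [gen_beta()] (or zero coefficients under the
#' null) and [gen_errors()] through `y = X beta + e`.  Independent sub-seeds
#' for the three components are derived from `config$seed`, so changing e.g.
#' the contamination regime does not perturb the design draw.
#'
#' @param config A [sim_config()] object.
#' @param beta Optional coefficient override (used for fixed-beta studies).
#' @return List with the prepared `data` (an `rr_data`; the design is already
#'   in correlation form so no re-standardization is applied), `beta_true`
#'   and the `config`.
#' @export
simulate_dataset <- function(config, beta = NULL) {
  if (!inherits(config, "sim_config")) {
    stop_input("'config' must be a sim_config object")
  }
  ss <- derive_seeds(config$seed, 3L)
  X <- gen_design(config$n, config$p, config$gamma, seed = ss[1])
  beta_true <- if (config$under_null) {
    numeric(config$p)
  } else {
    beta %||% gen_beta(config$p, config$sparsity, seed = ss[2])
  }
  eps <- gen_errors(config$n, config$cs_percent, config$sigma_sq, seed = ss[3])
  y <- drop(X %*% beta_true) + eps
  list(data = prepare_data(X, y, standardize = FALSE),
       beta_true = beta_true, config = config)
}

#' Run the Monte-Carlo study
#'
#' For each of `config$M` replicates a fresh design, coefficient vector (per
#' the regime; redrawn by default) and contaminated error vector are drawn,
#' each estimator is tuned by GCV on a coarse grid (default 10 x 10, no
#' continuous refinement, for tractability at large M) and fitted, and the
#' RRB test (plus the classical F test when \eqn{p < n - 1}) is carried out
#' at level `alpha`.  Squared estimation errors are accumulated into risks
#' and relative efficiencies against the first method.
#'
#' @param config A [sim_config()] object.
#' @param methods Subset of `c("ridge_ls", "ridge_rank", "sse")`; the first
#'   entry is the efficiency reference.  May be empty (tests only).
#' @param alpha Test level (default 0.05).
#' @param n_k,n_d Per-replicate tuning grid sizes (default 10).
#' @param refine Refine the per-replicate GCV optimum? Default `FALSE`.
#' @param rrb_k Ridge parameter for the RRB test when `"sse"` is not among
#'   `methods`; defaults to half the valid-region maximum.
#' @param calibration Decision rule for the RRB test (see [rrb_test()]).
#' @param keep_replicates Retain per-replicate records? Default `FALSE`.
#' @return Object of class `mc_summary`: per-method `risks` (mean squared
#'   estimation error), `efficiencies` vs the first method, empirical
#'   `reject_rate_rrb` and `reject_rate_f` (NA when the F test is not
#'   applicable), `n_skipped`, the `config`, and optionally `replicates`.
#' @export
run_monte_carlo <- function(config, methods = c("ridge_ls", "ridge_rank", "sse"),
                            alpha = 0.05, n_k = 10L, n_d = 10L, refine = FALSE,
                            rrb_k = NULL,
                            calibration = c("moment", "chisq"),
                            keep_replicates = FALSE) {
  if (!inherits(config, "sim_config")) {
    stop_input("'config' must be a sim_config object")
  }
  calibration <- match.arg(calibration)
  if (length(methods)) {
    bad <- setdiff(methods, c("ridge_ls", "ridge_rank", "sse"))
    if (length(bad)) stop_input("unknown method(s): %s", paste(bad, collapse = ", "))
  }
  M <- config$M
  seeds <- derive_seeds(config$seed, M + 1L)
  beta_fixed <- if (!config$redraw_beta && !config$under_null) {
    gen_beta(config$p, config$sparsity, seed = seeds[M + 1L])
  } else {
    NULL
  }

  est <- lapply(methods, function(m) matrix(NA_real_, M, config$p))
  names(est) <- methods
  sqerr <- matrix(NA_real_, M, length(methods),
                  dimnames = if (length(methods)) list(NULL, methods) else NULL)
  rej_rrb <- rej_f <- rep(NA, M)
  f_applicable <- config$p < config$n - 1L
  skipped <- 0L
  reps <- if (keep_replicates) vector("list", M) else NULL

  for (m in seq_len(M)) {
    cfg_m <- config
    cfg_m$seed <- seeds[m]
    ok <- tryCatch({
      sim <- simulate_dataset(cfg_m, beta = beta_fixed)
      data <- sim$data
      sc <- make_scores(data$n)
      rf <- if (data$rank < data$n - 1L &&
                any(c("ridge_rank", "sse") %in% methods)) {
        fit_rank(data, sc)
      } else {
        NULL
      }
      k_test <- NULL
      for (meth in methods) {
        tn <- optimize_gcv(
          data, sc,
          estimator = switch(meth, ridge_ls = "ridge",
                             ridge_rank = "rank_ridge", sse = "sse"),
          n_k = n_k, n_d = n_d, refine = refine, rank_fit = rf)
        bhat <- switch(meth,
          ridge_ls = ridge_ls(data, tn$k_opt),
          ridge_rank = ridge_rank(data, tn$k_opt, sc, rank_fit = rf)$coef,
          sse = sse(data, tn$k_opt, tn$d_opt, sc, rank_fit = rf,
                    rn = tn$rn_opt)$beta)
        est[[meth]][m, ] <- bhat
        sqerr[m, meth] <- sum((bhat - sim$beta_true)^2)
        if (meth == "sse") k_test <- tn$k_opt
      }
      k_test <- k_test %||% rrb_k %||% (k_valid_max(data) / 2)
      rej_rrb[m] <- rrb_test(data, k_test, sc, alpha,
                             calibration = calibration)$reject
      if (f_applicable && data$rank == data$p) {
        rej_f[m] <- f_test(data, alpha)$reject
      }
      if (keep_replicates) {
        reps[[m]] <- list(seed = seeds[m], k_test = k_test,
                          beta_true = sim$beta_true)
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) skipped <- skipped + 1L
    if (skipped > 0.05 * M) {
      stop_numeric("Monte-Carlo aborted: %d of %d replicates failed", skipped, M)
    }
  }

  risks <- effs <- NULL
  if (length(methods)) {
    risks <- colMeans(sqerr, na.rm = TRUE)
    effs <- risks[[1L]] / risks
  }

  structure(
    list(risks = risks, efficiencies = effs,
         reject_rate_rrb = mean(rej_rrb, na.rm = TRUE),
         reject_rate_f = if (f_applicable) mean(rej_f, na.rm = TRUE) else NA_real_,
         alpha = alpha, methods = methods, n_skipped = skipped,
         config = config, calibration = calibration,
         estimates = if (keep_replicates) est else NULL,
         replicates = reps),
    class = "mc_summary"
  )
}

#' @export
print.mc_summary <- function(x, ...) {
  print(x$config)
  if (!is.null(x$risks)) {
    cat("risks (mean squared estimation error):\n")
    print(round(x$risks, 5))
    cat("efficiencies vs", x$methods[1], ":\n")
    print(round(x$efficiencies, 4))
  }
  cat(sprintf("RRB rejection rate: %.4f (alpha = %g, %s calibration)\n",
              x$reject_rate_rrb, x$alpha, x$calibration))
  if (!is.na(x$reject_rate_f)) {
    cat(sprintf("F   rejection rate: %.4f\n", x$reject_rate_f))
  }
  if (x$n_skipped > 0) cat("skipped replicates:", x$n_skipped, "\n")
  invisible(x)
}
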