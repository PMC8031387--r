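test_that("X(k) matches its closed form under an orthonormal-scaled design", {
  set.seed(21)
  n <- 16; p <- 3
  d <- prepare_data(ortho_design(n, p), rnorm(n), standardize = FALSE)
  for (k in c(0.3, 1, 1.9)) {
    expect_equal(xk_matrix(d, k), (0.5 - 0.25 * k) * diag(p),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(xk_matrix(d, 2), "singular", class = "rr_numeric_error")
  # k -> 0 limit: B^{-1}, positive definite
  X0 <- xk_matrix(d, 0)
  expect_equal(X0, diag(p) / 2, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(attr(X0, "positive_definite"))
  # beyond the singularity the matrix is negative definite, flagged not hidden
  expect_false(attr(xk_matrix(d, 3), "positive_definite"))
})

test_that("R_n(k) matches the orthonormal-design closed form to 1e-10", {
  set.seed(22)
  n <- 24; p <- 5
  X <- ortho_design(n, p)
  d <- prepare_data(X, rnorm(n), standardize = FALSE)
  sc <- make_scores(n)
  a <- sc$psi(rank(d$y) / (n + 1))
  w2 <- sum(crossprod(X, a)^2)
  for (k in c(0.1, 0.468759, 1.2)) {
    closed <- w2 / sc$sigma_a_sq / (1 + k)^2 / (0.5 - 0.25 * k)
    expect_equal(rn_statistic(d, k, sc), closed, tolerance = 1e-10)
  }
})

test_that("R_n(k) equals a brute-force dense-matrix evaluation", {
  set.seed(23)
  for (dims in list(c(15, 4), c(8, 12))) {   # full rank and p > n
    n <- dims[1]; p <- dims[2]
    inst <- rand_instance(n, p, gamma = 0.4)
    d <- inst$data
    sc <- make_scores(n)
    k <- 0.35
    a <- sc$psi(rank(d$y) / (n + 1))
    S <- crossprod(d$X) / n
    B <- S + diag(p)
    Xk <- solve(B) - k * solve(B) %*% solve(B)
    Ak <- S + k * diag(p)
    w <- crossprod(d$X, a)
    brute <- drop(t(w) %*% solve(Ak, solve(Xk, solve(Ak, w)))) / sc$sigma_a_sq
    expect_equal(rn_statistic(d, k, sc), brute, tolerance = 1e-8)
  }
})

test_that("R_n(k) depends on y only through its ranks", {
  set.seed(24)
  inst <- rand_instance(20, 4)
  d1 <- inst$data
  for (f in list(function(y) exp(y), function(y) y^3, function(y) 10 * y - 4)) {
    d2 <- prepare_data(inst$X, f(inst$y), standardize = FALSE)
    expect_equal(rn_statistic(d2, 0.5), rn_statistic(d1, 0.5),
                 tolerance = 1e-10)
  }
})

test_that("R_n(k) vanishes when the score-column products vanish", {
  set.seed(25)
  n <- 12
  y <- rnorm(n)
  a <- make_scores(n)$psi(rank(y) / (n + 1))
  # build two centred columns orthogonal to the realized score vector
  M <- scale(matrix(rnorm(n * 2), n, 2), center = TRUE, scale = FALSE)
  X <- M - a %*% crossprod(a, M) / sum(a^2)
  d <- prepare_data(X, y, standardize = FALSE)
  expect_equal(rn_statistic(d, 0.5), 0, tolerance = 1e-20)
})

test_that("R_n(k) is continuous in k on the valid region and errors outside it", {
  set.seed(26)
  inst <- rand_instance(20, 30, gamma = 0.3)    # rank deficient: valid k < 1
  vals <- vapply(seq(0.05, 0.9, length.out = 40),
                 function(k) rn_statistic(inst$data, k), 0)
  expect_true(all(is.finite(vals)) && all(vals > 0))
  # shrinking increments in k produce proportionally shrinking increments in Rn
  base <- rn_statistic(inst$data, 0.4)
  jumps <- vapply(c(1e-2, 1e-4, 1e-6),
                  function(h) abs(rn_statistic(inst$data, 0.4 + h) - base), 0)
  expect_true(all(diff(jumps) < 0))
  expect_lt(jumps[3], 1e-4 * base)
  expect_error(rn_statistic(inst$data, 1.5), "positive definite",
               class = "rr_numeric_error")
})

test_that("exact permutation moments agree with full enumeration", {
  set.seed(27)
  n <- 6
  X <- scale(matrix(rnorm(n * 2), n, 2), center = TRUE, scale = FALSE)
  d <- prepare_data(X, rnorm(n), standardize = FALSE)
  sc <- make_scores(n)
  core <- rankridge:::rn_core(d, 0.4, sc, "literal", "printed")
  mv <- rankridge:::perm_moments(core$g, d$u, core$a)
  Q <- d$u %*% (core$g * t(d$u))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (q in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], q)
    }
    out
  }
  Tv <- vapply(perms(seq_len(n)),
               function(pp) drop(core$a[pp] %*% Q %*% core$a[pp]), 0)
  expect_equal(unname(mv["mean"]), mean(Tv), tolerance = 1e-12)
  expect_equal(unname(mv["var"]), mean(Tv^2) - mean(Tv)^2, tolerance = 1e-10)
})

test_that("rrb_test rejects exactly when the statistic reaches the critical value", {
  set.seed(28)
  for (i in 1:10) {
    inst <- rand_instance(25, 6)
    for (cal in c("moment", "chisq")) {
      tt <- rrb_test(inst$data, 0.4, alpha = 0.05, calibration = cal)
      expect_identical(tt$reject, tt$statistic >= tt$critical_value)
      expect_equal(tt$df, 6)
      expect_equal(tt$kind, "RRB")
    }
  }
  expect_error(rrb_test(rand_instance(10, 2)$data, 0.4, alpha = 1.2),
               class = "rr_input_error")
  expect_error(rrb_test(rand_instance(10, 2)$data, -0.4),
               class = "rr_input_error")
})

test_that("a statistic exactly at the critical value rejects (inclusive rule)", {
  set.seed(29)
  inst <- rand_instance(15, 3)
  stat <- rn_statistic(inst$data, 0.4)
  # pick alpha so that chi2_p(alpha) == the observed statistic
  alpha_star <- 1 - stats::pchisq(stat, df = 3)
  tt <- rrb_test(inst$data, 0.4, alpha = alpha_star, calibration = "chisq")
  expect_equal(tt$critical_value, stat, tolerance = 1e-10)
  expect_true(tt$reject)
})

test_that("F test is calibrated, detects exact fits, and respects p < n", {
  set.seed(30)
  # null calibration at moderate M
  rej <- replicate(300, {
    X <- gen_design(40, 5, 0.2)
    d <- prepare_data(X, rnorm(40), standardize = FALSE)
    f_test(d)$reject
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  X <- gen_design(20, 3, 0.2, seed = 1)
  y <- drop(X %*% c(1, 2, 3))
  dt <- prepare_data(X, y, standardize = FALSE)
  ft <- f_test(dt)
  expect_true(ft$reject)
  expect_true(is.infinite(ft$statistic))

  dh <- prepare_data(matrix(rnorm(71 * 120), 71, 120), rnorm(71))
  expect_error(f_test(dh), "not applicable", class = "rr_input_error")
})
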