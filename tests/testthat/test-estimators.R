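test_that("prepare_data centres and standardizes to correlation form", {
  d <- prepare_data(cbind(a = c(1, 2, 3)), c(4, 5, 6))
  expect_equal(drop(d$X), c(-1, 0, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(d$y, c(-1, 0, 1))
  expect_equal(d$y_center, 5)

  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)
  ds <- prepare_data(X, rnorm(10))
  expect_equal(diag(crossprod(ds$X)), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colMeans(ds$X), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)

  Xc <- cbind(ok = rnorm(10), flat = rep(2, 10))
  expect_error(prepare_data(Xc, rnorm(10)), "flat",
               class = "rr_input_error")
})

test_that("rank fit recovers a noise-free linear relation exactly", {
  set.seed(2)
  x <- rnorm(10)
  d <- prepare_data(cbind(x = x), 2 * x, standardize = FALSE)
  rf <- fit_rank(d)
  expect_equal(unname(rf$beta), 2, tolerance = 1e-12)
  expect_equal(rf$dispersion_value, 0, tolerance = 1e-10)
  expect_true(rf$converged)
})

test_that("rank fit is invariant to a response shift", {
  set.seed(3)
  inst <- rand_instance(25, 3)
  rf1 <- fit_rank(inst$data)
  rf2 <- fit_rank(prepare_data(inst$X, inst$y + 7, standardize = FALSE))
  expect_equal(rf1$beta, rf2$beta, tolerance = 1e-8)
})

test_that("1-D rank fit matches brute-force grid minimization of the dispersion", {
  set.seed(4)
  sc <- make_scores(10)
  for (i in 1:5) {
    x <- rnorm(10)
    y <- 1.5 * x + rnorm(10)
    d <- prepare_data(cbind(x), y, standardize = FALSE)
    rf <- fit_rank(d, sc)
    disp_at <- function(b) {
      vapply(b, function(bb) dispersion(d$y - bb * drop(d$X), sc), 0)
    }
    coarse <- seq(-10, 10, by = 0.01)
    b0 <- coarse[which.min(disp_at(coarse))]
    fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
    b_star <- fine[which.min(disp_at(fine))]
    expect_lt(abs(unname(rf$beta) - b_star), 1e-3)
  }
})

test_that("rank fit dispersion is no larger than at the least-squares solution", {
  set.seed(5)
  sc <- make_scores(12)
  for (i in 1:50) {
    inst <- rand_instance(12, 2, sd_noise = runif(1, 0.2, 2))
    rf <- fit_rank(inst$data, sc)
    d_ls <- dispersion(inst$data$y - drop(inst$data$X %*% ls_coef(inst$data)), sc)
    expect_lte(rf$dispersion_value, d_ls + 1e-8)
  }
})

test_that("rank fit refuses saturated designs and points at ridge_rank", {
  set.seed(6)
  d <- prepare_data(matrix(rnorm(5 * 9), 5, 9), rnorm(5))
  expect_error(fit_rank(d), "ridge_rank", class = "rr_numeric_error")
})

test_that("tau-hat is scale-equivariant and recovers known functionals", {
  set.seed(7)
  r <- rnorm(300)
  expect_equal(estimate_tau(3 * r), 3 * estimate_tau(r), tolerance = 1e-10)
  # Gaussian: tau = sqrt(pi/3); Uniform: tau = 1/sqrt(12); moderate n here,
  # the tighter n = 2000 recovery check lives in the acceptance suite
  expect_lt(abs(estimate_tau(rnorm(800)) / sqrt(pi / 3) - 1), 0.15)
  expect_lt(abs(estimate_tau(runif(800)) / (1 / sqrt(12)) - 1), 0.15)
  expect_error(estimate_tau(rep(1, 20)), class = "rr_numeric_error")
  expect_error(estimate_tau(rnorm(4)), class = "rr_input_error")
  sc_sign <- make_scores(300, "sign")
  expect_gt(estimate_tau(r, sc_sign), 0)
  expect_error(estimate_tau(r, make_scores(300, "normal")),
               class = "rr_input_error")
})

test_that("ridge least squares obeys its closed form and limits", {
  set.seed(8)
  n <- 20; p <- 4
  X <- ortho_design(n, p)                  # n^{-1} X'X = I
  y <- rnorm(n)
  d <- prepare_data(X, y, standardize = FALSE)
  for (k in c(0.1, 0.7, 1.5)) {
    expect_equal(ridge_ls(d, k), crossprod(X, d$y) / n / (1 + k),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # k -> 0 recovers least squares under the calibrated convention
  expect_equal(unname(ridge_ls(d, 1e-12)), ls_coef(d), tolerance = 1e-6)
  # literal mode is n times the calibrated one
  expect_equal(ridge_ls(d, 0.3, "literal"), n * ridge_ls(d, 0.3),
               tolerance = 1e-10)
  # monotone shrinkage along a log-spaced path
  inst <- rand_instance(25, 6, gamma = 0.8)
  norms <- vapply(exp(seq(log(1e-3), log(50), length.out = 20)),
                  function(k) sqrt(sum(ridge_ls(inst$data, k)^2)), 0)
  expect_true(all(diff(norms) <= 1e-12))
  expect_error(ridge_ls(prepare_data(matrix(rnorm(12), 4, 3), rnorm(4)), -1),
               class = "rr_input_error")
})

test_that("rank ridge tends to the rank fit as k -> 0 and to zero as k grows", {
  set.seed(9)
  inst <- rand_instance(30, 4)
  rf <- fit_rank(inst$data)
  rr <- ridge_rank(inst$data, 1e-12, rank_fit = rf)
  expect_equal(unname(rr$coef), unname(rf$beta), tolerance = 1e-4)
  expect_equal(rr$mode, "rank_fit")
  big <- ridge_rank(inst$data, 1e6, rank_fit = rf)
  expect_lt(sqrt(sum(big$coef^2)), 1e-3)
  norms <- vapply(exp(seq(log(1e-3), log(10), length.out = 15)),
                  function(k) sqrt(sum(ridge_rank(inst$data, k,
                                                  rank_fit = rf)$coef^2)), 0)
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("saturated rank ridge fitted values equal L2(k) y", {
  set.seed(10)
  sim <- simulate_dataset(sim_config(15, 30, gamma = 0.4, M = 1, seed = 10))
  d <- sim$data
  sc <- make_scores(d$n)
  k <- 0.3
  rr <- ridge_rank(d, k, sc)
  expect_equal(rr$mode, "saturated")
  L2 <- hat_matrix(d, k, scores = sc, which = "L2", tau = rr$tau_hat)
  expect_equal(rr$fitted, drop(L2 %*% d$y), tolerance = 1e-10)
})

test_that("SSE limit identities hold exactly", {
  set.seed(11)
  inst <- rand_instance(30, 5)
  rf <- fit_rank(inst$data)
  rr <- ridge_rank(inst$data, 0.4, rank_fit = rf)
  s0 <- sse(inst$data, 0.4, 0, rank_fit = rf)
  expect_identical(unname(s0$beta), unname(rr$coef))
  expect_equal(max(abs(s0$beta - rr$coef)), 0)
  sz <- sse(inst$data, 0.4, s0$rn, rank_fit = rf)
  expect_identical(max(abs(sz$beta)), 0)
  # d in (0, 2 Rn) shrinks the lq norm strictly, any q
  for (dd in s0$rn * c(0.3, 1, 1.7)) {
    sd_ <- sse(inst$data, 0.4, dd, rank_fit = rf)
    for (q in c(1, 2)) {
      expect_lt(sum(abs(sd_$beta)^q), sum(abs(rr$coef)^q))
    }
  }
  # positive part truncates sign flips
  sp <- sse(inst$data, 0.4, 3 * s0$rn, rank_fit = rf, positive_part = TRUE)
  expect_equal(max(abs(sp$beta)), 0)
  expect_error(sse(inst$data, 0.4, -1), class = "rr_input_error")
})

test_that("one corrupted response barely moves the rank fit but drags least squares", {
  set.seed(12)
  ratios <- replicate(100, {
    X <- matrix(rnorm(50 * 3), 50, 3)
    y <- drop(X %*% c(1, -2, 0.5)) + rnorm(50)
    y_bad <- y
    hit <- sample(50, 1)
    y_bad[hit] <- y_bad[hit] + 100
    da <- prepare_data(X, y, standardize = FALSE)
    db <- prepare_data(X, y_bad, standardize = FALSE)
    shift_rank <- sqrt(sum((fit_rank(da)$beta - fit_rank(db)$beta)^2))
    shift_ls <- sqrt(sum((ls_coef(da) - ls_coef(db))^2))
    shift_rank / shift_ls
  })
  expect_lt(median(ratios), 0.1)
})
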