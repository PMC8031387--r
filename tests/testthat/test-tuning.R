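test_that("hat matrices obey their chain of identities", {
  set.seed(31)
  inst <- rand_instance(20, 4)
  d <- inst$data
  sc <- make_scores(d$n)
  rf <- fit_rank(d, sc)
  k <- 0.5
  L1 <- hat_matrix(d, k, scores = sc, which = "L1")
  L2 <- hat_matrix(d, k, scores = sc, which = "L2", rank_fit = rf)
  expect_equal(L2, 2 * rf$tau_hat * L1, tolerance = 1e-12)
  # tau = 0.5 makes L2 collapse onto L1
  expect_equal(hat_matrix(d, k, scores = sc, which = "L2", tau = 0.5), L1,
               tolerance = 1e-12)
  # d = 0: no shrinkage
  L <- hat_matrix(d, k, 0, sc, which = "L", rank_fit = rf)
  expect_equal(L, L2, tolerance = 1e-12)
  # d = Rn: the smoother vanishes
  rn <- rn_statistic(d, k, sc)
  L0 <- hat_matrix(d, k, rn, sc, which = "L", rank_fit = rf)
  expect_equal(max(abs(L0)), 0)
  # L1 is the ridge_ls smoother: fitted values agree
  expect_equal(drop(L1 %*% d$y), drop(d$X %*% ridge_ls(d, k)),
               tolerance = 1e-10)
})

test_that("gcv matches hand evaluations and flags saturation", {
  y <- c(1, 1)
  expect_equal(gcv(matrix(0, 2, 2), y), 1)        # ||y||^2 / n
  expect_equal(gcv(0.5 * diag(2), y), 1)          # 0.25 / 0.25
  expect_true(is.na(gcv(diag(2), y)))             # denominator 0
  expect_error(gcv(matrix(0, 3, 3), y), class = "rr_input_error")
  set.seed(32)
  inst <- rand_instance(15, 3)
  L <- hat_matrix(inst$data, 0.3, scores = make_scores(15), which = "L1")
  num <- sum((inst$data$y - L %*% inst$data$y)^2) / 15
  den <- (1 - sum(diag(L)) / 15)^2
  expect_equal(gcv(L, inst$data$y), num / den, tolerance = 1e-12)
})

test_that("risk components match dense-matrix oracles", {
  set.seed(33)
  inst <- rand_instance(18, 4)
  d <- inst$data
  sc <- make_scores(d$n)
  rf <- fit_rank(d, sc)
  k <- 0.4
  rn <- rn_statistic(d, k, sc)
  dd <- 0.2 * rn
  rc <- risk_components(d, inst$beta, k, dd, sc, rank_fit = rf)
  L <- hat_matrix(d, k, dd, sc, which = "L", rank_fit = rf)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(rc$mu1, sum(diag(L)) / d$n, tolerance = 1e-10)
  expect_equal(rc$mu2, sum(ev^2) / d$n, tolerance = 1e-8)
  xb <- drop(d$X %*% inst$beta)
  expect_equal(rc$b2, sum((xb - L %*% xb)^2) / d$n, tolerance = 1e-10)
  expect_equal(rc$risk_estimate, rc$b2 + rf$tau_hat^2 * rc$mu2,
               tolerance = 1e-12)
})

test_that("GCV surface is invariant to permuting the sample order", {
  set.seed(34)
  inst <- rand_instance(25, 5)
  # tau is fixed so the check isolates the surface computation itself (the
  # pairwise-count tau estimator can flip by one pair under reordering)
  tr1 <- optimize_gcv(inst$data, estimator = "sse", n_k = 8, n_d = 8,
                      refine = FALSE, tau = 0.7)
  perm <- sample(25)
  d2 <- prepare_data(inst$X[perm, ], inst$y[perm], standardize = FALSE)
  tr2 <- optimize_gcv(d2, estimator = "sse", n_k = 8, n_d = 8, refine = FALSE,
                      tau = 0.7)
  expect_equal(tr2$gcv_surface, tr1$gcv_surface, tolerance = 1e-8)
  expect_equal(tr2$k_opt, tr1$k_opt, tolerance = 1e-10)
})

test_that("full shrinkage (d = Rn) reproduces the zero-smoother GCV baseline", {
  set.seed(35)
  inst <- rand_instance(20, 4)
  tr <- optimize_gcv(inst$data, estimator = "sse",
                     k_grid = 0.5, d_grid = c(0.01, 1), refine = FALSE)
  baseline <- sum(inst$data$y^2) / 20
  expect_equal(tr$gcv_surface[1, "1"], baseline, tolerance = 1e-10)
})

test_that("degenerate single-cell grids return that cell unrefined", {
  set.seed(36)
  inst <- rand_instance(20, 4)
  tr <- optimize_gcv(inst$data, estimator = "sse",
                     k_grid = 0.3, d_grid = 0.05)
  expect_false(tr$refined)
  expect_equal(tr$k_opt, 0.3)
  expect_equal(tr$d_frac_opt, 0.05)
  # 1-D tuning for the plain ridge estimator ignores d
  tr1 <- optimize_gcv(inst$data, estimator = "ridge", n_k = 10)
  expect_equal(tr1$d_opt, 0)
  expect_true(all(dim(tr1$gcv_surface) == c(10, 1)))
})

test_that("mean GCV tracks mean risk with a nearly constant tau^2 offset", {
  # plug-in check of the risk identity E(GCV) ~ E(risk) + tau^2 over a grid:
  # the offset should be about tau^2 and nearly constant across (k, d) cells
  set.seed(37)
  n <- 80; p <- 8; M <- 100
  beta <- gen_beta(p, "sparse", seed = 99) * 2
  ks <- exp(seq(log(0.005), log(0.5), length.out = 5))
  fs <- exp(seq(log(1e-4), log(0.3), length.out = 5))
  gsum <- rsum <- matrix(0, 5, 5)
  taus <- numeric(M)
  for (m in 1:M) {
    X <- gen_design(n, p, 0.2, seed = 3000 + m)
    e <- gen_errors(n, 0, 0.44, seed = 4000 + m)
    d <- prepare_data(X, drop(X %*% beta) + e, standardize = FALSE)
    rf <- fit_rank(d)
    taus[m] <- rf$tau_hat
    uy <- drop(crossprod(d$u, d$y))
    uxb <- d$d * drop(crossprod(d$v, beta))
    for (i in 1:5) {
      cl_base <- 2 * rf$tau_hat * d$lambda / (d$lambda + ks[i])
      for (j in 1:5) {
        cl <- (1 - fs[j]) * cl_base
        den <- 1 - sum(cl) / n
        gsum[i, j] <- gsum[i, j] +
          (sum(d$y^2) - 2 * sum(cl * uy^2) + sum(cl^2 * uy^2)) / n / den^2
        rsum[i, j] <- rsum[i, j] + sum((uxb - cl * uy)^2) / n
      }
    }
  }
  offset <- (gsum - rsum) / M
  expect_lt(stats::sd(offset) / mean(offset), 0.25)
  expect_lt(abs(mean(offset) / mean(taus)^2 - 1), 0.5)
})
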