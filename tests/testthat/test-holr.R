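test_that("marginal loglik matches the dense-grid marginalization oracle", {
  d <- sim_holr_data(10, 6, zeta = c(-0.5, 0.8), beta = 0.7, sigma = 0.8,
                     seed = 61)
  fit <- fit_holr(d$y, d$X, d$cluster, nodes = 15)
  expect_true(fit$converged)
  K <- fit$n_levels
  oracle <- oracle_marginal_loglik(d$y, d$X[, 1], d$cluster,
                                   zeta = fit$coefficients[seq_len(K - 1)],
                                   beta = fit$coefficients[K],
                                   sigma = sqrt(fit$sigma_u2))
  expect_lt(abs(fit$loglik - oracle), 1e-4)
})

test_that("sigma fixed at zero reproduces the single-level fit", {
  d <- sim_holr_data(12, 8, zeta = c(-1, 0, 1), beta = -0.4, sigma = 0.5,
                     seed = 62)
  h0 <- fit_holr(d$y, d$X, d$cluster, sigma_fixed = 0)
  po <- fit_proportional_odds(d$y, d$X)
  expect_lt(max(abs(h0$coefficients - po$coefficients)), 1e-5)
  expect_lt(abs(h0$loglik - po$loglik), 1e-5)
})

test_that("no cluster structure drives the variance to the boundary", {
  d <- sim_holr_data(40, 25, zeta = c(-0.8, 0.6), beta = 0.5, sigma = 0.9,
                     seed = 63)
  set.seed(64)
  perm <- sample(d$cluster)        # break the clustering
  fit <- fit_holr(d$y, d$X, perm, se = FALSE)
  expect_lt(fit$sigma_u2, 0.05)
})

test_that("doubling quadrature nodes leaves the loglik stable", {
  d <- sim_holr_data(15, 10, zeta = c(-0.5, 0.5), beta = 0.6, sigma = 0.7,
                     seed = 65)
  f15 <- fit_holr(d$y, d$X, d$cluster, nodes = 15, se = FALSE)
  f31 <- fit_holr(d$y, d$X, d$cluster, nodes = 31, se = FALSE,
                  start = list(zeta = f15$coefficients[1:2],
                               beta = f15$coefficients[3],
                               sigma = sqrt(f15$sigma_u2)))
  expect_lt(abs(f31$loglik - f15$loglik), 1e-4)
})

test_that("known parameters are recovered on one large dataset", {
  d <- sim_holr_data(120, 20, zeta = c(-1, 0.2, 1.3), beta = 0.8,
                     sigma = sqrt(0.5), seed = 66)
  fit <- fit_holr(d$y, d$X, d$cluster)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients["x"] - 0.8), 3 * fit$se["x"])
  expect_lt(abs(fit$sigma_u2 - 0.5), 3 * fit$sigma_u2_se)
})

test_that("mixed LR test counts fixed-effect df and enforces structure", {
  d <- sim_holr_data(15, 8, zeta = c(-0.5, 0.7), beta = 0.5, sigma = 0.6,
                     seed = 67)
  set.seed(68); g <- rbinom(120, 1, 0.5)
  f0 <- fit_holr(d$y, d$X, d$cluster, se = FALSE)
  f1 <- fit_holr(d$y, cbind(d$X, g = g), d$cluster, se = FALSE)
  lr <- lr_statistic_mixed(f1, f0)
  expect_equal(lr$df, 1L)
  expect_gte(lr$chi_square, 0)

  lr0 <- lr_statistic_mixed(f0, f0)
  expect_equal(c(lr0$chi_square, lr0$df, lr0$p_value), c(0, 0, 1))

  po <- fit_proportional_odds(d$y, d$X)
  expect_error(lr_statistic_mixed(f1, po), "holr_fit")
  expect_error(lr_statistic(po, f0), "mixed")

  f7 <- fit_holr(d$y, d$X, d$cluster, nodes = 7, se = FALSE)
  expect_error(lr_statistic_mixed(f1, f7), "quadrature")
})

test_that("input contracts are enforced", {
  d <- sim_holr_data(10, 5, zeta = c(-0.5, 0.5), beta = 0.3, sigma = 0.4,
                     seed = 69)
  expect_error(fit_holr(rep(2L, 50), d$X, d$cluster), "fewer than 2")
  expect_error(fit_holr(d$y, d$X, rep(1L, 50)), "2 clusters")
  expect_error(fit_holr(d$y[-1], d$X, d$cluster), "sizes differ")
})
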