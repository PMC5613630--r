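make_po_fixture <- function(n, K, beta, seed) {
  set.seed(seed)
  x <- rnorm(n)
  zeta <- seq(-1, 1, length.out = K - 1)
  cum <- plogis(outer(-x * beta, zeta, "+"))
  y <- as.integer(rowSums(runif(n) > cum))
  list(y = y, x = x)
}

test_that("intercept-only fit has the closed-form cutpoints", {
  y <- rep(0:3, c(10, 20, 25, 5))
  fit <- fit_proportional_odds(y)
  cp <- cumsum(c(10, 20, 25, 5)) / 60
  expect_equal(unname(fit$coefficients), qlogis(cp[1:3]), tolerance = 1e-10)
  expect_equal(fit$loglik,
               sum(c(10, 20, 25, 5) * log(c(10, 20, 25, 5) / 60)),
               tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("maximized loglik matches the grid-search oracle", {
  for (s in c(101, 202, 303)) {
    fx <- make_po_fixture(60, 3, beta = 0.8, seed = s)
    fit <- fit_proportional_odds(fx$y, cbind(x = fx$x))
    oracle <- oracle_grid_search(fx$y, fx$x)
    expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
    expect_gte(fit$loglik, oracle$loglik - 1e-6)  # ML at least as good
  }
})

test_that("likelihood is homogeneous under row duplication", {
  fx <- make_po_fixture(80, 4, beta = -0.5, seed = 21)
  f1 <- fit_proportional_odds(fx$y, cbind(x = fx$x))
  f2 <- fit_proportional_odds(rep(fx$y, 2), cbind(x = rep(fx$x, 2)))
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-4)
})

test_that("adding a predictor never decreases the loglik", {
  for (s in 31:35) {
    fx <- make_po_fixture(120, 5, beta = 0.4, seed = s)
    set.seed(s + 1000)
    z <- rnorm(120)
    f0 <- fit_proportional_odds(fx$y, cbind(x = fx$x))
    f1 <- fit_proportional_odds(fx$y, cbind(x = fx$x, z = z))
    expect_gte(f1$loglik, f0$loglik - 1e-8)
  }
})

test_that("estimates are invariant to predictor recentering", {
  fx <- make_po_fixture(100, 4, beta = 0.6, seed = 41)
  f1 <- fit_proportional_odds(fx$y, cbind(x = fx$x))
  f2 <- fit_proportional_odds(fx$y, cbind(x = fx$x + 5))
  b <- f1$coefficients["x"]
  expect_equal(f2$coefficients["x"], b, tolerance = 1e-5)
  expect_equal(unname(f2$coefficients[1:3]),
               unname(f1$coefficients[1:3] + 5 * b), tolerance = 1e-4)
})

test_that("unobserved categories are collapsed consistently", {
  y <- c(0L, 0L, 2L, 2L, 4L, 4L, 2L, 0L, 4L, 2L)  # categories 1, 3 absent
  fit <- fit_proportional_odds(y)
  expect_true(fit$collapsed)
  expect_equal(fit$n_levels, 3L)
  expect_error(fit_proportional_odds(rep(1L, 10)), "fewer than 2")
})

test_that("the LR statistic has the stated closed form and contracts", {
  fx <- make_po_fixture(150, 3, beta = 1, seed = 51)
  f1 <- fit_proportional_odds(fx$y, cbind(x = fx$x))
  f0 <- fit_proportional_odds(fx$y)
  lr <- lr_statistic(f1, f0)
  expect_equal(lr$chi_square, 2 * (f1$loglik - f0$loglik), tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value, pchisq(lr$chi_square, 1, lower.tail = FALSE))

  # chi-square(2) survival is exp(-x/2): df-2 comparison
  set.seed(52); z <- rnorm(150)
  f2 <- fit_proportional_odds(fx$y, cbind(x = fx$x, z = z,
                                          xz = fx$x * z))
  lr2 <- lr_statistic(f2, f1)
  expect_equal(lr2$df, 2L)
  expect_equal(lr2$p_value, exp(-lr2$chi_square / 2), tolerance = 1e-12)

  # identity comparison: df 0, p reported as 1
  lr0 <- lr_statistic(f1, f1)
  expect_equal(c(lr0$chi_square, lr0$df, lr0$p_value), c(0, 0, 1))

  # mismatched data refused
  fy <- make_po_fixture(150, 3, beta = 1, seed = 53)
  g1 <- fit_proportional_odds(fy$y, cbind(x = fy$x))
  expect_error(lr_statistic(f1, g1), "same data")

  # non-converged fits flagged, never a silent p-value
  bad <- f1; bad$converged <- FALSE
  lrb <- lr_statistic(f1, bad)
  expect_false(lrb$valid)
  expect_true(is.na(lrb$p_value))
})
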