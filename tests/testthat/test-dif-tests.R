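test_that("OLR DIF tests have the stated df and match a direct LR oracle", {
  d <- simulate_dif_data(10, 4, icc = 0.05, dif = 0, level = "within",
                         disc = "low", n_items = 6, seed = 71)
  u <- olr_dif_test(d, "item_6", test = "uniform")
  o <- olr_dif_test(d, "item_6", test = "omnibus")
  expect_equal(u$df, 1L)
  expect_equal(o$df, 2L)

  # chi-square equals twice the loglik gap of independently refitted models
  th <- rowSums(d[dif_items(d)])
  f1 <- fit_proportional_odds(d$item_6, cbind(theta = th))
  f2 <- fit_proportional_odds(d$item_6, cbind(theta = th, group = d$group))
  expect_equal(u$chi_square, 2 * (f2$loglik - f1$loglik), tolerance = 1e-8)

  # and the R1/R2 logliks agree with the grid-search oracle (3 categories)
  set.seed(72)
  y3 <- pmin(d$item_6[1:40], 2L)
  if (length(unique(y3)) == 3L) {
    fit <- fit_proportional_odds(y3, cbind(x = th[1:40]))
    oracle <- oracle_grid_search(y3, th[1:40])
    expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
  }
})

test_that("swapping focal and reference labels flips the coefficient only", {
  d <- simulate_dif_data(20, 10, icc = 0.05, dif = 0.8, level = "within",
                         disc = "high", seed = 73)
  r1 <- olr_dif_test(d, "item_16")
  d2 <- d; d2$group <- 1L - d2$group
  r2 <- olr_dif_test(d2, "item_16")
  expect_equal(r1$chi_square, r2$chi_square, tolerance = 1e-6)
  expect_equal(r1$beta_group, -r2$beta_group, tolerance = 1e-4)

  h1 <- holr_dif_test(d, "item_16", level = "within")
  h2 <- holr_dif_test(d2, "item_16", level = "within")
  expect_equal(h1$chi_square, h2$chi_square, tolerance = 1e-4)
  expect_equal(h1$beta_group, -h2$beta_group, tolerance = 1e-3)
})

test_that("a within-varying group analyzed as between is refused", {
  d <- simulate_dif_data(10, 4, icc = 0.05, dif = 0, level = "within",
                         disc = "low", n_items = 4, seed = 74)
  expect_error(holr_dif_test(d, "item_4", level = "between"),
               "varies within")
  db <- simulate_dif_data(10, 4, icc = 0.05, dif = 0, level = "between",
                          disc = "low", n_items = 4, seed = 75)
  expect_s3_class(holr_dif_test(db, "item_4", level = "between"),
                  "dif_result")
  expect_error(holr_dif_test(db, "item_4", level = "between",
                             test = "omnibus"), "within-cluster")
})

test_that("HOLR reduces to OLR when the variance sits at the boundary", {
  # icc = 0 and few persons per cluster: sigma_u^2 estimates at/near 0
  d <- simulate_dif_data(30, 10, icc = 0, dif = 0.4, level = "within",
                         disc = "low", n_items = 8, seed = 76)
  h <- holr_dif_test(d, "item_8", level = "within")
  o <- olr_dif_test(d, "item_8")
  expect_lt(h$sigma_u2, 0.02)
  expect_lt(abs(h$chi_square - o$chi_square), 0.01)
})

test_that("dif_scan covers every item and supports BH adjustment", {
  d <- simulate_dif_data(16, 36, icc = 0.05, dif = 0, level = "within",
                         disc = "low", n_items = 23, seed = 77)
  sc <- dif_scan(d, method = "OLR")
  expect_equal(nrow(sc), 23L)
  expect_identical(sc$item, paste0("item_", 1:23))
  expect_true(all(sc$df == 1L))
  expect_identical(sc$flagged[sc$valid], (sc$p_value < 0.05)[sc$valid])

  sc_bh <- dif_scan(d, method = "OLR", adjust = "BH")
  expect_lte(sum(sc_bh$flagged), sum(sc$flagged))

  # HOLR scan end-to-end on instrument-shaped data (few items for speed)
  d2 <- simulate_dif_data(16, 12, icc = 0.25, dif = 0, level = "between",
                          disc = "low", n_items = 5, seed = 78)
  sch <- dif_scan(d2, method = "HOLR", level = "between")
  expect_equal(nrow(sch), 5L)
  expect_true(all(sch$valid))
})
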