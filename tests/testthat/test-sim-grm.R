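test_that("item bank draws respect ranges, ordering and determinism", {
  set.seed(1)
  bank <- sample_item_bank(16, c(0.5, 0.99), c(-2.5, 2.5), 5)
  expect_length(bank$discrimination, 16)
  expect_true(all(bank$discrimination >= 0.5 & bank$discrimination <= 0.99))
  expect_true(all(bank$thresholds >= -2.5 & bank$thresholds <= 2.5))
  expect_true(all(apply(bank$thresholds, 1, function(b)
    all(diff(b) > 0))))

  set.seed(7); b1 <- sample_item_bank(8, c(1.5, 2), c(-2.5, 2.5), 5)
  set.seed(7); b2 <- sample_item_bank(8, c(1.5, 2), c(-2.5, 2.5), 5)
  expect_identical(b1, b2)

  set.seed(2)
  two <- sample_item_bank(4, c(0.5, 0.99), c(-2.5, 2.5), n_categories = 2)
  expect_equal(ncol(two$thresholds), 1L)

  expect_error(sample_item_bank(4, c(1, 0.5)), "lo < hi")
  expect_error(sample_item_bank(4, dif_magnitude = -1), ">= 0")
})

test_that("abilities have unit variance and the nominal ICC", {
  set.seed(3)
  ab0 <- sample_abilities(40, 100, icc = 0)
  expect_true(all(ab0$cluster_effect == 0))
  expect_lt(abs(var(ab0$theta) - 1), 3 * sqrt(2 / 4000))

  set.seed(4)
  ab <- sample_abilities(200, 20, icc = 0.45)
  expect_lt(abs(oracle_icc_anova(ab$theta, ab$cluster_id) - 0.45), 0.05)
  expect_lt(abs(var(ab$theta) - 1), 3 * sqrt(2 / 4000))

  set.seed(5)
  ab2 <- sample_abilities(200, 20, icc = 0.05)
  expect_lt(abs(oracle_icc_anova(ab2$theta, ab2$cluster_id) - 0.05), 0.05)

  expect_error(sample_abilities(10, 5, icc = 1), "\\[0, 1\\)")
  expect_error(sample_abilities(10, 5, icc = -0.1), "\\[0, 1\\)")
})

test_that("group assignment is balanced at the declared level", {
  set.seed(6)
  g <- assign_groups(20, 10, "within")
  cl <- rep(1:20, each = 10)
  expect_true(all(tapply(g, cl, sum) == 5))

  # odd cluster size: exact balance overall, near-balance per cluster
  g5 <- assign_groups(50, 5, "within")
  cl5 <- rep(1:50, each = 5)
  expect_equal(sum(g5), 125L)
  expect_true(all(tapply(g5, cl5, sum) %in% c(2L, 3L)))

  gb <- assign_groups(50, 5, "between")
  clb <- rep(1:50, each = 5)
  expect_equal(sum(tapply(gb, clb, max) == 1), 25L)
  expect_true(all(tapply(gb, clb, var) == 0))

  expect_error(assign_groups(25, 4, "between"), "even 'n_clusters'")
  expect_error(assign_groups(25, 5, "within"), "even 'n_clusters'")
})

test_that("category probabilities follow the cumulative-logit GRM", {
  # oracle: direct evaluation of 1/(1 + exp(-a (theta - b)))
  p <- category_probabilities(0, 1, c(-1, 0, 1, 2))
  ge <- 1 / (1 + exp(-(0 - c(-1, 0, 1, 2))))
  expect_equal(unname(ge), c(0.7311, 0.5, 0.2689, 0.1192), tolerance = 1e-4)
  expect_equal(unname(p[1, ]),
               c(1 - ge[1], ge[1] - ge[2], ge[2] - ge[3], ge[3] - ge[4],
                 ge[4]), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # logistic at its location: theta = b_1 + offset gives P(Y >= 1) = 1/2
  p2 <- category_probabilities(-0.6, 2.3, c(-1, 0, 1, 2), dif_offset = 0.4)
  expect_equal(unname(1 - p2[1, 1]), 0.5, tolerance = 1e-12)

  # limits
  expect_gt(category_probabilities(30, 1, c(-1, 0, 1, 2))[1, 5], 0.9999)
  expect_gt(category_probabilities(-30, 1, c(-1, 0, 1, 2))[1, 1], 0.9999)

  thetas <- seq(-3, 3, 0.5)
  pm <- category_probabilities(thetas, 0.8, c(-2, -1, 0.5, 1.7))
  expect_equal(rowSums(pm), rep(1, length(thetas)), tolerance = 1e-12)
  expect_true(all(pm >= 0 & pm <= 1))

  expect_error(category_probabilities(0, 1, c(1, 0)), "increasing")
  expect_error(category_probabilities(0, -1, c(0, 1)), "positive")
})

test_that("generated responses have the right shape and DIF direction", {
  d <- simulate_dif_data(50, 5, icc = 0.05, dif = 0.4, level = "within",
                         disc = "low", seed = 11)
  expect_s3_class(d, "dif_data")
  expect_equal(nrow(d), 250L)
  expect_length(dif_items(d), 16L)
  expect_true(all(as.matrix(d[dif_items(d)]) %in% 0:4))
  expect_true(all(table(d$cluster_id) == 5L))

  # matched theta: focal scores strictly lower under positive DIF
  set.seed(12)
  ab <- list(theta = rep(0, 4000), cluster_id = rep(1:200, each = 20))
  bank <- sample_item_bank(4, c(0.5, 0.99), c(-2.5, 2.5), 5,
                           studied_item = 4, dif_magnitude = 0.8)
  g <- assign_groups(200, 20, "within")
  r <- generate_responses(ab, bank, g, "within")
  foc <- mean(r$item_4[r$group == 1]); ref <- mean(r$item_4[r$group == 0])
  expect_lt(foc, ref)
  # and the gap matches the ICF oracle at theta = 0
  icf_gap <- sum(plogis(bank$discrimination[4] * (0 - bank$thresholds[4, ]))) -
    sum(plogis(bank$discrimination[4] * (0 - bank$thresholds[4, ] - 0.8)))
  expect_lt(abs((ref - foc) - icf_gap), 0.15)
  # core items unaffected in expectation
  expect_lt(abs(mean(r$item_1[r$group == 1]) - mean(r$item_1[r$group == 0])),
            0.15)
})

test_that("between-level DIF applies through the cluster label", {
  d <- simulate_dif_data(50, 10, icc = 0.25, dif = 0.8, level = "between",
                         disc = "high", seed = 13)
  expect_true(all(tapply(d$group, d$cluster_id, var) == 0))
  expect_equal(sum(tapply(d$group, d$cluster_id, max) == 1), 25L)
})

test_that("marginal category frequencies match quadrature probabilities", {
  set.seed(14)
  bank <- sample_item_bank(2, c(0.5, 0.99), c(-2.5, 2.5), 5,
                           studied_item = 2, dif_magnitude = 0)
  ab <- sample_abilities(500, 100, icc = 0)     # 50,000 iid N(0,1) abilities
  g <- assign_groups(500, 100, "within")
  r <- generate_responses(ab, bank, g, "within")
  pq <- oracle_marginal_cat_probs(bank$discrimination[1], bank$thresholds[1, ])
  freq <- as.numeric(table(factor(r$item_1, levels = 0:4))) / 50000
  se <- sqrt(pq * (1 - pq) / 50000)
  expect_true(all(abs(freq - pq) <= 3 * se + 1e-12))
})
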