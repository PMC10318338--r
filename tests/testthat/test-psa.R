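crit <- medopt_criteria()
fit <- mcda(medopt_matrix(), crit, medopt_values())

test_that("Dirichlet weight draws live on the simplex with the right mean", {
  set.seed(1)
  w <- sample_weights(medopt_values(), crit, kappa = 100, n = 10000)
  expect_true(all(abs(rowSums(w) - 1) < 1e-12))
  W <- criterion_weights(medopt_values(), crit)
  expect_true(all(abs(colMeans(w) - W / 100) < 0.005))

  # concentration limit: draws collapse onto the mean weights
  set.seed(2)
  wbig <- sample_weights(medopt_values(), crit, kappa = 1e9, n = 100)
  expect_lt(max(abs(sweep(wbig, 2, W / 100))), 1e-3)
  expect_error(sample_weights(medopt_values(), crit, kappa = 0, n = 1),
               "positive")
})

test_that("gamma score draws preserve means, zeros and the small-cv limit", {
  set.seed(3)
  d <- sample_scores(c(17.6, 0, 4.3), cv = 0.1, n = 10000)
  expect_equal(mean(d[, 1]), 17.6, tolerance = 0.05)
  expect_true(all(d[, 2] == 0))
  set.seed(4)
  tiny <- sample_scores(c(10, 5), cv = 0.001, n = 1000)
  expect_gt(mean(abs(tiny[, 1] - 10) / 10 < 0.01), 0.99)
  expect_error(sample_scores(c(-1, 2), cv = 0.1, n = 1), "non-negative")
  expect_error(sample_scores(c(1, 2), cv = 0, n = 1), "positive")
})

test_that("PSA results are reproducible bit-for-bit given a seed", {
  p1 <- run_psa(fit, scenario = "both", iterations = 200, seed = 11)
  p2 <- run_psa(fit, scenario = "both", iterations = 200, seed = 11)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$result, p2$result)
})

test_that("PSA result structure is internally coherent", {
  p <- run_psa(fit, scenario = "both", iterations = 500, seed = 12)
  r <- p$result
  expect_equal(sum(r$first_rank), 500)
  expect_true(all(r$lo <= r$mean & r$mean <= r$hi))
  acc <- acceptability(p)
  expect_equal(sum(acc$first_rank_prob), 1)
  expect_true(all(acc$first_rank_prob >= 0 & acc$first_rank_prob <= 1))
})

test_that("weights-only expectation matches the deterministic total", {
  p <- run_psa(fit, scenario = "weights", iterations = 10000, kappa = 100,
               seed = 13)
  i <- which(p$result$alternative == "Computerised Interface")
  se <- stats::sd(p$draws[, i]) / sqrt(p$iterations)
  expect_lt(abs(p$result$mean[i] - 83.8), 3 * se)
})

test_that("percentile intervals widen as the Dirichlet concentration drops", {
  widths <- vapply(c(1000, 100, 10), function(k) {
    p <- run_psa(fit, scenario = "weights", iterations = 1000, kappa = k,
                 seed = 14)
    with(p$result[1, ], hi - lo)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("the degenerate configuration reproduces the base model exactly", {
  p <- run_psa(fit, scenario = "both", iterations = 100, kappa = 1e12,
               cv = 1e-6, seed = 15)
  expect_equal(unname(p$result$mean), c(83.8, 79.6, 71.6, 67.8),
               tolerance = 1e-3)
  expect_equal(p$result$first_rank_prob, c(1, 0, 0, 0))
})

test_that("symmetric alternatives split first-rank acceptability evenly", {
  df <- data.frame(criterion_id = rep(c("c1", "c2"), each = 3),
                   name = rep(c("C1", "C2"), each = 3), domain_tag = "t",
                   level_rank = rep(0:2, 2),
                   level_label = rep(c("lo", "mid", "hi"), 2))
  crit2 <- mcda_criteria(df)
  vals2 <- value_system(data.frame(criterion_id = rep(c("c1", "c2"), each = 3),
                                   level_label = rep(c("lo", "mid", "hi"), 2),
                                   value_percent = rep(c(0, 25, 50), 2)))
  m2 <- performance_matrix(data.frame(
    alternative = rep(c("a", "b"), each = 2),
    criterion_id = rep(c("c1", "c2"), 2),
    level_label = c("hi", "lo", "lo", "hi")))
  p <- run_psa(mcda(m2, crit2, vals2), scenario = "both", iterations = 4000,
               seed = 16)
  expect_equal(p$result$first_rank_prob, c(0.5, 0.5), tolerance = 0.05)
})

test_that("simulate() returns the raw draw matrix", {
  s <- simulate(fit, nsim = 50, seed = 17, scenario = "weights")
  expect_s3_class(s, "data.frame")
  expect_equal(dim(s), c(50, 4))
  expect_equal(names(s), attr(medopt_matrix(), "alternatives"))
})
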