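test_that("normalisation forces {0, 100} for a single two-level criterion", {
  crit <- mcda_criteria(data.frame(criterion_id = "only", name = "Only",
                                   domain_tag = "t", level_rank = 0:1,
                                   level_label = c("lo", "hi")))
  empty <- judgement_set(data.frame(respondent_id = character(0),
                                    crit_a = character(0), a_lo = integer(0),
                                    a_hi = integer(0), crit_b = character(0),
                                    b_lo = integer(0), b_hi = integer(0),
                                    choice = character(0)))
  for (meth in c("center", "maxmin")) {
    fit <- fit_paprika(empty, crit, method = meth)
    expect_equal(fit$values$value_percent, c(0, 100), tolerance = 1e-6)
  }
})

test_that("an exact indifference on the swap pair yields equal 50/50 weights", {
  crit <- random_instance(1, 2, 2, seed = 1)$criteria
  js <- judgement_set(data.frame(
    respondent_id = "r", crit_a = "crit01", a_lo = 0, a_hi = 1,
    crit_b = "crit02", b_lo = 0, b_hi = 1, choice = "indifferent"))
  for (meth in c("center", "maxmin")) {
    fit <- fit_paprika(js, crit, method = meth)
    w <- criterion_weights(fit$values, crit)
    expect_equal(unname(w), c(50, 50), tolerance = 0.05)
  }
})

test_that("fits reproduce every explicit judgement with the required margin", {
  for (seed in c(3, 14)) {
    inst <- random_instance(1, 3, 3, seed = seed)
    resp <- synthetic_respondent(inst$values, beta = Inf)
    js <- simulate_session(resp, inst$criteria)
    for (meth in c("center", "maxmin")) {
      fit <- fit_paprika(js, inst$criteria, method = meth)
      expect_true(fit$feasible)
      expect_gte(fit$margin, fit$epsilon)
      expect_true(all(check_fit(fit)$reproduced))
    }
  }
})

test_that("a noiseless respondent's fitted values rank the whole question universe like the truth", {
  inst <- random_instance(1, 3, 3, seed = 21)
  resp <- synthetic_respondent(inst$values, beta = Inf)
  js <- simulate_session(resp, inst$criteria)
  fit <- fit_paprika(js, inst$criteria)
  expect_identical(oracle_value_status(fit$values, inst$criteria, tol = 1e-6),
                   oracle_value_status(inst$values, inst$criteria))
})

test_that("fitted values agree with every relation the closure resolves", {
  # brute-force ranking under the fitted values vs the symbolic closure
  set.seed(7)
  for (seed in c(31, 32)) {
    inst <- random_instance(1, 3, 3, seed = seed)
    n_pairs <- nrow(trade_off_pairs(inst$criteria))
    js <- random_truthful_judgements(inst$criteria, inst$values,
                                     sample(seq_len(n_pairs), 1))
    cl_status <- closure_relation(transitive_closure(js, inst$criteria))$status
    fit <- fit_paprika(js, inst$criteria)
    fit_status <- oracle_value_status(fit$values, inst$criteria, tol = 1e-6)
    resolved <- cl_status != "?"
    expect_identical(fit_status[resolved], cl_status[resolved])
  }
})

test_that("fitted orderings are invariant to the epsilon scale", {
  inst <- random_instance(1, 3, 3, seed = 41)
  resp <- synthetic_respondent(inst$values, beta = Inf)
  js <- simulate_session(resp, inst$criteria)
  f1 <- fit_paprika(js, inst$criteria, method = "maxmin", epsilon = 1e-3)
  f2 <- fit_paprika(js, inst$criteria, method = "maxmin", epsilon = 1e-1)
  expect_identical(oracle_value_status(f1$values, inst$criteria, tol = 1e-6),
                   oracle_value_status(f2$values, inst$criteria, tol = 1e-6))
})

test_that("additively inconsistent judgements are caught or soft-fitted", {
  crit <- random_instance(1, 2, 3, seed = 51)$criteria
  # a1 > b1, a2 > b2, yet B(0->2) > A(0->2): transitively acyclic but
  # infeasible for any additive value system
  js <- judgement_set(data.frame(
    respondent_id = "r",
    crit_a = c("crit01", "crit01", "crit02"),
    a_lo = c(0, 1, 0), a_hi = c(1, 2, 2),
    crit_b = c("crit02", "crit02", "crit01"),
    b_lo = c(0, 1, 0), b_hi = c(1, 2, 2),
    choice = "left"))
  expect_s3_class(transitive_closure(js, crit), "paprika_closure")
  expect_error(fit_paprika(js, crit, on_infeasible = "error"),
               "inconsisten")
  soft <- fit_paprika(js, crit)
  expect_false(soft$feasible)
  expect_lte(soft$margin, 0)
})

test_that("group aggregation is idempotent, symmetric and mismatch-safe", {
  inst <- random_instance(1, 2, 2, seed = 61)
  v1 <- value_system(data.frame(criterion_id = c("crit01", "crit01", "crit02", "crit02"),
                                level_label = rep(c("level_0", "level_1"), 2),
                                value_percent = c(0, 60, 0, 40)))
  v2 <- value_system(data.frame(criterion_id = c("crit01", "crit01", "crit02", "crit02"),
                                level_label = rep(c("level_0", "level_1"), 2),
                                value_percent = c(0, 40, 0, 60)))
  expect_equal(as.data.frame(aggregate_respondents(list(v1, v1))),
               as.data.frame(v1))
  agg <- aggregate_respondents(list(v1, v2))
  expect_equal(criterion_weights(agg, inst$criteria),
               c(crit01 = 50, crit02 = 50))
  v3 <- value_system(data.frame(criterion_id = "other",
                                level_label = c("level_0", "level_1"),
                                value_percent = c(0, 100)))
  expect_error(aggregate_respondents(list(v1, v3)), "mismatched")
  expect_error(aggregate_respondents(list()), "at least one")
})
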