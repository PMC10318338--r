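crit <- medopt_criteria()
pm <- medopt_matrix()
vals <- medopt_values()

test_that("unweighted and weighted totals reproduce the case-study tables exactly", {
  un <- unweighted_total(pm, crit)
  expect_identical(unname(un), c(25L, 24L, 22L, 22L))
  expect_identical(unweighted_total(pm, crit, "Computerised Interface"), 25L)
  expect_identical(unweighted_total(pm, crit, "Written Communication"), 22L)

  wt <- weighted_value(vals, pm, crit)
  expect_identical(unname(wt), c(83.8, 79.6, 71.6, 67.8))
  expect_identical(weighted_value(vals, pm, crit, "Face-to-Face"), 67.8)
  expect_error(unweighted_total(pm, crit, "Nonexistent"), "unknown alternative")
})

test_that("degenerate scoring limits hold", {
  worst <- expand.grid(alternative = c("a", "b"), criterion_id = names(crit),
                       stringsAsFactors = FALSE)
  worst$level_label <- vapply(worst$criterion_id,
                              function(id) crit[[id]]$levels$label[1], "")
  worst <- performance_matrix(worst)
  expect_identical(unname(unweighted_total(worst, crit)), c(10L, 10L))
  # all-worst levels carry zero part-worths
  expect_identical(unname(weighted_value(vals, worst, crit)), c(0, 0))
})

test_that("ranking is dense with Joint labels for ties", {
  r1 <- rank_alternatives(c(a = 25, b = 24, c = 22, d = 22))
  expect_equal(r1$rank, c(1L, 2L, 3L, 3L))
  expect_equal(r1$rank_label, c("First", "Second", "Joint third", "Joint third"))

  r2 <- rank_alternatives(c(a = 83.8, b = 79.6, c = 71.6, d = 67.8))
  expect_equal(r2$rank_label, c("First", "Second", "Third", "Fourth"))

  r3 <- rank_alternatives(c(a = 5, b = 5, c = 5))
  expect_equal(r3$rank_label, rep("Joint first", 3))

  r4 <- rank_alternatives(c(a = 10, b = 9.9, c = 5), tolerance = 0.2)
  expect_equal(r4$rank, c(1L, 1L, 2L))
  expect_error(rank_alternatives(numeric(0)), "at least one")
  expect_error(rank_alternatives(c(a = 1), tolerance = -1), "non-negative")
})

test_that("weight summary sorts by weight with id tie-break", {
  w <- weight_summary(vals, crit)
  expect_equal(w$criterion_id[1], "patient_needs")
  expect_equal(w$weight[1], 17.6)
  expect_equal(w$criterion_id[nrow(w)], "planning")
  expect_equal(w$weight[nrow(w)], 7.8)

  # uniform weights fall back to criterion id order
  uni <- as.data.frame(vals)
  uni$value_percent[uni$value_percent > 0] <- 5
  uni$value_percent[match(paste(names(crit), vapply(crit, function(cr)
    cr$levels$label[3], "")), paste(uni$criterion_id, uni$level_label))] <- 10
  wu <- weight_summary(value_system(uni), crit)
  expect_equal(wu$criterion_id, sort(names(crit)))

  # permutation invariance against a direct sort oracle
  inst <- random_instance(2, 3, 3, seed = 5)
  ws <- weight_summary(inst$values, inst$criteria)
  truth <- criterion_weights(inst$values, inst$criteria)
  expect_equal(ws$weight, unname(sort(truth, decreasing = TRUE)))
})

test_that("totals and ranks are invariant to criterion order", {
  fit <- mcda(pm, crit, vals)
  for (seed in 1:3) {
    set.seed(seed)
    perm <- sample(length(crit))
    crit_p <- structure(unclass(crit)[perm], class = "mcda_criteria")
    fit_p <- mcda(pm, crit_p, vals)
    expect_equal(fit_p$weighted$table, fit$weighted$table)
    expect_equal(fit_p$unweighted$table, fit$unweighted$table)
  }
})

test_that("a null criterion leaves weighted ranks unchanged", {
  crit_df <- as.data.frame(crit)
  extra <- data.frame(criterion_id = "null_crit", name = "Null",
                      domain_tag = "none", level_rank = 0:2,
                      level_label = c("n0", "n1", "n2"))
  crit2 <- mcda_criteria(rbind(crit_df, extra))
  pm2 <- performance_matrix(rbind(as.data.frame(pm),
                                  data.frame(alternative = attr(pm, "alternatives"),
                                             criterion_id = "null_crit",
                                             level_label = "n1")),
                            alternatives = attr(pm, "alternatives"))
  vals2 <- value_system(rbind(as.data.frame(vals),
                              data.frame(criterion_id = "null_crit",
                                         level_label = c("n0", "n1", "n2"),
                                         value_percent = 0)))
  wt2 <- weighted_value(vals2, pm2, crit2)
  r2 <- rank_alternatives(wt2)
  expect_equal(r2$alternative, mcda(pm, crit, vals)$weighted$table$alternative)
  expect_equal(r2$score, mcda(pm, crit, vals)$weighted$table$score)
})

test_that("upgrading a level never decreases the weighted total", {
  for (seed in 1:3) {
    inst <- random_instance(3, 4, 3, seed = seed + 20)
    m <- as.data.frame(inst$matrix)
    base_tot <- weighted_value(inst$values, inst$matrix, inst$criteria)
    i <- which(m$alternative == "alt1")[1]
    cr <- inst$criteria[[m$criterion_id[i]]]
    r <- cr$levels$rank[match(m$level_label[i], cr$levels$label)]
    if (r < 2) {
      m$level_label[i] <- cr$levels$label[cr$levels$rank == r + 1]
      up_tot <- weighted_value(inst$values, performance_matrix(m), inst$criteria)
      expect_gte(up_tot[["alt1"]], base_tot[["alt1"]])
    }
  }
})

test_that("the mcda object carries coherent methods", {
  fit <- mcda(pm, crit, vals)
  expect_s3_class(fit, "mcda")
  expect_equal(unname(coef(fit)[1]), 17.6)
  expect_output(print(fit), "Joint third")
  expect_output(print(summary(fit)), "Criterion weights")
  rep <- score_report(pm, crit, vals)
  expect_equal(rep$weighted$score, c(83.8, 79.6, 71.6, 67.8))
  f <- tempfile(fileext = ".csv")
  write_polar_data(fit, f)
  expect_equal(utils::read.csv(f)$weight, fit$weights$weight)
})
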