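test_that("undominated pair enumeration matches brute force", {
  c23 <- random_instance(1, 2, 3, seed = 1)$criteria
  c22 <- random_instance(1, 2, 2, seed = 1)$criteria
  c10 <- medopt_criteria()
  expect_equal(nrow(trade_off_pairs(c23)), 9)
  expect_equal(nrow(trade_off_pairs(c22)), 1)
  expect_equal(nrow(trade_off_pairs(c10)), 405)
  expect_equal(nrow(trade_off_pairs(c23)), oracle_pair_count(c23))
  expect_equal(nrow(trade_off_pairs(c22)), oracle_pair_count(c22))
  expect_equal(nrow(trade_off_pairs(c10)), oracle_pair_count(c10))
  # mixed level counts
  cmix <- random_instance(1, 3, 4, seed = 3)$criteria
  expect_equal(nrow(trade_off_pairs(cmix)), oracle_pair_count(cmix))
  expect_error(trade_off_pairs(structure(unclass(c23)[1],
                                         class = "mcda_criteria")),
               "at least 2")
})

test_that("transitive closure chains strict preferences", {
  crit <- random_instance(1, 3, 2, seed = 4)$criteria
  ids <- names(crit)
  js <- judgement_set(data.frame(
    respondent_id = "r", crit_a = ids[1:2], a_lo = 0, a_hi = 1,
    crit_b = ids[2:3], b_lo = 0, b_hi = 1, choice = "left"))
  cl <- transitive_closure(js, crit)
  rel <- closure_relation(cl)
  pairs <- trade_off_pairs(crit)
  k <- which(pairs$crit_a == ids[1] & pairs$crit_b == ids[3])
  expect_equal(rel$status[k], ">")
})

test_that("empty judgement sets resolve nothing across criteria", {
  crit <- random_instance(1, 3, 3, seed = 4)$criteria
  empty <- judgement_set(data.frame(respondent_id = character(0),
                                    crit_a = character(0), a_lo = integer(0),
                                    a_hi = integer(0), crit_b = character(0),
                                    b_lo = integer(0), b_hi = integer(0),
                                    choice = character(0)))
  rel <- closure_relation(transitive_closure(empty, crit))
  expect_true(all(rel$status == "?"))
})

test_that("closure equals the brute-force oracle on random consistent sets", {
  set.seed(42)
  for (n_crit in 2:3) {
    for (n_lev in 2:3) {
      for (rep in 1:4) {
        inst <- random_instance(1, n_crit, n_lev,
                                seed = 1000 * n_crit + 100 * n_lev + rep)
        n_pairs <- nrow(trade_off_pairs(inst$criteria))
        js <- random_truthful_judgements(inst$criteria, inst$values,
                                         sample(n_pairs, 1))
        got <- closure_relation(transitive_closure(js, inst$criteria))$status
        want <- oracle_closure_status(js, inst$criteria)
        expect_identical(got, want)
      }
    }
  }
})

test_that("strict-preference cycles are rejected with a witness", {
  crit <- random_instance(1, 3, 2, seed = 4)$criteria
  ids <- names(crit)
  cyc <- judgement_set(data.frame(
    respondent_id = "r", crit_a = ids, a_lo = 0, a_hi = 1,
    crit_b = ids[c(2, 3, 1)], b_lo = 0, b_hi = 1, choice = "left"))
  expect_error(transitive_closure(cyc, crit), "cycle")
})

test_that("the adaptive question chooser maximises expected eliminations", {
  # Exhaustive oracle: for every unresolved pair, add each strict answer,
  # recompute the closure from scratch, and count newly resolved pairs.
  crit <- random_instance(1, 2, 3, seed = 8)$criteria
  session <- new_session(crit)
  pairs <- trade_off_pairs(crit)
  empty <- judgement_set(data.frame(respondent_id = character(0),
                                    crit_a = character(0), a_lo = integer(0),
                                    a_hi = integer(0), crit_b = character(0),
                                    b_lo = integer(0), b_hi = integer(0),
                                    choice = character(0)))
  base_status <- oracle_closure_status(empty, crit)
  expected <- vapply(seq_len(nrow(pairs)), function(k) {
    if (base_status[k] != "?") return(-Inf)
    counts <- vapply(c("left", "right"), function(ch) {
      js <- judgement_set(data.frame(respondent_id = "o",
                                     crit_a = pairs$crit_a[k], a_lo = pairs$a_lo[k],
                                     a_hi = pairs$a_hi[k], crit_b = pairs$crit_b[k],
                                     b_lo = pairs$b_lo[k], b_hi = pairs$b_hi[k],
                                     choice = ch))
      sum(oracle_closure_status(js, crit) != "?") - sum(base_status != "?")
    }, numeric(1))
    mean(counts)
  }, numeric(1))
  q <- next_question(session)
  expect_equal(q$expected_eliminations, max(expected))
  expect_equal(q$pair, which.max(expected))  # enumeration-order tie-break
  # the most informative first question involves a middle level
  involved <- unlist(pairs[q$pair, c("a_lo", "a_hi", "b_lo", "b_hi")])
  expect_true(1 %in% involved)
})

test_that("sessions terminate, resolve everything, and ask fewer questions than pairs", {
  inst <- random_instance(1, 3, 3, seed = 9)
  resp <- synthetic_respondent(inst$values, beta = Inf)
  js <- simulate_session(resp, inst$criteria)
  expect_lt(attr(js, "n_questions"), nrow(trade_off_pairs(inst$criteria)))
  session <- new_session(inst$criteria)
  for (i in seq_len(nrow(js))) {
    q <- next_question(session)
    expect_false(is.null(q))
    session <- record_answer(session, q, js$choice[i])
  }
  expect_true(session_complete(session))
  expect_null(next_question(session))  # exhaustion signal

  # one unresolved pair left: the chooser must return it
  s2 <- new_session(random_instance(1, 2, 2, seed = 2)$criteria)
  q2 <- next_question(s2)
  expect_equal(q2$pair, 1)
})

test_that("judgement sets round-trip through JSON lines", {
  inst <- random_instance(1, 3, 3, seed = 10)
  resp <- synthetic_respondent(inst$values, beta = Inf, respondent_id = "r7")
  js <- simulate_session(resp, inst$criteria)
  f <- tempfile(fileext = ".jsonl")
  write_judgements(js, f, inst$criteria)
  back <- read_judgements(f, inst$criteria)
  expect_equal(as.data.frame(back), as.data.frame(js), ignore_attr = TRUE)
})

test_that("dominated or malformed judgements are rejected", {
  inst <- random_instance(1, 2, 3, seed = 11)
  expect_error(judgement_set(data.frame(
    respondent_id = "r", crit_a = "crit01", a_lo = 1, a_hi = 0,
    crit_b = "crit02", b_lo = 0, b_hi = 1, choice = "left")), "dominance")
  expect_error(judgement_set(data.frame(
    respondent_id = "r", crit_a = "crit01", a_lo = 0, a_hi = 1,
    crit_b = "crit01", b_lo = 0, b_hi = 1, choice = "left")), "distinct")
  f <- tempfile(fileext = ".jsonl")
  writeLines(paste0('{"respondent_id":"r","left":{"crit01":"level_2",',
                    '"crit02":"level_2"},"right":{"crit01":"level_0",',
                    '"crit02":"level_0"},"choice":"left"}'), f)
  expect_error(read_judgements(f, inst$criteria), "dominates")
})
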