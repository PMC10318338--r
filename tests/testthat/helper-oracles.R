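# Independent brute-force oracles used to cross-check the elicitation
# machinery.  These deliberately avoid the package's internal
# representations: they work from the public criteria data frame and the
# public judgement-set columns only.

# All swing quantities (criterion, lo, hi) of a criteria set.
oracle_quantities <- function(criteria) {
  df <- as.data.frame(criteria)
  rows <- list()
  for (id in unique(df$criterion_id)) {
    ranks <- sort(df$level_rank[df$criterion_id == id])
    for (lo in ranks) {
      for (hi in ranks[ranks > lo]) {
        rows[[length(rows) + 1]] <- data.frame(crit = id, lo = lo, hi = hi,
                                               stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Brute-force enumeration of undominated two-criterion profile pairs:
# enumerate every pair of two-criterion profiles on every criterion pair and
# keep those where each profile is strictly better on exactly one criterion.
oracle_pair_count <- function(criteria) {
  df <- as.data.frame(criteria)
  ids <- unique(df$criterion_id)
  count <- 0L
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      ra <- sort(df$level_rank[df$criterion_id == ids[a]])
      rb <- sort(df$level_rank[df$criterion_id == ids[b]])
      profiles <- expand.grid(la = ra, lb = rb)
      n <- nrow(profiles)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          d1 <- profiles$la[i] - profiles$la[j]
          d2 <- profiles$lb[i] - profiles$lb[j]
          if ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) count <- count + 1L
        }
      }
    }
  }
  count
}

# Scalar fixed-point Floyd-Warshall closure over swing quantities with
# explicit strict/weak bookkeeping.  Returns the status (">", "<", "=", "?")
# of every row of trade_off_pairs(criteria), in order.
oracle_closure_status <- function(judgements, criteria) {
  Q <- oracle_quantities(criteria)
  n <- nrow(Q)
  qid <- function(crit, lo, hi) which(Q$crit == crit & Q$lo == lo & Q$hi == hi)
  ge <- diag(TRUE, n)   # weak preference (>=) reachability
  st <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && Q$crit[i] == Q$crit[j] &&
          Q$lo[i] <= Q$lo[j] && Q$hi[j] <= Q$hi[i]) {
        st[i, j] <- TRUE
        ge[i, j] <- TRUE
      }
    }
  }
  for (k in seq_len(nrow(judgements))) {
    r <- judgements[k, ]
    qa <- qid(r$crit_a, r$a_lo, r$a_hi)
    qb <- qid(r$crit_b, r$b_lo, r$b_hi)
    if (r$choice == "left") {
      st[qa, qb] <- TRUE; ge[qa, qb] <- TRUE
    } else if (r$choice == "right") {
      st[qb, qa] <- TRUE; ge[qb, qa] <- TRUE
    } else {
      ge[qa, qb] <- TRUE; ge[qb, qa] <- TRUE
    }
  }
  repeat {
    changed <- FALSE
    for (k in seq_len(n)) {
      for (i in seq_len(n)) {
        if (!ge[i, k]) next
        for (j in seq_len(n)) {
          if (!ge[k, j]) next
          if (!ge[i, j]) { ge[i, j] <- TRUE; changed <- TRUE }
          s <- st[i, k] || st[k, j]
          if (s && !st[i, j]) { st[i, j] <- TRUE; changed <- TRUE }
        }
      }
    }
    if (!changed) break
  }
  pairs <- trade_off_pairs(criteria)
  vapply(seq_len(nrow(pairs)), function(k) {
    i <- qid(pairs$crit_a[k], pairs$a_lo[k], pairs$a_hi[k])
    j <- qid(pairs$crit_b[k], pairs$b_lo[k], pairs$b_hi[k])
    if (st[i, j]) ">"
    else if (st[j, i]) "<"
    else if (ge[i, j] && ge[j, i]) "="
    else "?"
  }, character(1))
}

# Swing of a value system over a level interval of one criterion.
oracle_swing <- function(values, criteria, crit, lo, hi) {
  df <- as.data.frame(criteria)
  lab <- function(r) df$level_label[df$criterion_id == crit & df$level_rank == r]
  v <- function(l) values$value_percent[values$criterion_id == crit &
                                          values$level_label == l]
  v(lab(hi)) - v(lab(lo))
}

# Status of every trade-off pair under a value system (the ranking an
# additive model with those values induces on the question universe).
oracle_value_status <- function(values, criteria, tol = 1e-9) {
  pairs <- trade_off_pairs(criteria)
  vapply(seq_len(nrow(pairs)), function(k) {
    d <- oracle_swing(values, criteria, pairs$crit_a[k],
                      pairs$a_lo[k], pairs$a_hi[k]) -
      oracle_swing(values, criteria, pairs$crit_b[k],
                   pairs$b_lo[k], pairs$b_hi[k])
    if (d > tol) ">" else if (d < -tol) "<" else "="
  }, character(1))
}

# Random consistent judgement subset: answer a random subset of the
# question universe truthfully from a latent value system.
random_truthful_judgements <- function(criteria, values, n_answers,
                                       respondent_id = "oracle") {
  pairs <- trade_off_pairs(criteria)
  status <- oracle_value_status(values, criteria)
  pick <- sample(nrow(pairs), min(n_answers, nrow(pairs)))
  judgement_set(data.frame(
    respondent_id = respondent_id,
    crit_a = pairs$crit_a[pick], a_lo = pairs$a_lo[pick], a_hi = pairs$a_hi[pick],
    crit_b = pairs$crit_b[pick], b_lo = pairs$b_lo[pick], b_hi = pairs$b_hi[pick],
    choice = c(">" = "left", "<" = "right", "=" = "indifferent")[status[pick]],
    stringsAsFactors = FALSE))
}
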