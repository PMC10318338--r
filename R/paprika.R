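# Pairwise trade-off elicitation in the style of the PAPRIKA method.
#
# Internally every two-criterion trade-off question is a comparison of two
# "swing" quantities: the value difference between two levels of one
# criterion versus the value difference between two levels of another.  A
# question profile pair (left better on criterion a, right better on
# criterion b) asks whether the swing on a outweighs the swing on b.  All
# bookkeeping (transitive closure, adaptive question choice, the ordinal
# constraint solve) is done on the swing quantities.

# Table of swing quantities: one row per criterion and level interval
# (lo < hi), in deterministic order (criteria order, then lo, then hi).
quantity_table <- function(criteria) {
  rows <- list()
  for (cr in criteria) {
    L <- nrow(cr$levels)
    for (lo in 0:(L - 2)) {
      for (hi in (lo + 1):(L - 1)) {
        rows[[length(rows) + 1]] <- data.frame(crit = cr$id, lo = lo, hi = hi,
                                               stringsAsFactors = FALSE)
      }
    }
  }
  q <- do.call(rbind, rows)
  q$qid <- seq_len(nrow(q))
  q
}

quantity_id <- function(Q, crit, lo, hi) {
  i <- which(Q$crit == crit & Q$lo == lo & Q$hi == hi)
  if (length(i) != 1) stop_mcda("no swing quantity for ", crit, " [", lo, ",", hi, "]")
  Q$qid[i]
}

# Incidence of quantities on single-step deltas (variables of the solve):
# row q, column (crit, step s) with s in 1..L-1 meaning the step from level
# s-1 to level s.
quantity_incidence <- function(criteria, Q) {
  steps <- do.call(rbind, lapply(criteria, function(cr) {
    data.frame(crit = cr$id, step = seq_len(nrow(cr$levels) - 1),
               stringsAsFactors = FALSE)
  }))
  A <- base::matrix(0, nrow = nrow(Q), ncol = nrow(steps),
                    dimnames = list(NULL, paste(steps$crit, steps$step, sep = ":")))
  for (i in seq_len(nrow(Q))) {
    sel <- steps$crit == Q$crit[i] & steps$step > Q$lo[i] & steps$step <= Q$hi[i]
    A[i, sel] <- 1
  }
  attr(A, "steps") <- steps
  A
}

# Within-criterion containment: a swing strictly contains another (same
# criterion, sub-interval) so it is strictly larger when levels are strictly
# ordered.
containment_edges <- function(Q) {
  n <- nrow(Q)
  S <- base::matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && Q$crit[i] == Q$crit[j] &&
          Q$lo[i] <= Q$lo[j] && Q$hi[j] <= Q$hi[i]) {
        S[i, j] <- TRUE
      }
    }
  }
  S
}

# Transitive closure of the swing relation.  base_strict / base_eq are
# asserted edges; returns GE (weak reachability, reflexive), ST (established
# strict preference), EQ (established equivalence) and a cycle flag.
close_relation <- function(base_strict, base_eq) {
  n <- nrow(base_strict)
  GE <- base_strict | base_eq | t(base_eq) | diag(TRUE, n)
  repeat {
    new <- GE | ((GE %*% GE) > 0)
    if (identical(new, GE)) break
    GE <- new
  }
  ST <- (GE %*% base_strict %*% GE) > 0
  EQ <- GE & t(GE) & !ST
  list(GE = GE, ST = ST, EQ = EQ, cycle = any(diag(ST)))
}

# Shortest asserted-edge cycle through a node flagged inconsistent.
find_cycle <- function(base_strict, base_eq, start) {
  adj <- base_strict | base_eq | t(base_eq)
  n <- nrow(adj)
  prev <- rep(NA_integer_, n)
  frontier <- which(adj[start, ])
  prev[frontier] <- start
  while (length(frontier) > 0) {
    if (start %in% frontier) break
    nxt <- integer(0)
    for (v in frontier) {
      reach <- which(adj[v, ] & (is.na(prev) | seq_len(n) == start))
      reach <- reach[is.na(prev[reach]) | reach == start]
      newly <- reach[is.na(prev[reach])]
      prev[newly] <- v
      if (start %in% reach && is.na(prev[start])) prev[start] <- v
      nxt <- c(nxt, newly)
    }
    if (!is.na(prev[start])) break
    frontier <- unique(nxt)
  }
  path <- start
  v <- prev[start]
  while (!is.na(v) && v != start) {
    path <- c(v, path)
    v <- prev[v]
  }
  c(start, path)
}

describe_quantity <- function(Q, qid, criteria = NULL) {
  i <- match(qid, Q$qid)
  lab <- function(crit, r) {
    if (is.null(criteria)) as.character(r) else level_label_of(criteria, crit, r)
  }
  paste0(Q$crit[i], "[", lab(Q$crit[i], Q$lo[i]), " -> ", lab(Q$crit[i], Q$hi[i]), "]")
}

#' Enumerate undominated two-criterion trade-off pairs
#'
#' All unordered pairs of two-criterion profiles where each profile is
#' strictly better on exactly one of the two criteria, so that a genuine
#' trade-off judgement is required.  These are the candidate questions of a
#' pairwise elicitation survey; the order is deterministic (criterion pair,
#' then level intervals).
#'
#' @param criteria An \code{mcda_criteria} object with at least 2 criteria.
#' @return A data frame with one row per pair: the two criteria, the level
#'   ranks each profile takes on them, and the profile labels.  The left
#'   profile is better on \code{crit_a}; the right profile on \code{crit_b}.
#' @export
#' @examples
#' nrow(trade_off_pairs(medopt_criteria()))  # 45 criterion pairs x 9
trade_off_pairs <- function(criteria) {
  if (length(criteria) < 2) stop_mcda("trade-off questions need at least 2 criteria")
  Q <- quantity_table(criteria)
  ids <- criterion_ids(criteria)
  rows <- list()
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      qa <- Q[Q$crit == ids[a], , drop = FALSE]
      qb <- Q[Q$crit == ids[b], , drop = FALSE]
      for (i in seq_len(nrow(qa))) {
        for (j in seq_len(nrow(qb))) {
          rows[[length(rows) + 1]] <- data.frame(
            crit_a = ids[a], a_lo = qa$lo[i], a_hi = qa$hi[i],
            crit_b = ids[b], b_lo = qb$lo[j], b_hi = qb$hi[j],
            qa = qa$qid[i], qb = qb$qid[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$pair <- seq_len(nrow(out))
  out
}

pair_profiles <- function(criteria, pair_row) {
  left <- c(level_label_of(criteria, pair_row$crit_a, pair_row$a_hi),
            level_label_of(criteria, pair_row$crit_b, pair_row$b_lo))
  right <- c(level_label_of(criteria, pair_row$crit_a, pair_row$a_lo),
             level_label_of(criteria, pair_row$crit_b, pair_row$b_hi))
  names(left) <- names(right) <- c(pair_row$crit_a, pair_row$crit_b)
  list(left = left, right = right)
}

#' Start an adaptive elicitation session
#'
#' Creates the state of a pairwise trade-off survey for one respondent:
#' the full set of undominated questions, and the (initially empty)
#' preference relation over swing quantities.
#'
#' @param criteria An \code{mcda_criteria} object with at least 2 criteria.
#' @return An object of class \code{paprika_session}.  Use
#'   [next_question()] to obtain the most informative open question and
#'   [record_answer()] to fold an answer (and everything it implies by
#'   transitivity) back into the session; [session_complete()] reports
#'   whether all pairs are resolved.
#' @seealso [simulate_session()], [fit_paprika()]
#' @export
new_session <- function(criteria) {
  if (length(criteria) < 2) stop_mcda("elicitation needs at least 2 criteria")
  Q <- quantity_table(criteria)
  n <- nrow(Q)
  base_strict <- containment_edges(Q)
  base_eq <- base::matrix(FALSE, n, n)
  cl <- close_relation(base_strict, base_eq)
  structure(list(criteria = criteria, Q = Q,
                 pairs = trade_off_pairs(criteria),
                 base_strict = base_strict, base_eq = base_eq,
                 GE = cl$GE, ST = cl$ST,
                 judgements = NULL, n_questions = 0L),
            class = "paprika_session")
}

session_resolved <- function(session) {
  qa <- session$pairs$qa
  qb <- session$pairs$qb
  st <- session$ST
  ge <- session$GE
  st[cbind(qa, qb)] | st[cbind(qb, qa)] | (ge[cbind(qa, qb)] & ge[cbind(qb, qa)])
}

#' @rdname new_session
#' @param session A \code{paprika_session}.
#' @export
session_complete <- function(session) all(session_resolved(session))

#' Most informative open question of a session
#'
#' Among unresolved trade-off pairs, returns the one whose possible strict
#' answers would resolve (directly or by transitivity) the largest expected
#' number of currently unresolved pairs, the expectation being the mean of
#' the two strict-answer outcomes.  Ties are broken by enumeration order,
#' so sessions are fully deterministic given the answers.
#'
#' @param session A \code{paprika_session}.
#' @return \code{NULL} when every pair is resolved (the session is
#'   exhausted); otherwise a list with the \code{pair} row index, the
#'   \code{left} and \code{right} profiles (named level-label vectors) and
#'   the expected elimination count.
#' @export
next_question <- function(session) {
  unres <- !session_resolved(session)
  if (!any(unres)) return(NULL)
  p <- session$pairs
  n <- nrow(session$Q)
  U <- base::matrix(FALSE, n, n)
  U[cbind(p$qa[unres], p$qb[unres])] <- TRUE
  U <- U | t(U)
  # C[i, j]: number of unresolved pairs resolved by answering "i beats j".
  C <- t(session$GE) %*% (U * 1) %*% t(session$GE)
  expected <- (C[cbind(p$qa, p$qb)] + C[cbind(p$qb, p$qa)]) / 2
  expected[!unres] <- -Inf
  k <- which.max(expected)  # first maximum = enumeration-order tie-break
  prof <- pair_profiles(session$criteria, p[k, ])
  list(pair = k, left = prof$left, right = prof$right,
       expected_eliminations = expected[k])
}

#' Record the answer to a trade-off question
#'
#' Adds the respondent's choice to the session relation and recomputes its
#' transitive closure, so every comparison the answer implies is marked
#' resolved and never asked.
#'
#' @param session A \code{paprika_session}.
#' @param question A question as returned by [next_question()].
#' @param choice One of \code{"left"}, \code{"right"}, \code{"indifferent"}.
#' @param respondent_id Identifier stored with the judgement.
#' @return The updated session.
#' @export
record_answer <- function(session, question, choice,
                          respondent_id = "anonymous") {
  choice <- match.arg(choice, c("left", "right", "indifferent"))
  row <- session$pairs[question$pair, ]
  if (choice == "left") {
    session$base_strict[row$qa, row$qb] <- TRUE
  } else if (choice == "right") {
    session$base_strict[row$qb, row$qa] <- TRUE
  } else {
    session$base_eq[row$qa, row$qb] <- TRUE
  }
  cl <- close_relation(session$base_strict, session$base_eq)
  if (cl$cycle) {
    stop_mcda("answer creates a preference cycle; session state unchanged")
  }
  session$GE <- cl$GE
  session$ST <- cl$ST
  j <- data.frame(respondent_id = respondent_id,
                  crit_a = row$crit_a, a_lo = row$a_lo, a_hi = row$a_hi,
                  crit_b = row$crit_b, b_lo = row$b_lo, b_hi = row$b_hi,
                  choice = choice, stringsAsFactors = FALSE)
  session$judgements <- rbind(session$judgements, j)
  session$n_questions <- session$n_questions + 1L
  session
}

#' @export
print.paprika_session <- function(x, ...) {
  cat("Elicitation session:", length(x$criteria), "criteria,",
      nrow(x$pairs), "trade-off pairs,",
      sum(session_resolved(x)), "resolved,",
      x$n_questions, "questions asked\n")
  invisible(x)
}

#' Assemble a judgement set
#'
#' A judgement set holds one respondent's answers to two-criterion
#' trade-off questions in the internal long form: each row names the two
#' criteria, the level-rank interval each profile swings over, and the
#' choice.  The left profile is the one better on \code{crit_a}.
#'
#' @param df Data frame with columns \code{respondent_id}, \code{crit_a},
#'   \code{a_lo}, \code{a_hi}, \code{crit_b}, \code{b_lo}, \code{b_hi},
#'   \code{choice}.
#' @return The validated data frame with class \code{judgement_set}.
#' @export
judgement_set <- function(df) {
  required <- c("respondent_id", "crit_a", "a_lo", "a_hi",
                "crit_b", "b_lo", "b_hi", "choice")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_mcda("judgement set is missing column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  if (!all(df$choice %in% c("left", "right", "indifferent"))) {
    stop_mcda("choice must be left, right or indifferent")
  }
  if (any(df$crit_a == df$crit_b)) {
    stop_mcda("a judgement must involve two distinct criteria")
  }
  if (any(df$a_lo >= df$a_hi) || any(df$b_lo >= df$b_hi)) {
    stop_mcda("profiles must differ on both criteria (no dominance)")
  }
  structure(as.data.frame(df), class = c("judgement_set", "data.frame"))
}

#' Read and write judgement sets as JSON lines
#'
#' One JSON object per line: \code{{"respondent_id": ..., "left": {crit:
#' level, ...}, "right": {...}, "choice": ...}}, with left and right defined
#' on the same two criteria and neither profile dominating the other.
#'
#' @param path File path.
#' @param criteria An \code{mcda_criteria} object used to translate level
#'   labels to ranks.
#' @return \code{read_judgements()} returns a \code{judgement_set};
#'   \code{write_judgements()} returns \code{path} invisibly.
#' @export
read_judgements <- function(path, criteria) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    crits <- names(rec$left)
    if (length(crits) != 2 || !setequal(crits, names(rec$right))) {
      stop_mcda("judgement profiles must be defined on the same two criteria")
    }
    r <- vapply(crits, function(cid) {
      c(left = level_rank_of(criteria, cid, rec$left[[cid]]),
        right = level_rank_of(criteria, cid, rec$right[[cid]]))
    }, numeric(2))
    d <- r["left", ] - r["right", ]
    if (!(any(d > 0) && any(d < 0))) {
      stop_mcda("one profile dominates the other; not a trade-off judgement")
    }
    a <- crits[d > 0][1]; b <- crits[d < 0][1]
    data.frame(respondent_id = rec$respondent_id %||% "anonymous",
               crit_a = a, a_lo = r["right", a], a_hi = r["left", a],
               crit_b = b, b_lo = r["left", b], b_hi = r["right", b],
               choice = rec$choice, stringsAsFactors = FALSE)
  })
  judgement_set(do.call(rbind, rows))
}

#' @rdname read_judgements
#' @param judgements A \code{judgement_set}.
#' @export
write_judgements <- function(judgements, path, criteria) {
  stopifnot(inherits(judgements, "judgement_set"))
  lines <- vapply(seq_len(nrow(judgements)), function(i) {
    r <- judgements[i, ]
    left <- stats::setNames(list(level_label_of(criteria, r$crit_a, r$a_hi),
                                 level_label_of(criteria, r$crit_b, r$b_lo)),
                            c(r$crit_a, r$crit_b))
    right <- stats::setNames(list(level_label_of(criteria, r$crit_a, r$a_lo),
                                  level_label_of(criteria, r$crit_b, r$b_hi)),
                             c(r$crit_a, r$crit_b))
    jsonlite::toJSON(list(respondent_id = r$respondent_id, left = left,
                          right = right, choice = r$choice),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Base relation asserted by a judgement set (plus containment).
judgement_relation <- function(judgements, criteria) {
  Q <- quantity_table(criteria)
  n <- nrow(Q)
  base_strict <- containment_edges(Q)
  base_eq <- base::matrix(FALSE, n, n)
  for (i in seq_len(nrow(judgements))) {
    r <- judgements[i, ]
    qa <- quantity_id(Q, r$crit_a, r$a_lo, r$a_hi)
    qb <- quantity_id(Q, r$crit_b, r$b_lo, r$b_hi)
    if (r$choice == "left") base_strict[qa, qb] <- TRUE
    else if (r$choice == "right") base_strict[qb, qa] <- TRUE
    else base_eq[qa, qb] <- TRUE
  }
  list(Q = Q, base_strict = base_strict, base_eq = base_eq)
}

#' Transitive closure of a judgement set
#'
#' Resolves everything a set of pairwise trade-off judgements implies: each
#' judgement compares two swing quantities (a level interval on one
#' criterion against a level interval on another), and strict preference
#' and indifference are closed under transitivity across those quantities,
#' together with the within-criterion dominance relations.  A strict
#' preference cycle is reported as an error with a witness.
#'
#' @param judgements A \code{judgement_set}.
#' @param criteria An \code{mcda_criteria} object.
#' @return An object of class \code{paprika_closure} with the quantity
#'   table \code{Q} and logical matrices \code{GE} (weak preference
#'   reachability), \code{ST} (strict preference) and \code{EQ}
#'   (indifference).
#' @export
transitive_closure <- function(judgements, criteria) {
  judgements <- judgement_set(judgements)
  rel <- judgement_relation(judgements, criteria)
  cl <- close_relation(rel$base_strict, rel$base_eq)
  if (cl$cycle) {
    bad <- which(diag(cl$ST))[1]
    cyc <- find_cycle(rel$base_strict, rel$base_eq, bad)
    stop_mcda("judgements contain a strict-preference cycle: ",
              paste(vapply(cyc, function(q) describe_quantity(rel$Q, q, criteria),
                           character(1)),
                    collapse = " > "))
  }
  structure(list(Q = rel$Q, GE = cl$GE, ST = cl$ST, EQ = cl$EQ,
                 criteria = criteria, judgements = judgements),
            class = "paprika_closure")
}

#' Resolved relation of a closure, in long form
#'
#' @param closure A \code{paprika_closure}.
#' @return Data frame of all cross-criterion swing-quantity pairs with
#'   their status: \code{">"}, \code{"<"}, \code{"="} or \code{"?"}.
#' @export
closure_relation <- function(closure) {
  Q <- closure$Q
  pairs <- trade_off_pairs(closure$criteria)
  status <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$qa[k]; j <- pairs$qb[k]
    status[k] <- if (closure$ST[i, j]) ">"
    else if (closure$ST[j, i]) "<"
    else if (closure$EQ[i, j]) "="
    else "?"
  }
  data.frame(quantity_a = vapply(pairs$qa, describe_quantity, character(1),
                                 Q = Q, criteria = closure$criteria),
             quantity_b = vapply(pairs$qb, describe_quantity, character(1),
                                 Q = Q, criteria = closure$criteria),
             qa = pairs$qa, qb = pairs$qb, status = status,
             stringsAsFactors = FALSE)
}

#' @export
print.paprika_closure <- function(x, ...) {
  rel <- closure_relation(x)
  cat("Preference closure over", nrow(x$Q), "swing quantities;",
      sum(rel$status != "?"), "of", nrow(rel), "trade-off pairs resolved\n")
  invisible(x)
}
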