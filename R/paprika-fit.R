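# Ordinal-constraint solve for respondent part-worths.
#
# A respondent's judgements (after transitive closure) give a partial order
# over swing quantities, each quantity being a non-negative combination of
# single-step level deltas.  Any value vector whose deltas respect that
# order reproduces every elicited judgement.  Two solvers are provided:
#
#   "maxmin":  an LP that maximises the smallest strict-preference margin
#              (subject to the scale constraint that the all-best profile
#              scores 100), then minimises the total part-worth mass as a
#              deterministic tie-break.
#   "center":  the analytic centre of the same constraint polytope (log
#              barrier over all strict margins and step positivity, with
#              indifferences as quadratic penalties), started from the
#              "maxmin" solution.  This is the default: it sits in the
#              middle of the set of value systems consistent with the
#              answers rather than at a face of it, which makes recovered
#              values far less extreme.

# Hasse cover edges of the strict class order (transitive reduction).
strict_covers <- function(ST, EQ) {
  n <- nrow(ST)
  rep_of <- seq_len(n)
  for (i in seq_len(n)) rep_of[i] <- min(which(EQ[i, ] | seq_len(n) == i))
  reps <- sort(unique(rep_of))
  Sc <- ST[reps, reps, drop = FALSE]
  red <- Sc & !((Sc %*% Sc) > 0)
  idx <- which(red, arr.ind = TRUE)
  list(rep_of = rep_of, reps = reps,
       covers = cbind(hi = reps[idx[, 1]], lo = reps[idx[, 2]]))
}

# Equality rows: each quantity minus its class representative.
equality_rows <- function(A, rep_of) {
  members <- which(rep_of != seq_along(rep_of))
  if (length(members) == 0) return(base::matrix(0, 0, ncol(A)))
  A[members, , drop = FALSE] - A[rep_of[members], , drop = FALSE]
}

gap_matrix <- function(A, covers) {
  nx <- ncol(A)
  if (nrow(covers) > 0) {
    A[covers[, "hi"], , drop = FALSE] - A[covers[, "lo"], , drop = FALSE]
  } else {
    base::matrix(0, 0, nx)
  }
}

# Max-min margin solve as a ridge-regularised QP: maximise the smallest
# strict margin m subject to the ordinal constraints and the all-best = 100
# normalisation, then minimise total part-worth mass at that margin
# (deterministic tie-break).  The tiny ridge keeps the QP strictly convex
# without visibly moving the LP optimum.
solve_maxmin <- function(A, covers, Aeq, epsilon, ridge = 1e-6) {
  nx <- ncol(A)
  gap_rows <- gap_matrix(A, covers)
  ineq <- rbind(gap_rows, diag(nx))          # strict gaps and step positivity
  # variables z = (x, m); constraints rows are t(Amat) in solve.QP terms
  Aeq2 <- cbind(rbind(Aeq, rep(1, nx)), 0)
  beq2 <- c(rep(0, nrow(Aeq)), 100)
  Aub <- cbind(ineq, -1)                     # gap - m >= 0
  mfloor <- c(rep(0, nx), 1)                 # m >= epsilon
  Amat <- t(rbind(Aeq2, Aub, mfloor))
  bvec <- c(beq2, rep(0, nrow(Aub)), epsilon)
  Dmat <- diag(ridge, nx + 1)
  dvec <- c(rep(0, nx), 1)                   # maximise m
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = length(beq2)),
    error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  x <- sol$solution[seq_len(nx)]
  m <- sol$solution[nx + 1]
  # L1 tie-break: minimise total part-worth mass at the achieved margin.
  # Part-worth mass of step s in a criterion with L levels is (L - s).
  Amat2 <- t(rbind(rbind(Aeq, rep(1, nx)), ineq))
  bvec2 <- c(rep(0, nrow(Aeq)), 100, rep(m * (1 - 1e-9), nrow(ineq)))
  sol2 <- tryCatch(
    quadprog::solve.QP(diag(ridge, nx), -attr(A, "l1_weights") * ridge^0,
                       Amat2, bvec2, meq = nrow(Aeq) + 1),
    error = function(e) NULL)
  if (!is.null(sol2)) {
    # rescale: solve.QP minimises ridge/2 ||x||^2 + l1'x; with ridge tiny the
    # linear term dominates, but guard against numerical failure
    x2 <- sol2$solution
    if (all(is.finite(x2))) x <- x2
  }
  list(x = pmax(x, 0), margin = m)
}

# Log barrier with linear extension below g0: finite everywhere, so the
# solve is well defined even for additively infeasible judgement sets.
barrier <- function(g, g0) {
  ifelse(g >= g0, log(pmax(g, g0)), log(g0) + (g - g0) / g0)
}

# Analytic centre of the ordinal polytope: maximise the sum of log barriers
# over all strict margins and step positivity, with indifference classes as
# quadratic penalties; the scale constraint sum(x) = 100 is built into a
# softmax parametrisation.
solve_center <- function(A, covers, Aeq, x0, lambda = 1e4, g0 = 0.01) {
  nx <- ncol(A)
  gap_rows <- gap_matrix(A, covers)
  obj <- function(y) {
    y <- y - max(y)
    x <- 100 * exp(y) / sum(exp(y))
    gaps <- if (nrow(gap_rows) > 0) drop(gap_rows %*% x) else numeric(0)
    pen <- if (nrow(Aeq) > 0) sum(drop(Aeq %*% x)^2) else 0
    -(sum(barrier(gaps, g0)) + sum(barrier(x, g0))) + lambda * pen
  }
  y0 <- log(pmax(x0, 1e-6))
  fit <- stats::optim(y0, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  y <- fit$par - max(fit$par)
  100 * exp(y) / sum(exp(y))
}

#' Fit part-worth values to a respondent's judgements
#'
#' Solves for level values that reproduce every elicited judgement: worst
#' level worth 0 on each criterion, strictly increasing level steps, each
#' strict preference holding with a positive margin, indifferences holding
#' with (near) zero margin, and the all-best profile normalised to score
#' 100.  See the package vignette for the two solution rules.
#'
#' @param judgements A \code{judgement_set} (e.g. from [simulate_session()]
#'   or [read_judgements()]).
#' @param criteria An \code{mcda_criteria} object.
#' @param method \code{"center"} (analytic centre of the feasible polytope,
#'   default) or \code{"maxmin"} (maximise the minimum margin, then
#'   minimise total part-worth mass).
#' @param epsilon Minimum strict-preference margin on the 0-100 scale used
#'   as a feasibility floor (default \code{1e-3}); fitted orderings are
#'   invariant to its scale.
#' @param on_infeasible What to do when the judgements are additively
#'   inconsistent (possible under choice noise): \code{"fallback"}
#'   (default) fits the extended-barrier centre anyway and flags the result
#'   with \code{feasible = FALSE}; \code{"error"} raises an inconsistency
#'   error.
#' @return An object of class \code{paprika_fit} with the fitted
#'   \code{values} (a \code{value_system}), the achieved minimum
#'   \code{margin}, the \code{closure} and the judgements.  \code{coef()}
#'   returns the level values; \code{print()} summarises.
#' @export
#' @examples
#' inst <- random_instance(2, 3, 3, seed = 7)
#' resp <- synthetic_respondent(inst$values, beta = Inf)
#' js <- simulate_session(resp, inst$criteria)
#' fit <- fit_paprika(js, inst$criteria)
#' coef(fit)
fit_paprika <- function(judgements, criteria,
                        method = c("center", "maxmin"), epsilon = 1e-3,
                        on_infeasible = c("fallback", "error")) {
  method <- match.arg(method)
  on_infeasible <- match.arg(on_infeasible)
  closure <- transitive_closure(judgements, criteria)
  Q <- closure$Q
  A <- quantity_incidence(criteria, Q)
  steps <- attr(A, "steps")
  Ls <- n_levels(criteria)
  attr(A, "l1_weights") <- Ls[steps$crit] - steps$step

  cov <- strict_covers(closure$ST, closure$EQ)
  Aeq <- equality_rows(A, cov$rep_of)
  sol <- solve_maxmin(A, cov$covers, Aeq, epsilon)
  feasible <- !is.null(sol)
  if (feasible) {
    x <- sol$x
    margin <- sol$margin
  } else {
    # Additively infeasible judgements (possible under choice noise even
    # when transitively consistent): solve with the extended barrier, which
    # is defined everywhere, and report the (negative) worst margin.
    if (on_infeasible == "error") {
      stop_mcda("judgements are additively inconsistent: no value system ",
                "reproduces every strict preference with margin ", epsilon)
    }
    x <- rep(100 / ncol(A), ncol(A))
    method <- "center"
  }
  if (method == "center") {
    x <- solve_center(A, cov$covers, Aeq, pmax(x, 1e-6))
  }
  gaps <- drop(gap_matrix(A, cov$covers) %*% x)
  margin <- min(c(gaps, x))
  names(x) <- colnames(A)

  rows <- list()
  for (cr in criteria) {
    v <- c(0, cumsum(x[steps$crit == cr$id]))
    rows[[cr$id]] <- data.frame(criterion_id = cr$id,
                                level_label = cr$levels$label,
                                value_percent = unname(v),
                                stringsAsFactors = FALSE)
  }
  values <- value_system(do.call(rbind, rows))
  structure(list(values = values, deltas = x, margin = margin,
                 feasible = feasible, method = method, epsilon = epsilon,
                 criteria = criteria, closure = closure,
                 judgements = closure$judgements),
            class = "paprika_fit")
}

#' @export
coef.paprika_fit <- function(object, ...) {
  stats::setNames(object$values$value_percent,
                  paste(object$values$criterion_id, object$values$level_label,
                        sep = ":"))
}

#' @export
print.paprika_fit <- function(x, ...) {
  cat("Part-worth fit (", x$method, ") from ", nrow(x$judgements),
      " judgements; min strict margin ", signif(x$margin, 3), "\n", sep = "")
  w <- criterion_weights(x$values, x$criteria)
  cat("Criterion weights:\n")
  print(round(w, 2))
  invisible(x)
}

# Signed fitted value of a sparse profile (named label vector).
profile_value <- function(values, profile) {
  sum(vapply(names(profile), function(cid) {
    value_of(values, cid, profile[[cid]])
  }, numeric(1)))
}

#' Check that a fit reproduces its judgements
#'
#' @param fit A \code{paprika_fit}.
#' @param tol Tolerance for indifference margins.
#' @return Data frame with one row per judgement and a logical
#'   \code{reproduced} column.
#' @export
check_fit <- function(fit, tol = 0.02) {
  js <- fit$judgements
  ok <- logical(nrow(js))
  margin <- numeric(nrow(js))
  for (i in seq_len(nrow(js))) {
    r <- js[i, ]
    va <- profile_swing(fit$values, fit$criteria, r$crit_a, r$a_lo, r$a_hi)
    vb <- profile_swing(fit$values, fit$criteria, r$crit_b, r$b_lo, r$b_hi)
    d <- va - vb
    margin[i] <- d
    ok[i] <- switch(r$choice,
                    left = d > 0,
                    right = d < 0,
                    indifferent = abs(d) <= tol)
  }
  cbind(js, margin = margin, reproduced = ok)
}

profile_swing <- function(values, criteria, crit, lo, hi) {
  value_of(values, crit, level_label_of(criteria, crit, hi)) -
    value_of(values, crit, level_label_of(criteria, crit, lo))
}

#' Aggregate respondent value systems into a group value system
#'
#' The group part-worth of each level is the arithmetic mean of the
#' respondents' part-worths; the group weight of a criterion is therefore
#' the mean of its best-level values, and group weights still sum to 100.
#'
#' @param models A list of \code{paprika_fit} objects or
#'   \code{value_system}s over identical criteria and levels.
#' @return A \code{value_system}.
#' @export
aggregate_respondents <- function(models) {
  if (length(models) < 1) stop_mcda("need at least one respondent model")
  vs <- lapply(models, function(m) {
    if (inherits(m, "paprika_fit")) m$values
    else if (inherits(m, "value_system")) m
    else stop_mcda("models must be paprika_fit or value_system objects")
  })
  ref <- vs[[1]]
  key <- function(v) paste(v$criterion_id, v$level_label, sep = "\r")
  ref_key <- key(ref)
  acc <- base::matrix(NA_real_, nrow = nrow(ref), ncol = length(vs))
  for (j in seq_along(vs)) {
    idx <- match(ref_key, key(vs[[j]]))
    if (any(is.na(idx)) || nrow(vs[[j]]) != nrow(ref)) {
      stop_mcda("respondent ", j, " has a mismatched criteria/level set")
    }
    acc[, j] <- vs[[j]]$value_percent[idx]
  }
  out <- ref
  out$value_percent <- rowMeans(acc)
  value_system(as.data.frame(out))
}
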