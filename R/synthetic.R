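# Synthetic respondents, cohorts and random problem instances.  These stand
# in for survey data: a respondent is a latent additive value function plus
# a logistic choice rule, and a cohort disperses criterion weights around a
# centre with a Dirichlet distribution.

#' Define a synthetic survey respondent
#'
#' A respondent answers trade-off questions from a latent additive value
#' function with logistic choice noise: given a value difference
#' \eqn{\Delta} between the two profiles, the left profile is chosen with
#' probability \eqn{1 / (1 + e^{-\beta\Delta})}.  \code{beta = Inf} is a
#' deterministic truth-teller (exact ties answered "indifferent").
#'
#' @param values A \code{value_system}: the respondent's true part-worths.
#' @param beta Non-negative inverse temperature of the choice rule;
#'   \code{Inf} for noiseless answers.
#' @param respondent_id Identifier attached to generated judgements.
#' @return An object of class \code{respondent_spec}.
#' @export
synthetic_respondent <- function(values, beta = Inf, respondent_id = "sim") {
  stopifnot(inherits(values, "value_system"))
  if (beta < 0) stop_mcda("beta must be non-negative")
  structure(list(values = values, beta = beta, respondent_id = respondent_id),
            class = "respondent_spec")
}

#' Answer one trade-off question
#'
#' @param respondent A \code{respondent_spec}.
#' @param left,right Sparse profiles: named character vectors mapping
#'   criterion ids to level labels.
#' @return \code{"left"}, \code{"right"} or \code{"indifferent"}.  Uses the
#'   current RNG stream when \code{beta} is finite.
#' @export
answer_question <- function(respondent, left, right) {
  d <- profile_value(respondent$values, left) -
    profile_value(respondent$values, right)
  if (is.infinite(respondent$beta)) {
    if (d > 1e-9) "left" else if (d < -1e-9) "right" else "indifferent"
  } else {
    if (stats::runif(1) < stats::plogis(respondent$beta * d)) "left" else "right"
  }
}

#' Simulate a full adaptive elicitation session
#'
#' Runs the adaptive question loop of [new_session()] against a synthetic
#' respondent until every trade-off pair is resolved.  Because only
#' unresolved pairs are ever asked, the recorded judgement set is always
#' internally consistent, even under choice noise (noise shows up as wrong
#' but coherent answers, exactly as in an adaptive survey).
#'
#' @param respondent A \code{respondent_spec}.
#' @param criteria An \code{mcda_criteria} object.
#' @return A \code{judgement_set} with attribute \code{n_questions}.
#' @export
simulate_session <- function(respondent, criteria) {
  session <- new_session(criteria)
  repeat {
    q <- next_question(session)
    if (is.null(q)) break
    ans <- answer_question(respondent, q$left, q$right)
    session <- record_answer(session, q, ans, respondent$respondent_id)
  }
  js <- judgement_set(session$judgements)
  attr(js, "n_questions") <- session$n_questions
  js
}

#' Generate a synthetic survey cohort
#'
#' Draws \code{n} respondents whose criterion weights are Dirichlet
#' dispersed around a centre value system (within-criterion level profiles
#' are scaled with the drawn weight), then simulates a full adaptive
#' session for each.
#'
#' @param n Number of respondents.
#' @param center A \code{value_system}: the population mean part-worths.
#' @param criteria An \code{mcda_criteria} object.
#' @param kappa_pop Dirichlet concentration of the between-respondent
#'   weight dispersion (larger = more homogeneous; \code{Inf} clones the
#'   centre).
#' @param beta Choice-noise inverse temperature per respondent
#'   (\code{Inf} = noiseless).
#' @param seed Optional integer seed for reproducibility.
#' @return List of \code{judgement_set}s with attribute \code{true_values}
#'   (the respondents' latent value systems).
#' @export
generate_cohort <- function(n, center, criteria, kappa_pop = 200,
                            beta = Inf, seed = NULL) {
  stopifnot(n >= 1)
  if (kappa_pop <= 0) stop_mcda("kappa_pop must be positive")
  if (!is.null(seed)) set.seed(seed)
  W <- criterion_weights(center, criteria)
  truths <- vector("list", n)
  sessions <- vector("list", n)
  for (r in seq_len(n)) {
    w <- if (is.infinite(kappa_pop)) W / 100
    else drop(rdirichlet(1, kappa_pop * W / 100))
    scale <- 100 * w / W
    tv <- as.data.frame(center)
    tv$value_percent <- tv$value_percent * scale[tv$criterion_id]
    truths[[r]] <- value_system(tv)
    resp <- synthetic_respondent(truths[[r]], beta = beta,
                                 respondent_id = sprintf("r%03d", r))
    sessions[[r]] <- simulate_session(resp, criteria)
  }
  attr(sessions, "true_values") <- truths
  sessions
}

#' Generate a random MCDA instance
#'
#' Produces a structurally valid random problem: criteria with generic
#' labels, a complete random performance matrix, and a value system whose
#' weights are drawn from a flat Dirichlet and scaled to sum to exactly 100
#' (one-decimal precision, largest weight absorbing the rounding
#' remainder).
#'
#' @param n_alternatives,n_criteria,n_levels Instance dimensions
#'   (\code{n_criteria >= 2} recommended for elicitation use,
#'   \code{n_levels >= 2}).
#' @param seed Optional integer seed.
#' @return List with \code{criteria}, \code{matrix} and \code{values}.
#' @export
#' @examples
#' inst <- random_instance(4, 10, 3, seed = 1)  # the case-study design
#' validate_matrix(inst$matrix, inst$criteria)$ok
random_instance <- function(n_alternatives, n_criteria, n_levels, seed = NULL) {
  stopifnot(n_alternatives >= 1, n_criteria >= 1, n_levels >= 2)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("crit%02d", seq_len(n_criteria))
  crit_df <- do.call(rbind, lapply(seq_len(n_criteria), function(i) {
    data.frame(criterion_id = ids[i],
               name = paste("Criterion", i),
               domain_tag = "synthetic",
               level_rank = 0:(n_levels - 1),
               level_label = paste0("level_", 0:(n_levels - 1)),
               stringsAsFactors = FALSE)
  }))
  criteria <- mcda_criteria(crit_df)

  w <- drop(rdirichlet(1, rep(1, n_criteria))) * 100
  w10 <- tenths(w)
  w10[which.max(w10)] <- w10[which.max(w10)] + (1000L - sum(w10))
  w <- w10 / 10

  val_df <- do.call(rbind, lapply(seq_len(n_criteria), function(i) {
    mids <- if (n_levels > 2) {
      round(w[i] * sort(stats::runif(n_levels - 2)), 1)
    } else {
      numeric(0)
    }
    data.frame(criterion_id = ids[i],
               level_label = paste0("level_", 0:(n_levels - 1)),
               value_percent = c(0, mids, w[i]),
               stringsAsFactors = FALSE)
  }))
  values <- value_system(val_df)

  alts <- sprintf("alt%d", seq_len(n_alternatives))
  mat_df <- expand.grid(alternative = alts, criterion_id = ids,
                        stringsAsFactors = FALSE)
  mat_df$level_label <- paste0("level_", sample(0:(n_levels - 1),
                                                nrow(mat_df), replace = TRUE))
  list(criteria = criteria,
       matrix = performance_matrix(mat_df, alternatives = alts),
       values = values)
}
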