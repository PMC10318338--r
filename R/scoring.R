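#' Unweighted ordinal totals
#'
#' Sums the 1..L ordinal points of each alternative's assigned levels over
#' all criteria (the "equal weights" model used when no preference data are
#' available).
#'
#' @param matrix A validated \code{performance_matrix}.
#' @param criteria An \code{mcda_criteria} object.
#' @param alternative Optional single alternative name; by default all
#'   alternatives are scored.
#' @return Named integer vector of totals (or a single integer).
#' @export
#' @examples
#' unweighted_total(medopt_matrix(), medopt_criteria())
unweighted_total <- function(matrix, criteria, alternative = NULL) {
  alts <- alternative %||% attr(matrix, "alternatives")
  if (!all(alts %in% attr(matrix, "alternatives"))) {
    stop_mcda("unknown alternative(s): ",
              paste(setdiff(alts, attr(matrix, "alternatives")), collapse = ", "))
  }
  pts <- contribution_table(matrix, criteria, model = "unweighted")
  out <- as.integer(colSums(pts))[match(alts, colnames(pts))]
  names(out) <- alts
  if (!is.null(alternative) && length(alternative) == 1) out[[1]] else out
}

#' Weighted additive totals
#'
#' The additive value model: an alternative's total is the sum over criteria
#' of the part-worth of its assigned level (\eqn{V_j = \sum_i S_{ij} W_i}).
#' Sums are computed in exact one-decimal arithmetic so that published
#' one-decimal tables are reproduced without floating-point drift.
#'
#' @param values A \code{value_system}.
#' @param matrix A validated \code{performance_matrix}.
#' @param criteria An \code{mcda_criteria} object.
#' @param alternative Optional single alternative name.
#' @return Named numeric vector of totals in percent (or a single number).
#' @export
#' @examples
#' weighted_value(medopt_values(), medopt_matrix(), medopt_criteria())
weighted_value <- function(values, matrix, criteria, alternative = NULL) {
  alts <- alternative %||% attr(matrix, "alternatives")
  if (!all(alts %in% attr(matrix, "alternatives"))) {
    stop_mcda("unknown alternative(s): ",
              paste(setdiff(alts, attr(matrix, "alternatives")), collapse = ", "))
  }
  contrib <- contribution_table(matrix, criteria, values = values,
                                model = "weighted")
  out <- apply(contrib, 2, sum_tenths)[match(alts, colnames(contrib))]
  names(out) <- alts
  if (!is.null(alternative) && length(alternative) == 1) out[[1]] else out
}

# Per-criterion x per-alternative contribution table; "unweighted" gives
# ordinal points, "weighted" gives part-worths.
contribution_table <- function(matrix, criteria, values = NULL,
                               model = c("weighted", "unweighted")) {
  model <- match.arg(model)
  alts <- attr(matrix, "alternatives")
  ids <- criterion_ids(criteria)
  out <- base::matrix(NA_real_, nrow = length(ids), ncol = length(alts),
                      dimnames = list(ids, alts))
  for (a in alts) {
    for (id in ids) {
      lab <- pm_level(matrix, a, id)
      out[id, a] <- if (model == "unweighted") {
        level_rank_of(criteria, id, lab) + 1
      } else {
        value_of(values, id, lab)
      }
    }
  }
  out
}

#' Rank alternatives by score with dense, tie-aware ranks
#'
#' Scores are sorted in descending order; alternatives whose scores are
#' equal (within \code{tolerance}) share a rank, rendered "Joint <rank>",
#' and the next distinct score takes the next consecutive (dense) rank.
#'
#' @param scores Named numeric vector of scores.
#' @param tolerance Non-negative score difference treated as a tie
#'   (default 0: exact equality, appropriate for one-decimal fixtures).
#' @return A data frame (\code{score_table}) with columns
#'   \code{alternative}, \code{score}, \code{rank} and \code{rank_label},
#'   sorted by descending score.
#' @export
#' @examples
#' rank_alternatives(c(a = 25, b = 24, c = 22, d = 22))
rank_alternatives <- function(scores, tolerance = 0) {
  if (length(scores) < 1) stop_mcda("need at least one alternative")
  if (tolerance < 0) stop_mcda("tolerance must be non-negative")
  ord <- order(-scores)
  s <- scores[ord]
  grp <- cumsum(c(TRUE, diff(-s) > tolerance))
  tied <- as.vector(table(grp)[grp] > 1)
  out <- data.frame(alternative = names(s) %||% as.character(seq_along(s)),
                    score = unname(s),
                    rank = grp,
                    rank_label = rank_label(grp, tied),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Criterion weight summary
#'
#' Criterion weights sorted in descending order (ties broken by criterion
#' id), the ordering used to present elicited weights, e.g. on a polar
#' chart.
#'
#' @param values A \code{value_system}.
#' @param criteria An \code{mcda_criteria} object.
#' @return Data frame with columns \code{criterion_id}, \code{name},
#'   \code{weight}.
#' @export
weight_summary <- function(values, criteria) {
  w <- criterion_weights(values, criteria)
  ord <- order(-w, names(w))
  data.frame(criterion_id = names(w)[ord],
             name = vapply(criteria[ord], `[[`, character(1), "name"),
             weight = unname(w[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit an additive MCDA model
#'
#' The central model constructor: combines a performance matrix, a criteria
#' set and an elicited value system into scored, ranked alternatives under
#' both the unweighted (ordinal points) and the weighted (additive
#' part-worth) model.
#'
#' @param matrix A \code{performance_matrix}.
#' @param criteria An \code{mcda_criteria} object.
#' @param values A \code{value_system}.
#' @param tolerance Tie tolerance passed to [rank_alternatives()].
#' @return An object of class \code{mcda} with components
#'   \code{unweighted} and \code{weighted} (each holding a per-criterion
#'   \code{contributions} matrix and a ranked \code{table}), and
#'   \code{weights} (the descending criterion weight summary).  Methods:
#'   \code{print}, \code{summary}, \code{coef} (criterion weights),
#'   \code{plot} (weight profile) and \code{simulate} (Monte Carlo score
#'   draws under uncertainty; see [run_psa()]).
#' @seealso [run_psa()], [medopt]
#' @export
#' @examples
#' fit <- mcda(medopt_matrix(), medopt_criteria(), medopt_values())
#' summary(fit)
#' coef(fit)
mcda <- function(matrix, criteria, values, tolerance = 0) {
  report <- validate_matrix(matrix, criteria)
  if (!report$ok) {
    stop_mcda("performance matrix fails validation (",
              nrow(report$missing), " missing, ",
              nrow(report$unknown), " unknown); see validate_matrix()")
  }
  vcheck <- validate_values(values, criteria)
  if (!vcheck$ok) {
    stop_mcda("value system fails validation: ",
              paste(vcheck$problems, collapse = "; "))
  }
  un_contrib <- contribution_table(matrix, criteria, model = "unweighted")
  w_contrib <- contribution_table(matrix, criteria, values, model = "weighted")
  un_tot <- unweighted_total(matrix, criteria)
  w_tot <- weighted_value(values, matrix, criteria)
  structure(list(criteria = criteria, matrix = matrix, values = values,
                 unweighted = list(contributions = un_contrib,
                                   table = rank_alternatives(un_tot, tolerance)),
                 weighted = list(contributions = w_contrib,
                                 table = rank_alternatives(w_tot, tolerance)),
                 weights = weight_summary(values, criteria),
                 tolerance = tolerance),
            class = "mcda")
}

#' @export
print.mcda <- function(x, ...) {
  cat("Additive MCDA over", nrow(x$weighted$table), "alternatives and",
      length(x$criteria), "criteria\n\n")
  merged <- merge(x$unweighted$table, x$weighted$table,
                  by = "alternative", suffixes = c(".unweighted", ".weighted"))
  merged <- merged[order(merged$rank.weighted), ]
  out <- data.frame(alternative = merged$alternative,
                    unweighted = merged$score.unweighted,
                    rank = merged$rank_label.unweighted,
                    weighted = merged$score.weighted,
                    rank.w = merged$rank_label.weighted)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mcda <- function(object, ...) {
  structure(list(fit = object), class = "summary.mcda")
}

#' @export
print.summary.mcda <- function(x, ...) {
  print(x$fit)
  cat("\nCriterion weights (descending):\n")
  print(x$fit$weights, row.names = FALSE)
  cat("\nWeighted contributions:\n")
  print(x$fit$weighted$contributions)
  invisible(x)
}

#' @export
coef.mcda <- function(object, ...) {
  stats::setNames(object$weights$weight, object$weights$criterion_id)
}

#' @export
plot.mcda <- function(x, ...) {
  w <- x$weights
  op <- graphics::par(mar = c(5, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(w$weight), names.arg = rev(w$criterion_id),
                    horiz = TRUE, las = 1, xlab = "criterion weight (%)", ...)
  invisible(x)
}

#' Export polar-chart data for criterion weights
#'
#' Writes the descending (criterion, weight) pairs used to draw a polar
#' chart of elicited weights.
#'
#' @param fit An \code{mcda} object.
#' @param path Destination CSV file.
#' @return \code{path}, invisibly.
#' @export
write_polar_data <- function(fit, path) {
  stopifnot(inherits(fit, "mcda"))
  utils::write.csv(fit$weights, path, row.names = FALSE)
  invisible(path)
}

#' Full score report
#'
#' Bundles the unweighted and weighted score tables and the descending
#' criterion weight summary.
#'
#' @inheritParams mcda
#' @return List with \code{unweighted}, \code{weighted} (both
#'   \code{score_table}s) and \code{weights}.
#' @export
score_report <- function(matrix, criteria, values, tolerance = 0) {
  fit <- mcda(matrix, criteria, values, tolerance)
  list(unweighted = fit$unweighted$table,
       weighted = fit$weighted$table,
       weights = fit$weights)
}
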