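# Probabilistic sensitivity analysis: Monte Carlo propagation of weight
# uncertainty (Dirichlet) and score uncertainty (gamma) into total-score
# and rank uncertainty.

#' Sample criterion weight vectors from a Dirichlet distribution
#'
#' Draws weight vectors whose mean matches the elicited weights: the
#' Dirichlet parameter is \eqn{\alpha_i = \kappa W_i / 100}, so the
#' concentration \eqn{\kappa} controls spread without moving the mean.
#'
#' @param values A \code{value_system}.
#' @param criteria An \code{mcda_criteria} object.
#' @param kappa Positive concentration parameter.
#' @param n Number of draws.
#' @return An \code{n} x n-criteria matrix of proportions; each row sums
#'   to 1.
#' @export
sample_weights <- function(values, criteria, kappa, n) {
  if (kappa <= 0) stop_mcda("kappa must be positive")
  W <- criterion_weights(values, criteria)
  out <- rdirichlet(n, kappa * W / 100)
  colnames(out) <- names(W)
  out
}

#' Sample perturbed score contributions from gamma distributions
#'
#' Each non-zero base contribution \eqn{c} is replaced by a gamma draw with
#' mean \eqn{c} and standard deviation \eqn{cv \cdot c} (shape
#' \eqn{1/cv^2}, scale \eqn{c \cdot cv^2}); zero contributions stay zero.
#'
#' @param contributions Numeric vector (or matrix) of non-negative base
#'   contributions.
#' @param cv Positive coefficient of variation.
#' @param n Number of draws.
#' @return An \code{n} x \code{length(contributions)} matrix of draws.
#' @export
sample_scores <- function(contributions, cv, n) {
  if (cv <= 0) stop_mcda("cv must be positive")
  cc <- as.numeric(contributions)
  if (any(cc < 0)) stop_mcda("base contributions must be non-negative")
  k <- length(cc)
  out <- base::matrix(0, nrow = n, ncol = k)
  nz <- which(cc > 0)
  if (length(nz) > 0) {
    shape <- 1 / cv^2
    out[, nz] <- stats::rgamma(n * length(nz), shape = shape,
                               scale = rep(cc[nz] * cv^2, each = n))
  }
  out
}

# Shared Monte Carlo engine: iterations x alternatives matrix of totals.
psa_draws <- function(fit, scenario, iterations, kappa, cv) {
  C <- fit$weighted$contributions            # criteria x alternatives
  W <- criterion_weights(fit$values, fit$criteria)
  n_alt <- ncol(C)
  n_crit <- nrow(C)
  scaled <- array(rep(t(C)[rep(seq_len(n_alt), iterations), ], 1),
                  dim = c(n_alt * iterations, n_crit))
  # rows grouped by iteration: ((it1 alt1..altA), (it2 alt1..altA), ...)
  if (scenario %in% c("weights", "both")) {
    Wd <- sample_weights(fit$values, fit$criteria, kappa, iterations)
    factor <- sweep(Wd * 100, 2, W, "/")     # iterations x criteria
    scaled <- scaled * factor[rep(seq_len(iterations), each = n_alt), ]
  }
  if (scenario %in% c("scores", "both")) {
    shape <- 1 / cv^2
    nz <- scaled > 0
    draws <- scaled
    draws[nz] <- stats::rgamma(sum(nz), shape = shape,
                               scale = scaled[nz] * cv^2)
    scaled <- draws
  }
  totals <- base::matrix(rowSums(scaled), nrow = iterations, ncol = n_alt,
                         byrow = TRUE)
  colnames(totals) <- colnames(C)
  totals
}

#' Run a probabilistic sensitivity analysis
#'
#' Monte Carlo simulation of the weighted additive model under three
#' uncertainty scenarios: \code{"scores"} perturbs each non-zero weighted
#' contribution with a mean-preserving gamma distribution, \code{"weights"}
#' redraws the criterion weights from a mean-matching Dirichlet
#' distribution (rescaling each criterion's level values proportionally),
#' and \code{"both"} does both.  Each iteration recomputes all total
#' scores; the report gives per-alternative expected scores, equal-tailed
#' 2.5-97.5 percentile intervals, and first-rank acceptability (the share
#' of iterations in which the alternative ranks first, ties broken
#' uniformly at random).
#'
#' @param fit An \code{mcda} object (see [mcda()]).
#' @param scenario One of \code{"both"}, \code{"weights"}, \code{"scores"}.
#' @param iterations Number of Monte Carlo iterations (default 1000).
#' @param kappa Dirichlet concentration for weight uncertainty
#'   (default 100).
#' @param cv Gamma coefficient of variation for score uncertainty
#'   (default 0.1).
#' @param seed Optional integer seed; results are bit-for-bit reproducible
#'   given the seed and configuration.
#' @return An object of class \code{mcda_psa}: a result data frame
#'   (\code{alternative}, \code{mean}, \code{lo}, \code{hi},
#'   \code{first_rank}, \code{first_rank_prob}), the draw matrix, and the
#'   configuration echo.
#' @seealso [acceptability()], [mcda()]
#' @export
#' @examples
#' fit <- mcda(medopt_matrix(), medopt_criteria(), medopt_values())
#' run_psa(fit, scenario = "weights", seed = 42)
run_psa <- function(fit, scenario = c("both", "weights", "scores"),
                    iterations = 1000, kappa = 100, cv = 0.1, seed = NULL) {
  stopifnot(inherits(fit, "mcda"))
  scenario <- match.arg(scenario)
  if (iterations < 1) stop_mcda("iterations must be at least 1")
  if (kappa <= 0) stop_mcda("kappa must be positive")
  if (cv <= 0) stop_mcda("cv must be positive")
  if (!is.null(seed)) set.seed(seed)
  totals <- psa_draws(fit, scenario, iterations, kappa, cv)
  first <- max.col(totals, ties.method = "random")
  counts <- tabulate(first, nbins = ncol(totals))
  qs <- apply(totals, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  result <- data.frame(alternative = colnames(totals),
                       mean = colMeans(totals),
                       lo = qs[1, ], hi = qs[2, ],
                       first_rank = counts,
                       first_rank_prob = counts / iterations,
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(result = result, draws = totals, scenario = scenario,
                 iterations = iterations, kappa = kappa, cv = cv,
                 seed = seed,
                 base = stats::setNames(fit$weighted$table$score,
                                        fit$weighted$table$alternative)),
            class = "mcda_psa")
}

#' @export
print.mcda_psa <- function(x, ...) {
  cat("PSA scenario '", x$scenario, "': ", x$iterations, " iterations (kappa = ",
      x$kappa, ", cv = ", x$cv, ")\n", sep = "")
  out <- x$result
  out$mean <- round(out$mean, 1)
  out$lo <- round(out$lo, 1)
  out$hi <- round(out$hi, 1)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mcda_psa <- function(object, ...) object$result

#' @export
plot.mcda_psa <- function(x, ...) {
  r <- x$result
  n <- nrow(r)
  op <- graphics::par(mar = c(5, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(r$mean, seq_len(n), xlim = range(c(r$lo, r$hi)),
                 yaxt = "n", ylab = "", xlab = "total score (%)",
                 pch = 19, ...)
  graphics::segments(r$lo, seq_len(n), r$hi, seq_len(n))
  graphics::axis(2, at = seq_len(n), labels = r$alternative, las = 1)
  invisible(x)
}

#' First-rank acceptability table
#'
#' The probability, under the simulated uncertainty, that each alternative
#' attains the first rank.  Probabilities sum to 1 (within-iteration ties
#' are broken uniformly at random before counting).
#'
#' @param psa An \code{mcda_psa} object.
#' @return Data frame with \code{alternative} and \code{first_rank_prob}.
#' @export
acceptability <- function(psa) {
  stopifnot(inherits(psa, "mcda_psa"))
  psa$result[c("alternative", "first_rank_prob")]
}

#' Monte Carlo score draws for an MCDA fit
#'
#' \code{simulate()} method for \code{mcda} objects: returns the raw
#' iteration-by-alternative total-score draws used by [run_psa()].
#'
#' @param object An \code{mcda} object.
#' @param nsim Number of iterations.
#' @param seed Optional integer seed.
#' @param scenario,kappa,cv As in [run_psa()].
#' @param ... Unused.
#' @return A data frame with \code{nsim} rows, one column per alternative.
#' @export
simulate.mcda <- function(object, nsim = 1000, seed = NULL,
                          scenario = c("both", "weights", "scores"),
                          kappa = 100, cv = 0.1, ...) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  as.data.frame(psa_draws(object, scenario, nsim, kappa, cv))
}
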