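# Replication report and file validation for the bundled case study.

#' Replicate the bundled case-study results
#'
#' Recomputes the case-study score tables from the packaged fixtures and
#' checks them, cell-exactly, against the published reference: unweighted
#' totals 25/24/22/22 with ranks First, Second, Joint third, Joint third;
#' weighted totals 83.8/79.6/71.6/67.8 with ranks First to Fourth; top
#' criterion weight 17.6 (patient needs) and bottom 7.8 (planning); weights
#' summing to 100.  Optionally also runs the three probabilistic
#' sensitivity scenarios and checks that each preserves the deterministic
#' rank order of mean scores.
#'
#' @param psa Also run the three PSA scenarios (default \code{FALSE}).
#' @param iterations,kappa,cv,seed PSA configuration (see [run_psa()]).
#' @return An object of class \code{mcda_report}: \code{checks} (data frame
#'   of named checks and pass flags), \code{ok}, the underlying \code{fit}
#'   and, if requested, the list of \code{psa} results.
#' @export
#' @examples
#' case_study_report()$ok
case_study_report <- function(psa = FALSE, iterations = 1000, kappa = 100,
                              cv = 0.1, seed = 1L) {
  criteria <- medopt_criteria()
  fit <- mcda(medopt_matrix(), criteria, medopt_values())
  ref <- medopt_reference()

  checks <- list()
  add <- function(name, pass) checks[[length(checks) + 1]] <<- data.frame(
    check = name, pass = pass, stringsAsFactors = FALSE)

  un <- fit$unweighted$table
  wt <- fit$weighted$table
  for (i in seq_len(nrow(ref))) {
    a <- ref$alternative[i]
    add(paste0("unweighted total: ", a),
        un$score[un$alternative == a] == ref$unweighted_total[i])
    add(paste0("unweighted rank: ", a),
        un$rank_label[un$alternative == a] == ref$unweighted_rank[i])
    add(paste0("weighted total: ", a),
        tenths(wt$score[wt$alternative == a]) == tenths(ref$weighted_total[i]))
    add(paste0("weighted rank: ", a),
        wt$rank_label[wt$alternative == a] == ref$weighted_rank[i])
  }
  w <- fit$weights
  add("top criterion is patient_needs at 17.6",
      w$criterion_id[1] == "patient_needs" && tenths(w$weight[1]) == 176L)
  add("bottom criterion is planning at 7.8",
      w$criterion_id[nrow(w)] == "planning" && tenths(w$weight[nrow(w)]) == 78L)
  add("criterion weights sum to 100", sum(tenths(w$weight)) == 1000L)

  psa_runs <- NULL
  if (psa) {
    base_order <- wt$alternative
    psa_runs <- lapply(c("scores", "weights", "both"), function(sc) {
      run_psa(fit, scenario = sc, iterations = iterations,
              kappa = kappa, cv = cv, seed = seed)
    })
    names(psa_runs) <- c("scores", "weights", "both")
    for (sc in names(psa_runs)) {
      r <- psa_runs[[sc]]$result
      add(paste0("PSA '", sc, "' preserves the base rank order"),
          identical(r$alternative[order(-r$mean)], base_order))
    }
  }

  checks <- do.call(rbind, checks)
  structure(list(checks = checks, ok = all(checks$pass), fit = fit,
                 psa = psa_runs),
            class = "mcda_report")
}

#' @export
print.mcda_report <- function(x, ...) {
  cat("Case-study replication:", if (x$ok) "PASS" else "FAIL", "\n")
  if (!x$ok) print(x$checks[!x$checks$pass, ], row.names = FALSE)
  else cat("  all", nrow(x$checks), "checks passed\n")
  invisible(x)
}

#' Validate a criteria/matrix/values file triple
#'
#' Reads the three input files (CSV or JSON), runs all structural
#' validators, and aggregates the outcome into a machine-readable report.
#' When the packaged case-study fixtures are being validated, the two
#' documented editorial discrepancies (see [medopt_discrepancies()]) are
#' attached as warnings.
#'
#' @param criteria_path,matrix_path,values_path Input file paths.
#' @return A list of class \code{file_validation}: \code{ok},
#'   \code{errors} (character), \code{warnings} (character),
#'   \code{matrix_report}, \code{values_report}.
#' @export
validate_files <- function(criteria_path, matrix_path, values_path) {
  errors <- character(0)
  warnings <- character(0)
  criteria <- tryCatch(read_criteria(criteria_path), error = function(e) {
    errors <<- c(errors, paste0("criteria: ", conditionMessage(e))); NULL
  })
  matrix <- tryCatch(read_performance_matrix(matrix_path), error = function(e) {
    errors <<- c(errors, paste0("matrix: ", conditionMessage(e))); NULL
  })
  values <- tryCatch(read_value_system(values_path), error = function(e) {
    errors <<- c(errors, paste0("values: ", conditionMessage(e))); NULL
  })
  matrix_report <- values_report <- NULL
  if (!is.null(matrix) && nrow(matrix) == 0) {
    errors <- c(errors, "matrix: contains no assignments")
  }
  if (!is.null(criteria) && !is.null(matrix)) {
    matrix_report <- validate_matrix(matrix, criteria)
    if (!matrix_report$ok) {
      errors <- c(errors, paste0("matrix: ", nrow(matrix_report$missing),
                                 " missing cell(s), ",
                                 nrow(matrix_report$unknown),
                                 " unknown label(s)"))
    }
  }
  if (!is.null(criteria) && !is.null(values)) {
    values_report <- validate_values(values, criteria)
    if (!values_report$ok) {
      errors <- c(errors, paste0("values: ", values_report$problems))
    }
  }
  if (is_medopt_fixture(criteria_path, "medopt_criteria.csv")) {
    disc <- medopt_discrepancies()
    if (nrow(disc$matrix_cells) > 0) {
      warnings <- c(warnings, paste0(
        "documented discrepancy: qualitative grid differs from the score ",
        "table in ", nrow(disc$matrix_cells), " matrix cell(s): ",
        paste(disc$matrix_cells$alternative, "/",
              disc$matrix_cells$criterion_id, collapse = "; ")))
    }
    if (nrow(disc$value_cells) > 0) {
      warnings <- c(warnings, paste0(
        "documented discrepancy: survey level-weight table differs from ",
        "the score table in ", nrow(disc$value_cells), " value cell(s): ",
        paste(disc$value_cells$criterion_id, "/",
              disc$value_cells$level_label, collapse = "; ")))
    }
  }
  structure(list(ok = length(errors) == 0, errors = errors,
                 warnings = warnings, matrix_report = matrix_report,
                 values_report = values_report),
            class = "file_validation")
}

is_medopt_fixture <- function(path, file) {
  identical(normalizePath(path, mustWork = FALSE),
            normalizePath(medopt_path(file), mustWork = FALSE))
}

#' @export
print.file_validation <- function(x, ...) {
  cat("File validation:", if (x$ok) "PASS" else "FAIL", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
as.list.file_validation <- function(x, ...) {
  list(ok = x$ok, errors = x$errors, warnings = x$warnings,
       missing_cells = if (!is.null(x$matrix_report)) x$matrix_report$missing,
       unknown_labels = if (!is.null(x$matrix_report)) x$matrix_report$unknown)
}
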