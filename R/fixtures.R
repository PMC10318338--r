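#' Bundled case study: medication-optimisation interventions for NHS hospitals
#'
#' The package ships a complete worked example: a multi-criteria decision
#' analysis ranking four types of nudge intervention that could optimise
#' medication use in English NHS hospitals (Computerised Interface, Built
#' Environment, Written Communication, Face-to-Face).  Ten implementation
#' criteria were selected from the Consolidated Framework for Implementation
#' Research, each measured on a three-point scale, and criterion weights were
#' elicited from a national survey of 356 quality improvers via pairwise
#' trade-off questions.
#'
#' Two known editorial discrepancies exist between the qualitative grid and
#' the numeric scoring tables of the original study report; see
#' [medopt_discrepancies()].  The \code{"scoring"} variants reproduce the
#' published numeric score tables cell by cell and are the fixtures used for
#' replication; the \code{"qualitative"} matrix and \code{"survey"} value
#' table preserve the published qualitative grid and level-weight table
#' verbatim.
#'
#' @param which Which variant of the fixture to load (see Details).
#' @return \code{medopt_criteria()} returns an \code{mcda_criteria} with 10
#'   three-level criteria; \code{medopt_matrix()} a \code{performance_matrix}
#'   over the four intervention types; \code{medopt_values()} a
#'   \code{value_system}; \code{medopt_reference()} a data frame of the
#'   published totals and rank labels used as the replication reference.
#' @name medopt
#' @examples
#' fit <- mcda(medopt_matrix(), medopt_criteria(), medopt_values())
#' fit
NULL

medopt_path <- function(file) {
  system.file("extdata", file, package = "mcdaid", mustWork = TRUE)
}

#' @rdname medopt
#' @export
medopt_criteria <- function() {
  read_criteria(medopt_path("medopt_criteria.csv"))
}

#' @rdname medopt
#' @export
medopt_matrix <- function(which = c("scoring", "qualitative")) {
  which <- match.arg(which)
  file <- switch(which,
                 scoring = "medopt_matrix.csv",
                 qualitative = "medopt_matrix_qualitative.csv")
  read_performance_matrix(medopt_path(file))
}

#' @rdname medopt
#' @export
medopt_values <- function(which = c("scoring", "survey")) {
  which <- match.arg(which)
  file <- switch(which,
                 scoring = "medopt_values.csv",
                 survey = "medopt_values_survey.csv")
  read_value_system(medopt_path(file))
}

#' @rdname medopt
#' @export
medopt_reference <- function() {
  utils::read.csv(medopt_path("medopt_reference.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Documented discrepancies in the bundled case study
#'
#' Cross-checks the two variants of the case-study fixtures and reports the
#' cells on which they disagree.  Two discrepancies are expected: one
#' performance-matrix cell whose qualitative label disagrees with the numeric
#' score tables (Built Environment / available resources), and level values
#' whose survey-table entries differ from the per-cell numbers in the
#' published score table (patient needs at the middle level; available
#' resources at the middle level).
#'
#' @return A list of class \code{medopt_discrepancies} with data frames
#'   \code{matrix_cells} and \code{value_cells}, plus \code{n_warnings} (one
#'   warning per non-empty category).
#' @export
medopt_discrepancies <- function() {
  criteria <- medopt_criteria()
  m_score <- medopt_matrix("scoring")
  m_qual <- medopt_matrix("qualitative")
  key <- function(m) paste(m$alternative, m$criterion_id, sep = "\r")
  qual_at <- m_qual$level_label[match(key(m_score), key(m_qual))]
  diff_m <- m_score$level_label != qual_at
  matrix_cells <- data.frame(alternative = m_score$alternative[diff_m],
                             criterion_id = m_score$criterion_id[diff_m],
                             scoring_label = m_score$level_label[diff_m],
                             qualitative_label = qual_at[diff_m],
                             stringsAsFactors = FALSE, row.names = NULL)

  v_score <- medopt_values("scoring")
  v_surv <- medopt_values("survey")
  keyv <- function(v) paste(v$criterion_id, v$level_label, sep = "\r")
  surv_at <- v_surv$value_percent[match(keyv(v_score), keyv(v_surv))]
  diff_v <- tenths(v_score$value_percent) != tenths(surv_at)
  value_cells <- data.frame(criterion_id = v_score$criterion_id[diff_v],
                            level_label = v_score$level_label[diff_v],
                            scoring_value = v_score$value_percent[diff_v],
                            survey_value = surv_at[diff_v],
                            stringsAsFactors = FALSE, row.names = NULL)

  structure(list(matrix_cells = matrix_cells, value_cells = value_cells,
                 n_warnings = (nrow(matrix_cells) > 0) + (nrow(value_cells) > 0)),
            class = "medopt_discrepancies")
}

#' @export
print.medopt_discrepancies <- function(x, ...) {
  cat("Documented case-study discrepancies (", x$n_warnings, " warnings)\n", sep = "")
  if (nrow(x$matrix_cells) > 0) {
    cat("Performance-matrix labels that disagree with the numeric score table:\n")
    print(x$matrix_cells, row.names = FALSE)
  }
  if (nrow(x$value_cells) > 0) {
    cat("Level values whose survey-table entry differs from the score table:\n")
    print(x$value_cells, row.names = FALSE)
  }
  invisible(x)
}
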