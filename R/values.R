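#' Construct a value system (part-worth table)
#'
#' A value system stores, for every criterion level, its part-worth: the
#' percentage contribution that level adds to an alternative's total score.
#' By construction the worst level of each criterion is worth 0 and the best
#' level is worth the criterion's weight, so the best-level values sum to
#' (about) 100 across criteria.
#'
#' @param df Data frame with columns \code{criterion_id}, \code{level_label}
#'   and \code{value_percent}.
#' @return An object of class \code{value_system} (a long data frame).
#' @seealso [validate_values()], [criterion_weights()], [medopt_values()]
#' @export
value_system <- function(df) {
  required <- c("criterion_id", "level_label", "value_percent")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_mcda("value table is missing column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(criterion_id = as.character(df$criterion_id),
                   level_label = as.character(df$level_label),
                   value_percent = as.numeric(df$value_percent),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$value_percent))) stop_mcda("value_percent has missing values")
  if (any(df$value_percent < 0)) stop_mcda("level values must be non-negative")
  if (anyDuplicated(df[c("criterion_id", "level_label")])) {
    stop_mcda("duplicate (criterion, level) entry in value table")
  }
  structure(df, class = c("value_system", "data.frame"))
}

#' Read a value system from CSV or JSON
#'
#' @param path Path to a \code{.csv} or \code{.json} file (JSON: array of
#'   \code{{criterion_id, level_label, value_percent}} objects).
#' @return A \code{value_system}.
#' @export
read_value_system <- function(path) {
  if (is_json_path(path)) {
    value_system(jsonlite::fromJSON(path))
  } else {
    value_system(utils::read.csv(path, stringsAsFactors = FALSE,
                                 check.names = FALSE))
  }
}

#' Write a value system to CSV or JSON
#'
#' @param values A \code{value_system}.
#' @param path Destination file; format chosen from the extension.
#' @return \code{path}, invisibly.
#' @export
write_value_system <- function(values, path) {
  stopifnot(inherits(values, "value_system"))
  df <- as.data.frame(values)
  if (is_json_path(path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

value_of <- function(values, criterion_id, level_label) {
  hit <- values$criterion_id == criterion_id & values$level_label == level_label
  if (!any(hit)) {
    stop_mcda("no value for level '", level_label, "' of criterion '",
              criterion_id, "'")
  }
  values$value_percent[which(hit)[1]]
}

#' Criterion weights implied by a value system
#'
#' The weight of a criterion is the value of its best level (equivalently,
#' the swing from worst to best).
#'
#' @param values A \code{value_system}.
#' @param criteria An \code{mcda_criteria} object giving the level order.
#' @return Named numeric vector of weights in percent, in criteria order.
#' @export
criterion_weights <- function(values, criteria) {
  stopifnot(inherits(values, "value_system"), inherits(criteria, "mcda_criteria"))
  vapply(criteria, function(cr) {
    best <- cr$levels$label[which.max(cr$levels$rank)]
    value_of(values, cr$id, best)
  }, numeric(1))
}

#' Validate a value system against a criteria set
#'
#' Checks the structural invariants of a part-worth table: every level of
#' every criterion has a value, the worst level is worth 0, values are
#' non-decreasing in level rank, the best-level value equals the criterion
#' weight (trivially true here since weights are defined as best-level
#' values) and weights sum to 100 within \code{sum_tol}.
#'
#' @param values A \code{value_system}.
#' @param criteria An \code{mcda_criteria} object.
#' @param sum_tol Tolerance on the weight sum (default 0.5, matching
#'   one-decimal rounding of ten weights).
#' @return A list of class \code{values_validation} with a character vector
#'   \code{problems} (empty iff \code{ok}).
#' @export
validate_values <- function(values, criteria, sum_tol = 0.5) {
  stopifnot(inherits(values, "value_system"), inherits(criteria, "mcda_criteria"))
  problems <- character(0)
  for (cr in criteria) {
    v <- vapply(cr$levels$label, function(lab) {
      hit <- values$criterion_id == cr$id & values$level_label == lab
      if (!any(hit)) NA_real_ else values$value_percent[which(hit)[1]]
    }, numeric(1))
    if (any(is.na(v))) {
      problems <- c(problems, paste0("criterion '", cr$id,
                                     "' is missing values for level(s): ",
                                     paste(cr$levels$label[is.na(v)], collapse = ", ")))
      next
    }
    if (v[1] != 0) {
      problems <- c(problems, paste0("criterion '", cr$id,
                                     "' worst level must be worth 0 (got ", v[1], ")"))
    }
    if (any(diff(v) < 0)) {
      problems <- c(problems, paste0("criterion '", cr$id,
                                     "' level values are not non-decreasing"))
    }
  }
  if (length(problems) == 0) {
    w <- criterion_weights(values, criteria)
    total <- sum_tenths(w)
    if (abs(total - 100) > sum_tol) {
      problems <- c(problems, paste0("criterion weights sum to ", total,
                                     ", outside 100 +/- ", sum_tol))
    }
  }
  structure(list(problems = problems, ok = length(problems) == 0),
            class = "values_validation")
}

#' @export
print.values_validation <- function(x, ...) {
  if (x$ok) cat("Value system passes all invariants.\n")
  else cat("Value system problems:\n", paste0("  - ", x$problems, "\n"), sep = "")
  invisible(x)
}

#' @export
print.value_system <- function(x, ...) {
  cat("Value system (", length(unique(x$criterion_id)), " criteria):\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
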