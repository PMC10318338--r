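#' Construct a performance matrix
#'
#' A performance matrix assigns each alternative a qualitative performance
#' level on each criterion.  It is stored in long form (one row per cell);
#' the order of alternatives is the order of first occurrence unless given
#' explicitly.
#'
#' @param df Data frame with columns \code{alternative}, \code{criterion_id}
#'   and \code{level_label}.
#' @param alternatives Optional character vector fixing the display order of
#'   alternatives.
#' @return An object of class \code{performance_matrix} (a long data frame
#'   with an \code{alternatives} attribute).
#' @seealso [validate_matrix()], [rag_render()], [medopt_matrix()]
#' @export
performance_matrix <- function(df, alternatives = NULL) {
  required <- c("alternative", "criterion_id", "level_label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_mcda("performance matrix is missing column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(alternative = as.character(df$alternative),
                   criterion_id = as.character(df$criterion_id),
                   level_label = as.character(df$level_label),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("alternative", "criterion_id")])) {
    dup <- df[duplicated(df[c("alternative", "criterion_id")]), ]
    stop_mcda("duplicate assignment for (", dup$alternative[1], ", ",
              dup$criterion_id[1], ")")
  }
  alternatives <- alternatives %||% unique(df$alternative)
  structure(df, alternatives = alternatives, class = c("performance_matrix", "data.frame"))
}

#' Read a performance matrix from CSV or JSON
#'
#' JSON files hold an array of \code{{alternative, criterion_id,
#' level_label}} objects.
#'
#' @param path Path to a \code{.csv} or \code{.json} file.
#' @return A \code{performance_matrix}.
#' @export
read_performance_matrix <- function(path) {
  if (is_json_path(path)) {
    performance_matrix(jsonlite::fromJSON(path))
  } else {
    performance_matrix(utils::read.csv(path, stringsAsFactors = FALSE,
                                       check.names = FALSE))
  }
}

#' Write a performance matrix to CSV or JSON
#'
#' @param matrix A \code{performance_matrix}.
#' @param path Destination file; format chosen from the extension.
#' @return \code{path}, invisibly.
#' @export
write_performance_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "performance_matrix"))
  df <- as.data.frame(matrix)
  if (is_json_path(path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.performance_matrix <- function(x, ...) {
  alts <- attr(x, "alternatives")
  cat("Performance matrix:", length(alts), "alternatives x",
      length(unique(x$criterion_id)), "criteria\n")
  print(matrix_wide(x), ...)
  invisible(x)
}

matrix_wide <- function(matrix) {
  alts <- attr(matrix, "alternatives")
  crits <- unique(matrix$criterion_id)
  out <- base::matrix(NA_character_, nrow = length(crits), ncol = length(alts),
                      dimnames = list(crits, alts))
  out[cbind(match(matrix$criterion_id, crits),
            match(matrix$alternative, alts))] <- matrix$level_label
  out
}

pm_level <- function(matrix, alternative, criterion_id) {
  hit <- matrix$alternative == alternative & matrix$criterion_id == criterion_id
  if (!any(hit)) {
    stop_mcda("no assignment for (", alternative, ", ", criterion_id, ")")
  }
  matrix$level_label[which(hit)[1]]
}

#' Validate a performance matrix against a criteria set
#'
#' Checks that every (alternative, criterion) cell is filled exactly once and
#' that every assigned label is a valid level of its criterion.  Problems are
#' collected into a report rather than raised as errors.
#'
#' @param matrix A \code{performance_matrix}.
#' @param criteria An \code{mcda_criteria} object.
#' @return A list of class \code{matrix_validation} with elements
#'   \code{missing} (data frame of empty cells), \code{unknown} (data frame
#'   of assignments whose label is not a level of the criterion) and
#'   \code{ok} (\code{TRUE} iff both are empty).
#' @export
validate_matrix <- function(matrix, criteria) {
  stopifnot(inherits(matrix, "performance_matrix"),
            inherits(criteria, "mcda_criteria"))
  alts <- attr(matrix, "alternatives")
  ids <- criterion_ids(criteria)
  grid <- expand.grid(alternative = alts, criterion_id = ids,
                      stringsAsFactors = FALSE)
  key <- paste(matrix$alternative, matrix$criterion_id, sep = "\r")
  present <- paste(grid$alternative, grid$criterion_id, sep = "\r") %in% key
  missing <- grid[!present, , drop = FALSE]
  row.names(missing) <- NULL

  known_crit <- matrix$criterion_id %in% ids
  valid <- logical(nrow(matrix))
  valid[known_crit] <- vapply(which(known_crit), function(i) {
    matrix$level_label[i] %in% criteria[[matrix$criterion_id[i]]]$levels$label
  }, logical(1))
  unknown <- as.data.frame(matrix)[!valid, , drop = FALSE]
  row.names(unknown) <- NULL

  structure(list(missing = missing, unknown = unknown,
                 ok = nrow(missing) == 0 && nrow(unknown) == 0),
            class = "matrix_validation")
}

#' @export
print.matrix_validation <- function(x, ...) {
  if (x$ok) {
    cat("Performance matrix is complete and consistent.\n")
  } else {
    if (nrow(x$missing) > 0) {
      cat(nrow(x$missing), "missing cell(s):\n")
      print(x$missing)
    }
    if (nrow(x$unknown) > 0) {
      cat(nrow(x$unknown), "unknown level label(s):\n")
      print(x$unknown)
    }
  }
  invisible(x)
}

#' Render a performance matrix as a red/amber/green grid
#'
#' Maps the three-point scales used for qualitative performance measurement
#' onto traffic-light tags: worst level red, middle amber, best green.
#'
#' @param matrix A validated \code{performance_matrix}.
#' @param criteria An \code{mcda_criteria} object whose criteria all have
#'   exactly 3 levels.
#' @return A character matrix (criteria x alternatives) of \code{"red"},
#'   \code{"amber"}, \code{"green"} tags, of class \code{rag_grid}.
#' @export
#' @examples
#' rag_render(medopt_matrix(), medopt_criteria())
rag_render <- function(matrix, criteria) {
  if (any(n_levels(criteria) != 3)) {
    bad <- names(which(n_levels(criteria) != 3))
    stop_mcda("RAG rendering needs exactly 3 levels per criterion; offending: ",
              paste(bad, collapse = ", "))
  }
  rep_check <- validate_matrix(matrix, criteria)
  if (!rep_check$ok) stop_mcda("matrix fails validation; see validate_matrix()")
  alts <- attr(matrix, "alternatives")
  ids <- criterion_ids(criteria)
  tags <- c("red", "amber", "green")
  out <- base::matrix(NA_character_, nrow = length(ids), ncol = length(alts),
                      dimnames = list(ids, alts))
  for (i in seq_len(nrow(matrix))) {
    r <- level_rank_of(criteria, matrix$criterion_id[i], matrix$level_label[i])
    out[matrix$criterion_id[i], matrix$alternative[i]] <- tags[r + 1]
  }
  structure(out, class = c("rag_grid", "matrix"))
}

#' @export
print.rag_grid <- function(x, ansi = isatty(stdout()), ...) {
  m <- unclass(x)
  if (isTRUE(ansi)) {
    codes <- c(red = "\033[31m", amber = "\033[33m", green = "\033[32m")
    m[] <- paste0(codes[m], m, "\033[0m")
  }
  print(m, quote = FALSE)
  invisible(x)
}
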