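#' Construct a set of decision criteria
#'
#' A criteria set is the backbone of an additive MCDA model: each criterion
#' carries an ordered scale of qualitative performance levels running from
#' worst (rank 0) to best (rank \code{L - 1}).  The integer ordinal points of
#' a level (\code{rank + 1}) are the 1..L coding used for unweighted scoring.
#'
#' @param df A data frame in long form with columns \code{criterion_id},
#'   \code{name}, \code{domain_tag}, \code{level_rank} and \code{level_label};
#'   one row per (criterion, level).  Criteria appear in the order of first
#'   occurrence.
#' @return An object of class \code{mcda_criteria}: a named list with one
#'   entry per criterion holding \code{id}, \code{name}, \code{domain_tag}
#'   and a \code{levels} data frame (\code{label}, \code{rank},
#'   \code{ordinal_points}) sorted by rank.
#' @seealso [read_criteria()], [random_instance()], [medopt_criteria()]
#' @export
#' @examples
#' crit <- mcda_criteria(data.frame(
#'   criterion_id = "cost", name = "Cost", domain_tag = "resources",
#'   level_rank = 0:2,
#'   level_label = c("Expensive", "Moderate", "Cheap")))
#' crit
mcda_criteria <- function(df) {
  required <- c("criterion_id", "name", "domain_tag", "level_rank", "level_label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_mcda("criteria table is missing column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  df$criterion_id <- as.character(df$criterion_id)
  df$level_label <- as.character(df$level_label)
  df$level_rank <- as.integer(df$level_rank)
  ids <- unique(df$criterion_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$criterion_id == id, , drop = FALSE]
    sub <- sub[order(sub$level_rank), , drop = FALSE]
    if (nrow(sub) < 2) {
      stop_mcda("criterion '", id, "' has fewer than 2 levels")
    }
    if (anyDuplicated(sub$level_rank)) {
      stop_mcda("criterion '", id, "' has duplicated level ranks")
    }
    if (anyDuplicated(sub$level_label)) {
      stop_mcda("criterion '", id, "' has duplicated level labels")
    }
    if (!identical(sub$level_rank, seq_len(nrow(sub)) - 1L)) {
      stop_mcda("criterion '", id, "' level ranks must be 0..L-1 without gaps")
    }
    list(id = id,
         name = as.character(sub$name[1]),
         domain_tag = as.character(sub$domain_tag[1]),
         levels = data.frame(label = sub$level_label,
                             rank = sub$level_rank,
                             ordinal_points = sub$level_rank + 1L,
                             stringsAsFactors = FALSE))
  })
  names(out) <- ids
  structure(out, class = "mcda_criteria")
}

#' Read criteria from CSV or JSON
#'
#' The CSV layout is the long form accepted by [mcda_criteria()]; the JSON
#' layout is an array of objects \code{{id, name, domain_tag, levels:
#' [{label, rank}]}}.  The format is chosen from the file extension.
#'
#' @param path Path to a \code{.csv} or \code{.json} file.
#' @return An \code{mcda_criteria} object.
#' @export
read_criteria <- function(path) {
  if (is_json_path(path)) {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    df <- do.call(rbind, lapply(doc, function(cr) {
      lev <- do.call(rbind, lapply(cr$levels, function(l) {
        data.frame(level_rank = as.integer(l$rank),
                   level_label = as.character(l$label),
                   stringsAsFactors = FALSE)
      }))
      cbind(data.frame(criterion_id = cr$id, name = cr$name,
                       domain_tag = cr$domain_tag,
                       stringsAsFactors = FALSE),
            lev)
    }))
    mcda_criteria(df)
  } else {
    mcda_criteria(utils::read.csv(path, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  }
}

#' Write criteria to CSV or JSON
#'
#' @param criteria An \code{mcda_criteria} object.
#' @param path Destination file; format chosen from the extension as in
#'   [read_criteria()].
#' @return \code{path}, invisibly.
#' @export
write_criteria <- function(criteria, path) {
  stopifnot(inherits(criteria, "mcda_criteria"))
  if (is_json_path(path)) {
    doc <- lapply(unclass(criteria), function(cr) {
      list(id = cr$id, name = cr$name, domain_tag = cr$domain_tag,
           levels = lapply(seq_len(nrow(cr$levels)), function(i) {
             list(label = cr$levels$label[i], rank = cr$levels$rank[i])
           }))
    })
    jsonlite::write_json(unname(doc), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(criteria), path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
as.data.frame.mcda_criteria <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(cr) {
    data.frame(criterion_id = cr$id, name = cr$name,
               domain_tag = cr$domain_tag,
               level_rank = cr$levels$rank,
               level_label = cr$levels$label,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' @export
print.mcda_criteria <- function(x, ...) {
  cat(length(x), "decision criteria:\n")
  for (cr in x) {
    cat("  ", cr$id, " (", cr$domain_tag, "): ",
        paste(cr$levels$label, collapse = " < "), "\n", sep = "")
  }
  invisible(x)
}

criterion_ids <- function(criteria) names(criteria)

n_levels <- function(criteria) {
  vapply(criteria, function(cr) nrow(cr$levels), integer(1))
}

level_rank_of <- function(criteria, id, label) {
  cr <- criteria[[id]]
  if (is.null(cr)) stop_mcda("unknown criterion '", id, "'")
  i <- match(label, cr$levels$label)
  if (is.na(i)) {
    stop_mcda("unknown level '", label, "' for criterion '", id, "'")
  }
  cr$levels$rank[i]
}

level_label_of <- function(criteria, id, rank) {
  cr <- criteria[[id]]
  cr$levels$label[match(rank, cr$levels$rank)]
}
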