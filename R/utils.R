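# Small shared helpers.

# Exact one-decimal accumulation: fixture values are printed to one decimal,
# so sums are done in integer tenths to avoid binary floating-point drift.
tenths <- function(x) as.integer(round(x * 10))

from_tenths <- function(x) x / 10

# Sum that is exact for one-decimal inputs (as printed tables are) and
# falls back to plain floating-point addition otherwise.
sum_tenths <- function(x) {
  if (length(x) > 0 && max(abs(x * 10 - round(x * 10))) < 1e-9) {
    sum(tenths(x)) / 10
  } else {
    sum(x)
  }
}

ordinal_word <- function(n) {
  words <- c("First", "Second", "Third", "Fourth", "Fifth",
             "Sixth", "Seventh", "Eighth", "Ninth", "Tenth")
  ifelse(n <= length(words), words[n], paste0(n, "th"))
}

# Dense rank labels with ties rendered "Joint <rank>" (e.g. "Joint third").
rank_label <- function(rank, tied) {
  w <- ordinal_word(rank)
  ifelse(tied, paste("Joint", tolower(w)), w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mcda <- function(...) stop(..., call. = FALSE)

is_json_path <- function(path) grepl("\\.json$", path, ignore.case = TRUE)

# Dirichlet draws via normalised gamma variates; rows sum to one.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
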