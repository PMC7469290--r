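# internal helpers shared across modules

# Coerce a count table to a numeric matrix with feature rows and sample
# columns. Accepts a matrix with dimnames, or a data frame whose first
# column holds feature ids.
as_count_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort(sprintf("`%s` must have row and column names", arg))
    }
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    ids <- as.character(x[[1L]])
    m <- as.matrix(x[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    return(m)
  }
  abort(sprintf("`%s` must be a matrix or data frame", arg))
}

check_nonnegative <- function(m, what = "count") {
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "negative %s at row '%s', column '%s'", what,
      rownames(m)[bad[1, 1]] %||% bad[1, 1],
      colnames(m)[bad[1, 2]] %||% bad[1, 2]
    ))
  }
  invisible(m)
}

check_no_duplicates <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d) > 0) {
    abort(sprintf("duplicated %s: %s", what, paste(head(d, 5), collapse = ", ")))
  }
  invisible(x)
}

# deterministic rank: ties broken by a secondary key
rank_by <- function(primary, tiebreak) {
  order(order(primary, tiebreak))
}
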