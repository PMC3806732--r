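# Internal helpers shared across modules.

# Coerce a samples-by-taxa tibble (first column `sample_id`) to a numeric
# matrix with sample ids as rownames. Validates shape, not content.
abundance_matrix <- function(table, arg = "table") {
  if (!is.data.frame(table) || ncol(table) < 2L) {
    abort(sprintf("`%s` must be a data frame with a `sample_id` column and at least one taxon column.", arg))
  }
  if (names(table)[1L] != "sample_id") {
    abort(sprintf("the first column of `%s` must be named `sample_id`, not `%s`.", arg, names(table)[1L]))
  }
  ids <- as.character(table$sample_id)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sample ids in `%s`: %s",
                  arg, paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(table[, -1L, drop = FALSE])
  if (!is.numeric(m) && !is.logical(m)) {
    abort(sprintf("taxon columns of `%s` must all be numeric.", arg))
  }
  rownames(m) <- ids
  m
}

# Row-wise relative abundance of a nonnegative matrix; errors on all-zero rows.
relabund_matrix <- function(m, arg = "table") {
  if (any(m < 0)) abort(sprintf("`%s` contains negative values.", arg))
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(sprintf("sample(s) with zero total abundance in `%s`: %s",
                  arg, paste(rownames(m)[tot <= 0], collapse = ", ")))
  }
  sweep(m, 1L, tot, "/")
}

# Validate/align a labels tibble (`sample_id`, `group`) against sample ids.
# Returns a factor of group labels in the order of `ids`.
align_labels <- function(labels, ids) {
  if (!is.data.frame(labels) || !all(c("sample_id", "group") %in% names(labels))) {
    abort("`labels` must be a data frame with columns `sample_id` and `group`.")
  }
  if (anyDuplicated(labels$sample_id)) abort("duplicate sample ids in `labels`.")
  missing <- setdiff(ids, labels$sample_id)
  if (length(missing) > 0L) {
    abort(sprintf("samples missing from `labels`: %s", paste(missing, collapse = ", ")))
  }
  g <- labels$group[match(ids, labels$sample_id)]
  factor(as.character(g))
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%g, %g%s.",
                  name, if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
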