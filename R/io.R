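#' Read a samples-by-taxa abundance table
#'
#' Reads a TSV (first column `sample_id`, remaining columns taxon ids) or
#' a BIOM file (transposed to sample-major on import; requires the
#' biomformat package). Whether the table holds counts or proportions is
#' auto-detected: rows summing to 1 within 1e-6 are proportions,
#' all-integer values are counts. All-zero taxon columns are retained but
#' flagged with a warning.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"biom"`.
#' @return Tibble with a `"kind"` attribute (`"counts"` or
#'   `"proportions"`).
#' @export
read_abundance_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM files requires the `biomformat` package.")
    }
    b <- biomformat::read_biom(path)
    m <- t(as(biomformat::biom_data(b), "matrix"))  # biom is taxa x samples
    tab <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                            tibble::as_tibble(m))
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    prob <- readr::problems(tab)
    if (nrow(prob) > 0L) {
      abort(sprintf("parse error at line %d of %s: %s",
                    prob$row[1] + 1L, path, prob$expected[1]))
    }
    names(tab)[1] <- "sample_id"
  }
  m <- abundance_matrix(tab)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    abort(sprintf("negative value at line %d (sample `%s`) of %s.",
                  neg[1, 1] + 1L, rownames(m)[neg[1, 1]], path))
  }
  sums <- rowSums(m)
  kind <- if (all(abs(sums - 1) <= 1e-6)) {
    "proportions"
  } else if (all(m == floor(m))) {
    "counts"
  } else {
    abort(sprintf("cannot classify %s as counts or proportions.", path))
  }
  zero_cols <- colnames(m)[colSums(m) == 0]
  if (length(zero_cols) > 0L) {
    warn(sprintf("all-zero taxon column(s): %s",
                 paste(head(zero_cols, 5), collapse = ", ")))
  }
  attr(tab, "kind") <- kind
  tab
}

#' Write a samples-by-taxa abundance table as TSV
#'
#' @param table Tibble, first column `sample_id`.
#' @param path Output path.
#' @export
write_abundance_table <- function(table, path) {
  abundance_matrix(table)  # shape validation
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read and write sample-to-group labels
#'
#' Labels are a two-column TSV with header `sample_id`, `group`. Extra
#' columns are dropped with a warning.
#'
#' @param path File path.
#' @return Tibble `sample_id`, `group`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab))) {
    abort(sprintf("%s must have columns `sample_id` and `group`.", path))
  }
  extra <- setdiff(names(tab), c("sample_id", "group"))
  if (length(extra) > 0L) {
    warn(sprintf("ignoring unknown label column(s): %s",
                 paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(tab$sample_id)) abort(sprintf("duplicate sample ids in %s.", path))
  dplyr::mutate(tab[c("sample_id", "group")],
                sample_id = as.character(.data$sample_id),
                group = as.character(.data$group))
}

#' @rdname read_labels
#' @param labels Tibble `sample_id`, `group`.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels[c("sample_id", "group")], path, progress = FALSE)
  invisible(path)
}

#' Read and write t-RFLP peak tables
#'
#' Peak tables are CSV with header `sample_id,fragment_bp,area`, one row
#' per detected peak, in the layout fragment-analysis software exports.
#'
#' @param path File path.
#' @return Long tibble `sample_id`, `fragment_bp`, `area`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "fragment_bp", "area")
  if (!all(need %in% names(tab))) {
    abort(sprintf("%s must have columns %s.", path, paste(need, collapse = ", ")))
  }
  if (any(!is.finite(tab$area)) || any(tab$area < 0)) {
    bad <- which(!is.finite(tab$area) | tab$area < 0)[1]
    abort(sprintf("negative or non-finite peak area at line %d of %s.",
                  bad + 1L, path))
  }
  dplyr::mutate(tab[need], sample_id = as.character(.data$sample_id))
}

#' @rdname read_peaks
#' @param peaks Long tibble `sample_id`, `fragment_bp`, `area`.
#' @export
write_peaks <- function(peaks, path) {
  readr::write_csv(peaks[c("sample_id", "fragment_bp", "area")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write and read structured result reports as JSON
#'
#' Reports are pretty-printed JSON carrying a `schema_version` field.
#' Numeric values are written at full precision and no timestamps are
#' embedded, so identical results produce byte-identical files.
#'
#' @param obj A named list (tibbles allowed as elements).
#' @param path Output path.
#' @export
write_report <- function(obj, path) {
  payload <- c(list(schema_version = "1.0"), obj)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write a square dissimilarity matrix as TSV
#'
#' @param D A `dist` object or symmetric matrix.
#' @param path Output path.
#' @export
write_dissimilarity <- function(D, path) {
  m <- as.matrix(as_dissimilarity(D))
  tab <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m) %||% as.character(seq_len(nrow(m)))),
    tibble::as_tibble(m))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
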