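#' Standardize t-RFLP peak profiles
#'
#' Converts raw peak areas to proportions of each sample's total area,
#' zeroes out peaks representing less than `min_frac` of the total (the
#' conventional 1% floor for fragment-analysis noise), and renormalizes
#' the surviving peaks to sum to one. The floor is strict: a peak at
#' exactly `min_frac` survives. Filtering and renormalization are done
#' once per sample against that sample's own total area, and survivors
#' are not re-filtered after renormalization.
#'
#' Fractional fragment sizes (as reported by fragment-analysis software)
#' are binned to integer bp by round-half-to-even before standardization;
#' areas falling in the same bin are summed.
#'
#' @param peaks Long tibble of peaks with columns `sample_id`,
#'   `fragment_bp`, `area` (areas nonnegative, per-sample total positive).
#' @param min_frac Proportion floor in \[0, 1); default 0.01.
#' @return Long tibble `sample_id`, `fragment_bp`, `proportion`, where
#'   each sample's proportions sum to 1.
#' @examples
#' peaks <- tibble::tibble(sample_id = "a",
#'   fragment_bp = c(100, 150, 200), area = c(98, 1.5, 0.5))
#' standardize_peaks(peaks)  # the 0.5% peak is floored and dropped
#' @export
standardize_peaks <- function(peaks, min_frac = 0.01) {
  if (!is.data.frame(peaks) ||
      !all(c("sample_id", "fragment_bp", "area") %in% names(peaks))) {
    abort("`peaks` must have columns `sample_id`, `fragment_bp`, `area`.")
  }
  check_fraction(min_frac, "min_frac", lo = 0, hi = 1, hi_open = TRUE)
  if (nrow(peaks) == 0L) abort("`peaks` is empty.")
  if (any(!is.finite(peaks$area)) || any(peaks$area < 0)) {
    abort("peak areas must be finite and nonnegative.")
  }

  peaks |>
    dplyr::mutate(fragment_bp = as.integer(round(.data$fragment_bp))) |>
    dplyr::summarise(area = sum(.data$area),
                     .by = c("sample_id", "fragment_bp")) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      total <- sum(d$area)
      if (total <= 0) {
        abort(sprintf("sample `%s` has nonpositive total peak area.", key$sample_id))
      }
      p <- d$area / total
      keep <- p >= min_frac
      if (!any(keep)) {
        abort(sprintf("empty profile after filtering for sample `%s`.", key$sample_id))
      }
      tibble::tibble(fragment_bp = d$fragment_bp[keep],
                     proportion = p[keep] / sum(p[keep]))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, .data$fragment_bp)
}

#' Arcsine-square-root variance-stabilizing transform
#'
#' Maps a proportion p to `asin(sqrt(p))` in radians, the classical
#' variance-stabilizing transform for binomial-type proportions; used on
#' relative abundances before mean-comparison tests and ordination.
#' Monotone increasing on \[0, 1\] with range \[0, pi/2\].
#'
#' @param p Numeric vector of proportions in \[0, 1\] (values within 1e-12
#'   outside are clamped; anything further is an error).
#' @return Numeric vector of transformed values in \[0, pi/2\].
#' @examples
#' arcsine_sqrt(c(0, 0.25, 1))  # 0, pi/6, pi/2
#' @export
arcsine_sqrt <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  bad <- !is.na(p) & (p < -1e-12 | p > 1 + 1e-12)
  if (any(bad)) {
    abort(sprintf("proportions outside [0, 1]: %s",
                  paste(format(utils::head(p[bad], 3)), collapse = ", ")))
  }
  asin(sqrt(pmin(pmax(p, 0), 1)))
}

#' Convert a count or abundance table to relative abundances
#'
#' @param table Samples-by-taxa tibble, first column `sample_id`.
#' @return Tibble of the same shape with rows summing to 1.
#' @export
relative_abundance <- function(table) {
  m <- relabund_matrix(abundance_matrix(table))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}

#' Build the variance-stabilized sample-by-feature matrix
#'
#' Aligns profiles on the union of their features (absent features filled
#' with proportion 0) and applies [arcsine_sqrt()] elementwise. Accepts
#' either a standardized long peak table (columns `sample_id`,
#' `fragment_bp`, `proportion`, e.g. from [standardize_peaks()]) or a wide
#' row-normalized samples-by-taxa table (e.g. from
#' [relative_abundance()]).
#'
#' @param x Long standardized peaks or wide relative-abundance tibble.
#' @return Wide tibble: `sample_id` plus one transformed column per
#'   feature (fragment length or taxon), values in \[0, pi/2\].
#' @export
transform_matrix <- function(x) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  if (all(c("sample_id", "fragment_bp", "proportion") %in% names(x))) {
    if (anyDuplicated(x[c("sample_id", "fragment_bp")])) {
      abort("duplicate (sample_id, fragment_bp) rows in `x`.")
    }
    x <- x |>
      dplyr::mutate(fragment_bp = sprintf("bp_%d", as.integer(.data$fragment_bp))) |>
      tidyr::pivot_wider(id_cols = "sample_id",
                         names_from = "fragment_bp",
                         values_from = "proportion",
                         values_fill = 0,
                         names_sort = TRUE)
  }
  m <- abundance_matrix(x, arg = "x")
  sums <- rowSums(m)
  if (any(abs(sums - 1) > 1e-6)) {
    abort(sprintf("rows must sum to 1 (off by > 1e-6): %s",
                  paste(utils::head(rownames(m)[abs(sums - 1) > 1e-6], 3),
                        collapse = ", ")))
  }
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(arcsine_sqrt(m)))
}
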