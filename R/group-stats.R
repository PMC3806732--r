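
stars_for <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 5e-2 ~ "*",
    .default = "")
}

# Shared scaffolding: per-taxon group comparison over a transformed matrix.
per_taxon_test <- function(tm, labels, test_fun, test_name) {
  m <- abundance_matrix(tm, arg = "tm")
  g <- align_labels(labels, rownames(m))
  groups <- levels(g)
  res <- purrr::map_dfr(colnames(m), function(tx) {
    x <- m[, tx]
    means <- tapply(x, g, mean)
    degenerate <- var(x) == 0
    if (degenerate) {
      row <- tibble::tibble(statistic = 0, p_value = 1)
    } else {
      row <- test_fun(x, g)
    }
    dplyr::bind_cols(
      tibble::tibble(taxon = tx, test = test_name),
      row,
      tibble::as_tibble(as.list(stats::setNames(
        means, sprintf("mean_%s", groups)))),
      tibble::tibble(degenerate = degenerate))
  })
  dplyr::mutate(res, stars = stars_for(.data$p_value))
}

#' Per-taxon one-way ANOVA across groups
#'
#' Classical fixed-effects one-way F-test of equal group means, run
#' independently for every taxon column of a variance-stabilized matrix
#' (see [transform_matrix()]). Taxa with zero total variance are reported
#' with p = 1 and flagged degenerate rather than failing, so sparse taxa
#' never abort a pipeline run. Perfectly separated taxa (zero
#' within-group variance, distinct means) report an infinite F and an
#' underflow-safe minimal p-value.
#'
#' @param tm Samples-by-taxa tibble of transformed values, first column
#'   `sample_id`.
#' @param labels Tibble `sample_id`, `group`; >= 2 groups with >= 2
#'   samples each.
#' @return Tibble with one row per taxon: `taxon`, `test`, `statistic`
#'   (F), `p_value`, per-group means on the transformed scale,
#'   `degenerate`, and significance `stars` (at 0.05, 0.01, 0.001,
#'   0.0001).
#' @export
taxon_anova <- function(tm, labels) {
  g <- align_labels(labels, as.character(tm$sample_id))
  sizes <- table(g)
  if (nlevels(g) < 2L) abort("need at least 2 groups.")
  if (any(sizes < 2L)) {
    abort(sprintf("group(s) with fewer than 2 samples: %s",
                  paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  per_taxon_test(tm, labels, function(x, g) {
    within_var <- tapply(x, g, var)
    if (all(within_var == 0)) {
      # zero within-group variance with distinct means: F diverges
      tibble::tibble(statistic = Inf, p_value = 1e-300)
    } else {
      ft <- oneway.test(x ~ g, var.equal = TRUE)
      tibble::tibble(statistic = unname(ft$statistic),
                     p_value = max(unname(ft$p.value), 1e-300))
    }
  }, "anova")
}

#' Per-taxon two-sample t-tests between two groups
#'
#' Two-sided two-sample t-test per taxon on the transformed scale,
#' pooled-variance by default (`var_equal = FALSE` gives Welch). With two
#' groups and pooled variance, the squared t statistic equals the
#' [taxon_anova()] F statistic. Degenerate (constant) taxa report t = 0,
#' p = 1.
#'
#' @inheritParams taxon_anova
#' @param group_a,group_b Names of the two groups to compare.
#' @param var_equal Pool the group variances (classical t-test)?
#' @return Tibble as in [taxon_anova()] with `statistic` = t.
#' @export
taxon_t_test <- function(tm, labels, group_a, group_b, var_equal = TRUE) {
  g_all <- align_labels(labels, as.character(tm$sample_id))
  for (gr in c(group_a, group_b)) {
    if (!gr %in% levels(g_all)) abort(sprintf("unknown group `%s`.", gr))
  }
  keep <- g_all %in% c(group_a, group_b)
  if (any(table(droplevels(g_all[keep])) < 2L)) {
    abort("both groups need at least 2 samples.")
  }
  tm2 <- tm[keep, , drop = FALSE]
  labels2 <- dplyr::filter(labels, .data$sample_id %in% tm2$sample_id)
  per_taxon_test(tm2, labels2, function(x, g) {
    if (all(tapply(x, g, var) == 0)) {
      if (diff(tapply(x, g, mean)) == 0) {
        tibble::tibble(statistic = 0, p_value = 1)
      } else {
        tibble::tibble(statistic = Inf, p_value = 1e-300)
      }
    } else {
      tt <- t.test(x[g == group_a], x[g == group_b], var.equal = var_equal)
      tibble::tibble(statistic = unname(tt$statistic),
                     p_value = max(unname(tt$p.value), 1e-300))
    }
  }, if (var_equal) "t" else "t_welch")
}

#' Adjust per-taxon p-values for multiple testing
#'
#' Adds a `p_adjusted` column using [stats::p.adjust()]
#' (Benjamini-Hochberg step-up by default). Raw p-values and their stars
#' are left untouched; with hundreds of simultaneous taxon tests the
#' adjusted column is the defensible discovery criterion.
#'
#' @param results Result tibble from [taxon_anova()] or [taxon_t_test()]
#'   (any tibble with a `p_value` column works).
#' @param method Adjustment method, see [stats::p.adjust.methods].
#' @return `results` with a `p_adjusted` column appended (or replaced).
#' @export
adjust_p <- function(results, method = "BH") {
  if (!is.data.frame(results) || !"p_value" %in% names(results)) {
    abort("`results` must be a data frame with a `p_value` column.")
  }
  p <- results$p_value
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must be in [0, 1].")
  dplyr::mutate(results, p_adjusted = p.adjust(.data$p_value, method = method))
}
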