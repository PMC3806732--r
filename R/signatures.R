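#' Presence/absence matrix of an abundance table
#'
#' Reduces a count or relative-abundance table to detection calls per
#' subject, the input scale for prevalence, core-microbiome and consortium
#' analyses. Two derivation rules are offered: `"count"` calls a taxon
#' present at a count of at least `min_count` (default 1); `"abundance"`
#' calls it present at any value strictly greater than zero (for tables
#' already filtered/normalized).
#'
#' @param table Samples-by-taxa tibble, first column `sample_id`.
#' @param rule `"count"` or `"abundance"`.
#' @param min_count Detection threshold for the `"count"` rule.
#' @return Tibble `sample_id` plus one logical column per taxon; the rule
#'   used is recorded in the `"rule"` attribute.
#' @export
presence_matrix <- function(table, rule = c("count", "abundance"),
                            min_count = 1) {
  rule <- match.arg(rule)
  m <- abundance_matrix(table)
  if (any(m < 0)) abort("`table` contains negative values.")
  pm <- if (rule == "count") m >= min_count else m > 0
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                          tibble::as_tibble(pm))
  attr(out, "rule") <- rule
  out
}

#' Per-group and overall taxon prevalence
#'
#' For every taxon, the exact fraction of subjects in which it is present,
#' within each group and across the whole cohort.
#'
#' @param pm Presence matrix from [presence_matrix()].
#' @param labels Tibble `sample_id`, `group` covering all samples.
#' @return Tibble with `taxon`, one prevalence column per group, and
#'   `overall`.
#' @export
prevalence <- function(pm, labels) {
  m <- abundance_matrix(pm, arg = "pm") > 0
  g <- align_labels(labels, rownames(m))
  per_group <- vapply(levels(g),
                      function(lv) colMeans(m[g == lv, , drop = FALSE]),
                      numeric(ncol(m)))
  if (is.null(dim(per_group))) {  # single-taxon table: vapply drops dims
    per_group <- matrix(per_group, nrow = 1L,
                        dimnames = list(colnames(m), levels(g)))
  }
  tibble::tibble(taxon = colnames(m)) |>
    dplyr::bind_cols(tibble::as_tibble(per_group)) |>
    dplyr::mutate(overall = unname(colMeans(m)))
}

#' Core microbiome at a prevalence threshold
#'
#' Taxa whose all-cohort prevalence is at least `tau`; `tau = 1` gives the
#' strict core present in every subject.
#'
#' @param prev Prevalence table from [prevalence()].
#' @param tau Prevalence threshold in (0, 1].
#' @return Character vector of core taxon ids.
#' @export
core_microbiome <- function(prev, tau = 1.0) {
  check_fraction(tau, "tau", lo = 0, hi = 1, lo_open = TRUE)
  if (!all(c("taxon", "overall") %in% names(prev))) {
    abort("`prev` must have columns `taxon` and `overall` (see `prevalence()`).")
  }
  prev$taxon[prev$overall >= tau]
}

#' Group-specific signature sets at a prevalence threshold
#'
#' For each group g, the signature set S_g holds the taxa present in at
#' least `tau` of g's subjects (the canonical threshold is 80%). The
#' exclusive partition assigns each taxon appearing in exactly one group's
#' set to that group — the Venn regions of the S_g with a single member
#' group. Taxa shared by several sets (e.g. the universal core) belong to
#' multi-group regions and to no exclusive set.
#'
#' @param prev Prevalence table from [prevalence()].
#' @param tau Within-group prevalence threshold in (0, 1]; membership uses
#'   `>= tau`.
#' @return A `microsig_signatures` object: list with `threshold`, `groups`,
#'   `sets` (named list of taxon sets), `exclusive` (named list of
#'   single-group Venn regions), and `regions` (tibble `taxon`, `region`,
#'   `n_groups` for every taxon in at least one set).
#' @export
group_signatures <- function(prev, tau = 0.8) {
  check_fraction(tau, "tau", lo = 0, hi = 1, lo_open = TRUE)
  groups <- setdiff(names(prev), c("taxon", "overall"))
  if (length(groups) == 0L) abort("`prev` has no group columns.")
  sets <- lapply(groups, function(g) prev$taxon[prev[[g]] >= tau])
  names(sets) <- groups

  member <- vapply(sets, function(s) prev$taxon %in% s, logical(nrow(prev)))
  n_in <- rowSums(member)
  in_any <- n_in > 0
  region <- apply(member[in_any, , drop = FALSE], 1L, function(r)
    paste(groups[r], collapse = "+"))
  regions <- tibble::tibble(taxon = prev$taxon[in_any], region = region,
                            n_groups = as.integer(n_in[in_any]))
  exclusive <- lapply(groups, function(g) {
    regions$taxon[regions$region == g]
  })
  names(exclusive) <- groups
  structure(list(threshold = tau, groups = groups, sets = sets,
                 exclusive = exclusive, regions = regions),
            class = "microsig_signatures")
}

#' @export
print.microsig_signatures <- function(x, ...) {
  cat(sprintf("<microsig_signatures> tau = %g\n", x$threshold))
  for (g in x$groups) {
    cat(sprintf("  %s: %d taxa (%d exclusive)\n", g,
                length(x$sets[[g]]), length(x$exclusive[[g]])))
  }
  invisible(x)
}

#' @rdname group_signatures
#' @param x A `microsig_signatures` object.
#' @param ... Unused.
#' @return `tidy()`: long tibble `group`, `taxon`, `exclusive`.
#' @method tidy microsig_signatures
#' @export
tidy.microsig_signatures <- function(x, ...) {
  purrr::map_dfr(x$groups, function(g) {
    tibble::tibble(group = g, taxon = x$sets[[g]],
                   exclusive = x$sets[[g]] %in% x$exclusive[[g]])
  })
}

#' Fraction of a consortium carried by one subject
#'
#' @param presence Named logical vector (or one-row presence matrix) of a
#'   subject's taxon detections.
#' @param consortium Non-empty character vector of consortium taxon ids.
#' @return Fraction of `consortium` present in the subject, in \[0, 1\].
#' @export
subject_coverage <- function(presence, consortium) {
  if (is.data.frame(presence)) {
    m <- abundance_matrix(presence, arg = "presence") > 0
    if (nrow(m) != 1L) abort("`presence` must describe a single subject.")
    presence <- m[1L, ]
  }
  if (length(consortium) == 0L) abort("empty consortium.")
  missing <- setdiff(consortium, names(presence))
  if (length(missing) > 0L) {
    abort(sprintf("consortium taxa absent from `presence`: %s",
                  paste(missing, collapse = ", ")))
  }
  mean(as.logical(presence[consortium]))
}

#' Consortium prediction likelihood per group
#'
#' Quantifies how well mere presence of a group's consortium identifies
#' that group. A subject "qualifies" for group g when it carries strictly
#' more than `theta` of g's consortium taxa. The likelihood is
#' L_g = (qualifying subjects belonging to g) / (qualifying subjects in
#' the denominator population). With `denominator = "all"` (default) the
#' denominator spans the whole cohort, so L_g is in \[0, 1\] and reads as
#' a precision; `"others"` restricts it to subjects outside g (an
#' odds-like ratio that can exceed 1 and is undefined when no outsider
#' qualifies).
#'
#' @param pm Presence matrix from [presence_matrix()].
#' @param labels Tibble `sample_id`, `group` covering all samples.
#' @param sigs A `microsig_signatures` object from [group_signatures()].
#' @param theta Coverage threshold in (0, 1); qualification is strict
#'   (`coverage > theta`), so ties at exactly `theta` do not qualify.
#' @param consortium `"exclusive"` (default) uses each group's exclusive
#'   Venn set; `"full"` uses the whole >= tau signature set.
#' @param denominator `"all"` or `"others"` (see above).
#' @return Tibble with one row per group: `group`, `consortium_size`,
#'   `numerator`, `denominator`, `likelihood` (`NA` when the consortium is
#'   empty or the denominator is 0, flagged in `undefined`), plus the
#'   `theta`/`tau`/policy columns used.
#' @export
consortium_likelihood <- function(pm, labels, sigs, theta = 0.8,
                                  consortium = c("exclusive", "full"),
                                  denominator = c("all", "others")) {
  consortium <- match.arg(consortium)
  denominator <- match.arg(denominator)
  check_fraction(theta, "theta", lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  if (!inherits(sigs, "microsig_signatures")) {
    abort("`sigs` must come from `group_signatures()`.")
  }
  m <- abundance_matrix(pm, arg = "pm") > 0
  g <- align_labels(labels, rownames(m))
  extra <- setdiff(sigs$groups, levels(g))
  if (length(extra) > 0L) {
    abort(sprintf("signature group(s) absent from `labels`: %s",
                  paste(extra, collapse = ", ")))
  }

  purrr::map_dfr(sigs$groups, function(grp) {
    C <- if (consortium == "exclusive") sigs$exclusive[[grp]] else sigs$sets[[grp]]
    if (length(C) == 0L) {
      return(tibble::tibble(group = grp, consortium_size = 0L,
                            numerator = NA_integer_, denominator = NA_integer_,
                            likelihood = NA_real_, undefined = TRUE))
    }
    missing <- setdiff(C, colnames(m))
    if (length(missing) > 0L) {
      abort(sprintf("consortium taxa absent from `pm`: %s",
                    paste(missing, collapse = ", ")))
    }
    coverage <- rowMeans(m[, C, drop = FALSE])
    qualifies <- coverage > theta
    num <- sum(qualifies & g == grp)
    den <- if (denominator == "all") sum(qualifies) else sum(qualifies & g != grp)
    if (den == 0L) {
      warn(sprintf("no qualifying subjects in the denominator for group `%s`.", grp))
    }
    tibble::tibble(group = grp, consortium_size = length(C),
                   numerator = as.integer(num), denominator = as.integer(den),
                   likelihood = if (den > 0) num / den else NA_real_,
                   undefined = den == 0L)
  }) |>
    dplyr::mutate(theta = theta, tau = sigs$threshold,
                  consortium = consortium, denominator_policy = denominator)
}
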