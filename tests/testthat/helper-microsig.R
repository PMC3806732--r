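# Shared fixtures and independent oracles, built in code at test time.

# A small planted cohort for fast end-to-end checks.
tiny_spec <- function(seed = 1, ...) {
  args <- modifyList(
    list(n_groups = 2, n_per_group = 6, n_core_taxa = 2,
         n_signature_taxa_per_group = 3, p_within = 1, p_without = 0,
         n_background_taxa = 8, background_prevalence_range = c(0.3, 0.6),
         depth = 800, seed = seed),
    list(...))
  do.call(cohort_spec, args)
}

# A wide abundance tibble from a plain matrix.
as_table <- function(m, ids = sprintf("s%d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("t%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(m))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent two-pass oracle for peak standardization: explicit loops,
# no shared code with standardize_peaks().
oracle_standardize <- function(bp, area, min_frac = 0.01) {
  total <- 0
  for (a in area) total <- total + a
  p <- numeric(length(area))
  for (i in seq_along(area)) p[i] <- area[i] / total
  keep_bp <- integer(0); keep_p <- numeric(0)
  for (i in seq_along(p)) {
    if (p[i] >= min_frac) {
      keep_bp <- c(keep_bp, bp[i]); keep_p <- c(keep_p, p[i])
    }
  }
  s <- 0
  for (q in keep_p) s <- s + q
  list(fragment_bp = keep_bp, proportion = keep_p / s)
}

# Brute-force consortium likelihood by explicit subject enumeration.
oracle_likelihood <- function(presence, groups, consortium, group,
                              theta = 0.8, denominator = "all") {
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(presence))) {
    hits <- 0L
    for (tx in consortium) if (presence[i, tx]) hits <- hits + 1L
    qualifies <- hits / length(consortium) > theta
    if (!qualifies) next
    if (groups[i] == group) num <- num + 1L
    if (denominator == "all" || groups[i] != group) den <- den + 1L
  }
  list(numerator = num, denominator = den,
       likelihood = if (den > 0) num / den else NA_real_)
}
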