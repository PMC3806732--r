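#' Specify a synthetic cohort design
#'
#' Builds a validated design object for [generate_cohort()]. The defaults
#' emulate a four-group oral-microbiome survey: 4 groups of 25 subjects,
#' 398 species-level OTUs of which 8 form a universal core, 10 per group
#' form a group-specific consortium (present in 95% of their own group and
#' 5% of the others), and the remainder are background flora with a shared
#' cohort-wide prevalence; one group has a lower Dirichlet concentration,
#' giving it depressed evenness and Shannon diversity.
#'
#' Presence of each taxon in each subject is Bernoulli at its planted
#' prevalence; abundances of the present taxa are Dirichlet with the
#' group's concentration parameter and converted to counts by a multinomial
#' draw of the expected sequencing depth. Richness (prevalence draws) and
#' evenness (concentration) are therefore controlled separately.
#'
#' @param n_groups Number of subject groups.
#' @param n_per_group Subjects per group.
#' @param n_core_taxa Taxa planted at prevalence 1 in every group.
#' @param n_signature_taxa_per_group Taxa per group planted at `p_within`
#'   inside the group and `p_without` outside it.
#' @param p_within,p_without Within/outside-group prevalence of signature
#'   taxa; must satisfy `0 <= p_without < p_within <= 1`.
#' @param n_background_taxa Taxa with a single cohort-wide prevalence drawn
#'   uniformly from `background_prevalence_range` (no group effect).
#' @param background_prevalence_range Length-2 numeric in \[0, 1\].
#' @param abundance_concentration Positive Dirichlet concentration per
#'   group (recycled); lower values give more uneven communities. The
#'   default depresses evenness in the first group.
#' @param depth Expected total count per sample (multinomial size).
#' @param seed Integer seed; identical spec + seed is bit-reproducible.
#' @return A `microsig_cohort_spec` list.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_groups = 4,
                        n_per_group = 25,
                        n_core_taxa = 8,
                        n_signature_taxa_per_group = 10,
                        p_within = 0.95,
                        p_without = 0.05,
                        n_background_taxa = 350,
                        background_prevalence_range = c(0.20, 0.40),
                        abundance_concentration = c(0.3, rep(1, n_groups - 1)),
                        depth = 6336,
                        seed = 1) {
  n_groups <- check_count(n_groups, "n_groups", min = 1L)
  n_per_group <- check_count(n_per_group, "n_per_group", min = 1L)
  n_core_taxa <- check_count(n_core_taxa, "n_core_taxa", min = 0L)
  n_signature_taxa_per_group <-
    check_count(n_signature_taxa_per_group, "n_signature_taxa_per_group", min = 0L)
  n_background_taxa <- check_count(n_background_taxa, "n_background_taxa", min = 0L)
  depth <- check_count(depth, "depth", min = 1L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  check_fraction(p_within, "p_within", lo = 0, hi = 1, lo_open = TRUE)
  check_fraction(p_without, "p_without", lo = 0, hi = 1)
  if (p_without >= p_within) abort("`p_without` must be strictly less than `p_within`.")
  if (!is.numeric(background_prevalence_range) ||
      length(background_prevalence_range) != 2L ||
      any(background_prevalence_range < 0) ||
      any(background_prevalence_range > 1) ||
      background_prevalence_range[1] > background_prevalence_range[2]) {
    abort("`background_prevalence_range` must be an increasing pair in [0, 1].")
  }
  conc <- rep_len(as.numeric(abundance_concentration), n_groups)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("`abundance_concentration` must be positive and finite.")
  }
  n_taxa <- n_core_taxa + n_groups * n_signature_taxa_per_group + n_background_taxa
  if (n_taxa < 1L) abort("`n_core_taxa` + signature + `n_background_taxa` must be >= 1.")
  structure(
    list(n_groups = n_groups, n_per_group = n_per_group,
         n_core_taxa = n_core_taxa,
         n_signature_taxa_per_group = n_signature_taxa_per_group,
         p_within = p_within, p_without = p_without,
         n_background_taxa = n_background_taxa,
         background_prevalence_range = as.numeric(background_prevalence_range),
         abundance_concentration = conc,
         depth = depth, seed = seed),
    class = "microsig_cohort_spec")
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws an OTU count table, group labels and the planted ground truth from
#' a [cohort_spec()]. Taxon identities are anonymous (`otu_001`, ...); the
#' returned `truth` element records which taxa are core, which belong to
#' each group's consortium, and the full planted prevalence matrix.
#'
#' @param spec A `microsig_cohort_spec` from [cohort_spec()].
#' @return A list of class `microsig_cohort` with elements
#'   * `table`: tibble, `sample_id` + one integer count column per taxon;
#'   * `labels`: tibble with `sample_id`, `group`;
#'   * `truth`: list with `core_taxa`, `signature_taxa` (named by group),
#'     `background_taxa`, and `planted_prevalence` (taxon-by-group tibble);
#'   * `spec`: the input spec.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_groups = 2, n_per_group = 5,
#'   n_core_taxa = 2, n_signature_taxa_per_group = 2,
#'   n_background_taxa = 10, depth = 500, seed = 42))
#' dim(coh$table)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "microsig_cohort_spec")) {
    spec <- do.call(cohort_spec, spec)
  }
  G <- spec$n_groups
  n <- G * spec$n_per_group
  n_sig <- G * spec$n_signature_taxa_per_group
  n_taxa <- spec$n_core_taxa + n_sig + spec$n_background_taxa

  taxa <- sprintf("otu_%03d", seq_len(n_taxa))
  groups <- sprintf("G%d", seq_len(G))
  core_taxa <- taxa[seq_len(spec$n_core_taxa)]
  sig_taxa <- if (spec$n_signature_taxa_per_group > 0) {
    split(taxa[spec$n_core_taxa + seq_len(n_sig)],
          rep(groups, each = spec$n_signature_taxa_per_group))
  } else {
    stats::setNames(rep(list(character()), G), groups)
  }
  bg_taxa <- taxa[seq.int(spec$n_core_taxa + n_sig + 1, length.out = spec$n_background_taxa)]

  sample_ids <- sprintf("S%03d", seq_len(n))
  group_of <- rep(groups, each = spec$n_per_group)

  withr::with_seed(spec$seed, {
    # Planted prevalence matrix: taxa x groups.
    prev <- matrix(0, n_taxa, G, dimnames = list(taxa, groups))
    prev[core_taxa, ] <- 1
    for (g in groups) {
      prev[sig_taxa[[g]], ] <- spec$p_without
      prev[sig_taxa[[g]], g] <- spec$p_within
    }
    if (length(bg_taxa) > 0) {
      r <- spec$background_prevalence_range
      prev[bg_taxa, ] <- runif(length(bg_taxa), r[1], r[2])  # shared across groups
    }

    counts <- matrix(0L, n, n_taxa, dimnames = list(sample_ids, taxa))
    for (i in seq_len(n)) {
      p <- prev[, group_of[i]]
      present <- rbinom(n_taxa, 1L, p) == 1L
      if (!any(present)) present[which.max(p)] <- TRUE  # degenerate guard
      alpha <- spec$abundance_concentration[match(group_of[i], groups)]
      w <- rgamma(sum(present), shape = alpha, rate = 1)
      if (all(w == 0)) w <- rep(1, length(w))  # numeric underflow at tiny alpha
      # Every detected taxon gets >= 1 count so observed presence equals the
      # planted Bernoulli layer; the rest of the depth is multinomial.
      n_present <- sum(present)
      if (spec$depth > n_present) {
        counts[i, present] <- 1L +
          as.integer(rmultinom(1L, spec$depth - n_present, w / sum(w)))
      } else {
        counts[i, present] <- as.integer(rmultinom(1L, spec$depth, w / sum(w)))
      }
    }
  })

  table <- dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                            tibble::as_tibble(counts))
  labels <- tibble::tibble(sample_id = sample_ids, group = group_of)
  truth <- list(
    core_taxa = core_taxa,
    signature_taxa = sig_taxa,
    background_taxa = bg_taxa,
    planted_prevalence = dplyr::bind_cols(tibble::tibble(taxon = taxa),
                                          tibble::as_tibble(prev)))
  structure(list(table = table, labels = labels, truth = truth, spec = spec),
            class = "microsig_cohort")
}

#' @export
print.microsig_cohort <- function(x, ...) {
  cat(sprintf("<microsig_cohort> %d samples x %d taxa, %d groups (seed %d)\n",
              nrow(x$table), ncol(x$table) - 1L, x$spec$n_groups, x$spec$seed))
  invisible(x)
}

#' Assign restriction-fragment lengths to taxa
#'
#' Gives every taxon an integer terminal-fragment length in 50-1200 bp,
#' emulating species-specific restriction sites. A chosen fraction of taxa
#' is deliberately assigned shared lengths, emulating fragment-size
#' collisions between species in real digests.
#'
#' @param taxa Character vector of taxon ids.
#' @param collision_rate Target fraction of taxa sharing a length with at
#'   least one other taxon, in \[0, 1).
#' @param seed Integer seed.
#' @return Tibble with columns `taxon`, `fragment_bp`.
#' @export
random_fragment_map <- function(taxa, collision_rate = 0.1, seed = 1) {
  if (length(taxa) < 1L) abort("`taxa` must be non-empty.")
  if (anyDuplicated(taxa)) abort("`taxa` contains duplicates.")
  check_fraction(collision_rate, "collision_rate", lo = 0, hi = 1, hi_open = TRUE)
  n <- length(taxa)
  pairs <- floor(round(collision_rate * n) / 2)
  n_lengths <- n - pairs
  if (n_lengths > length(50:1200)) {
    abort("too many taxa for distinct fragment lengths in 50-1200 bp.")
  }
  withr::with_seed(seed, {
    lengths <- sample(50:1200, n_lengths)
    idx <- sample.int(n)  # random role assignment
  })
  bp <- integer(n)
  # First 2*pairs shuffled taxa share pairwise lengths; rest are unique.
  if (pairs > 0) {
    shared <- lengths[seq_len(pairs)]
    bp[idx[seq_len(2 * pairs)]] <- rep(shared, each = 2)
  }
  bp[idx[seq.int(2 * pairs + 1, length.out = n - 2 * pairs)]] <-
    lengths[seq.int(pairs + 1, length.out = n - 2 * pairs)]
  tibble::tibble(taxon = as.character(taxa), fragment_bp = bp)
}

#' Derive t-RFLP peak profiles from an abundance table
#'
#' Converts each sample's relative abundances into an electropherogram
#' summary: the peak area at a fragment length is the summed abundance of
#' all taxa mapped to that length (fragment-size collisions merge peaks),
#' perturbed by multiplicative lognormal noise and scaled to an arbitrary
#' positive total area, as a fragment analyzer would report.
#'
#' @param table Samples-by-taxa tibble (counts or proportions), first
#'   column `sample_id`.
#' @param fmap Fragment map from [random_fragment_map()] covering every
#'   taxon in `table`.
#' @param noise_sd Standard deviation of the lognormal peak noise on the
#'   log scale; 0 gives noise-free areas.
#' @param seed Integer seed.
#' @param total_area Reported total area per sample (arbitrary units).
#' @return Long tibble with columns `sample_id`, `fragment_bp`, `area`;
#'   zero-abundance lengths are omitted.
#' @export
generate_trflp <- function(table, fmap, noise_sd = 0.1, seed = 1,
                           total_area = 1e5) {
  m <- abundance_matrix(table)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    abort("`noise_sd` must be a single nonnegative number.")
  }
  unmapped <- setdiff(colnames(m), fmap$taxon)
  if (length(unmapped) > 0L) {
    abort(sprintf("taxa missing from `fmap`: %s", paste(unmapped, collapse = ", ")))
  }
  rel <- relabund_matrix(m)
  bp <- fmap$fragment_bp[match(colnames(rel), fmap$taxon)]
  # Sum abundances of taxa sharing a fragment length.
  agg <- t(rowsum(t(rel), group = bp))  # samples x unique lengths
  lengths <- as.integer(colnames(agg))

  out <- withr::with_seed(seed, {
    purrr::map(seq_len(nrow(agg)), function(i) {
      a <- agg[i, ]
      keep <- a > 0
      a <- a[keep]
      if (noise_sd > 0) a <- a * exp(rnorm(length(a), 0, noise_sd))
      tibble::tibble(sample_id = rownames(agg)[i],
                     fragment_bp = lengths[keep],
                     area = unname(total_area * a / sum(a)))
    })
  })
  dplyr::bind_rows(out)
}
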