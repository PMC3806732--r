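test_that("cohort generation is deterministic and validates its spec", {
  spec <- tiny_spec(seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$table, b$table)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$table), spec$n_groups * spec$n_per_group)
  expect_true(all(rowSums(a$table[-1]) == spec$depth))

  expect_error(cohort_spec(p_within = 0.4, p_without = 0.5), "p_without")
  expect_error(cohort_spec(n_per_group = 0), "n_per_group")
  expect_error(cohort_spec(depth = 0), "depth")
  expect_error(cohort_spec(background_prevalence_range = c(0.5, 0.2)),
               "background_prevalence_range")
  expect_error(cohort_spec(abundance_concentration = -1),
               "abundance_concentration")
})

test_that("degenerate prevalences force the planted presence pattern", {
  coh <- generate_cohort(tiny_spec(seed = 7, p_within = 1, p_without = 0))
  pm <- abs(as.matrix(coh$table[-1])) > 0
  rownames(pm) <- coh$table$sample_id
  for (g in names(coh$truth$signature_taxa)) {
    sig <- coh$truth$signature_taxa[[g]]
    own <- coh$labels$sample_id[coh$labels$group == g]
    other <- setdiff(coh$labels$sample_id, own)
    expect_true(all(pm[own, sig]))
    expect_false(any(pm[other, sig]))
  }
  expect_true(all(pm[, coh$truth$core_taxa]))
})

test_that("empirical signature prevalence tracks the planted value", {
  # Binomial bound: within 3 * sqrt(p(1-p)/n) of 0.95 in >= 95% of
  # (taxon, seed) pairs at n = 25 per group.
  tol <- 3 * sqrt(0.95 * 0.05 / 25)
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    coh <- generate_cohort(cohort_spec(
      n_groups = 4, n_per_group = 25, n_core_taxa = 2,
      n_signature_taxa_per_group = 3, p_within = 0.95, p_without = 0.05,
      n_background_taxa = 5, depth = 300, seed = s))
    pm <- presence_matrix(coh$table)
    prev <- prevalence(pm, coh$labels)
    for (g in names(coh$truth$signature_taxa)) {
      emp <- prev[[g]][match(coh$truth$signature_taxa[[g]], prev$taxon)]
      hits <- hits + sum(abs(emp - 0.95) <= tol)
      total <- total + length(emp)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("empirical prevalences converge to planted values at large n", {
  coh <- generate_cohort(cohort_spec(
    n_groups = 2, n_per_group = 200, n_core_taxa = 2,
    n_signature_taxa_per_group = 3, p_within = 0.9, p_without = 0.1,
    n_background_taxa = 20, depth = 500, seed = 5))
  prev <- prevalence(presence_matrix(coh$table), coh$labels)
  planted <- coh$truth$planted_prevalence
  for (g in c("G1", "G2")) {
    err <- abs(prev[[g]][match(planted$taxon, prev$taxon)] - planted[[g]])
    # binomial noise at n = 200 has sd up to ~0.035 per taxon, so the
    # convergence check is on the mean absolute error
    expect_lte(mean(err), 0.03)
    expect_lte(max(err), 4 * sqrt(0.5 * 0.5 / 200))
  }
})

test_that("a lower concentration group has lower equitability", {
  worse <- 0L
  for (s in 1:10) {
    coh <- generate_cohort(cohort_spec(
      n_groups = 2, n_per_group = 25, n_core_taxa = 5,
      n_signature_taxa_per_group = 1, n_background_taxa = 60,
      abundance_concentration = c(0.3, 1), depth = 2000, seed = s))
    div <- diversity_table(coh$table)
    j <- tapply(div$equitability, coh$labels$group[match(div$sample_id,
                  coh$labels$sample_id)], mean)
    worse <- worse + (j[["G1"]] < j[["G2"]])
  }
  expect_equal(worse, 10L)
})

test_that("fragment maps hit the requested collision rate deterministically", {
  taxa <- sprintf("t%03d", 1:398)
  a <- random_fragment_map(taxa, collision_rate = 0.1, seed = 3)
  b <- random_fragment_map(taxa, collision_rate = 0.1, seed = 3)
  expect_identical(a, b)
  shared <- a$fragment_bp %in% a$fragment_bp[duplicated(a$fragment_bp)]
  expect_gte(mean(shared), 0.05)
  expect_lte(mean(shared), 0.15)
  expect_true(all(a$fragment_bp >= 50 & a$fragment_bp <= 1200))

  none <- random_fragment_map(taxa, collision_rate = 0, seed = 3)
  expect_false(any(duplicated(none$fragment_bp)))
  one <- random_fragment_map("solo", collision_rate = 0, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_true(one$fragment_bp >= 50 && one$fragment_bp <= 1200)
})

test_that("t-RFLP profiles sum collided taxa and respect zero noise", {
  tab <- as_table(matrix(c(0.6, 0.4), 1), ids = "a")
  fmap <- tibble::tibble(taxon = c("t1", "t2"), fragment_bp = c(100L, 150L))
  pk <- generate_trflp(tab, fmap, noise_sd = 0, seed = 1)
  expect_equal(pk$fragment_bp, c(100L, 150L))
  expect_equal(pk$area / sum(pk$area), c(0.6, 0.4))

  # collision: both taxa at 120 bp merge into one peak
  tab2 <- as_table(matrix(c(0.3, 0.2, 0.5), 1), ids = "a")
  fmap2 <- tibble::tibble(taxon = c("t1", "t2", "t3"),
                          fragment_bp = c(120L, 120L, 300L))
  pk2 <- generate_trflp(tab2, fmap2, noise_sd = 0, seed = 1)
  expect_equal(pk2$area[pk2$fragment_bp == 120] / sum(pk2$area), 0.5)

  expect_error(generate_trflp(as_table(matrix(0, 1, 2), ids = "a"),
                              fmap, noise_sd = 0, seed = 1), "zero total")
  expect_error(generate_trflp(tab, fmap[1, ], noise_sd = 0, seed = 1), "t2")

  # determinism with noise
  coh <- generate_cohort(tiny_spec(seed = 2))
  fm <- random_fragment_map(setdiff(names(coh$table), "sample_id"), 0.1, seed = 4)
  expect_identical(generate_trflp(coh$table, fm, 0.2, seed = 9),
                   generate_trflp(coh$table, fm, 0.2, seed = 9))
})
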