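test_that("presence matrix applies the stated detection rule", {
  tab <- as_table(matrix(c(0, 3, 1), 1), ids = "a")
  pm <- presence_matrix(tab, rule = "count")
  expect_equal(unlist(pm[-1], use.names = FALSE), c(FALSE, TRUE, TRUE))
  expect_equal(attr(pm, "rule"), "count")

  rel <- as_table(matrix(c(0, 0.009, 0.2), 1), ids = "a")
  pm2 <- presence_matrix(rel, rule = "abundance")
  expect_equal(unlist(pm2[-1], use.names = FALSE), c(FALSE, TRUE, TRUE))

  expect_error(presence_matrix(tibble::tibble(sample_id = character())),
               "at least one taxon")
  expect_error(presence_matrix(tab, rule = "votes"))
})

test_that("prevalence gives exact per-group and overall fractions", {
  m <- rbind(c(1, 1), c(1, 0), c(1, 0), c(1, 0), c(0, 0),   # group A: 5
             c(1, 0), c(1, 0))                              # group B: 2
  tab <- as_table(m)
  labels <- tibble::tibble(sample_id = tab$sample_id,
                           group = c(rep("A", 5), rep("B", 2)))
  prev <- prevalence(presence_matrix(tab), labels)
  expect_equal(prev$A, c(4 / 5, 1 / 5))
  expect_equal(prev$B, c(1, 0))
  expect_equal(prev$overall, c(6 / 7, 1 / 7))

  expect_error(prevalence(presence_matrix(tab), labels[-1, ]), "missing")
})

test_that("core microbiome thresholds the overall prevalence monotonically", {
  prev <- tibble::tibble(taxon = c("t1", "t2", "t3"),
                         A = c(1, 0.5, 0), overall = c(1, 0.5, 0.25))
  expect_equal(core_microbiome(prev, 1.0), "t1")
  expect_equal(core_microbiome(prev, 0.5), c("t1", "t2"))
  for (lo in c(0.3, 0.5, 0.9)) {
    expect_true(all(core_microbiome(prev, 0.9) %in% core_microbiome(prev, lo)))
  }
  expect_error(core_microbiome(prev, 0), "tau")
})

test_that("group signatures use >= tau and partition Venn regions", {
  # group of 5: 4/5 = 0.8 is in (boundary), 3/5 = 0.6 is out
  m <- rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 0, 1), c(0, 0, 1),
             c(0, 1, 1), c(0, 1, 1), c(0, 1, 1), c(0, 1, 1), c(1, 1, 1))
  tab <- as_table(m)
  labels <- tibble::tibble(sample_id = tab$sample_id,
                           group = rep(c("A", "B"), each = 5))
  sigs <- group_signatures(prevalence(presence_matrix(tab), labels), tau = 0.8)
  expect_setequal(sigs$sets$A, c("t1", "t3"))       # t1: 4/5; t2: 3/5 out
  expect_setequal(sigs$sets$B, c("t2", "t3"))
  expect_equal(sigs$exclusive$A, "t1")
  expect_equal(sigs$exclusive$B, "t2")
  # t3 at prevalence 1 everywhere: in every set, exclusive nowhere
  expect_equal(sigs$regions$region[sigs$regions$taxon == "t3"], "A+B")
  expect_false("t3" %in% unlist(sigs$exclusive))
  expect_length(intersect(sigs$exclusive$A, sigs$exclusive$B), 0)

  td <- tidy(sigs)
  expect_setequal(td$taxon[td$group == "A"], sigs$sets$A)

  # anti-tone in tau
  prev <- prevalence(presence_matrix(tab), labels)
  for (g in c("A", "B")) {
    expect_true(all(group_signatures(prev, 0.9)$sets[[g]] %in%
                      group_signatures(prev, 0.5)$sets[[g]]))
  }
})

test_that("subject coverage counts consortium carriage", {
  pres <- c(t1 = TRUE, t2 = TRUE, t3 = FALSE, t4 = FALSE, t5 = TRUE)
  expect_equal(subject_coverage(pres, c("t1", "t2", "t5")), 1)
  expect_equal(subject_coverage(pres, c("t1", "t2", "t3", "t4")), 0.5)
  expect_equal(subject_coverage(pres, c("t3", "t4")), 0)
  expect_error(subject_coverage(pres, character()), "empty consortium")
  expect_error(subject_coverage(pres, "t9"), "absent")
})

test_that("consortium likelihood matches the worked example", {
  # A = {a1,a2,a3}, B = {b1,b2,b3}; C_A = {t1,t2}; a1,a2,b1 carry both,
  # a3 carries t1 only, b2,b3 carry neither -> qualifiers {a1,a2,b1}, L_A = 2/3
  m <- rbind(c(1, 1), c(1, 1), c(1, 0), c(1, 1), c(0, 0), c(0, 0))
  tab <- as_table(m, ids = c("a1", "a2", "a3", "b1", "b2", "b3"))
  labels <- tibble::tibble(sample_id = tab$sample_id,
                           group = rep(c("A", "B"), each = 3))
  pm <- presence_matrix(tab)
  sigs <- structure(list(threshold = 0.8, groups = c("A", "B"),
                         sets = list(A = c("t1", "t2"), B = character()),
                         exclusive = list(A = c("t1", "t2"), B = character()),
                         regions = tibble::tibble(taxon = c("t1", "t2"),
                                                  region = "A", n_groups = 1L)),
                    class = "microsig_signatures")
  lik <- consortium_likelihood(pm, labels, sigs, theta = 0.8)
  a <- lik[lik$group == "A", ]
  expect_equal(a$numerator, 2L)
  expect_equal(a$denominator, 3L)
  expect_equal(a$likelihood, 2 / 3)
  # empty consortium for B reported undefined
  expect_true(lik$undefined[lik$group == "B"])
  expect_true(is.na(lik$likelihood[lik$group == "B"]))
})

test_that("likelihood is 1 under perfect exclusivity and 1/G under full sharing", {
  coh <- generate_cohort(tiny_spec(seed = 4, p_within = 1, p_without = 0))
  pm <- presence_matrix(coh$table)
  prev <- prevalence(pm, coh$labels)
  sigs <- group_signatures(prev, tau = 0.8)
  lik <- consortium_likelihood(pm, coh$labels, sigs, theta = 0.8)
  expect_equal(lik$likelihood, rep(1, 2))

  # a consortium carried fully by everyone in a balanced G-group cohort
  sigs_core <- structure(list(threshold = 0.8, groups = c("G1", "G2"),
                              sets = list(G1 = coh$truth$core_taxa,
                                          G2 = coh$truth$core_taxa),
                              exclusive = list(G1 = coh$truth$core_taxa,
                                               G2 = coh$truth$core_taxa),
                              regions = tibble::tibble(taxon = character(),
                                                       region = character(),
                                                       n_groups = integer())),
                         class = "microsig_signatures")
  lik2 <- consortium_likelihood(pm, coh$labels, sigs_core, theta = 0.5)
  expect_equal(lik2$likelihood, rep(1 / 2, 2))
})

test_that("likelihood agrees exactly with brute-force enumeration", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(4:10, 1)
    n_taxa <- sample(3:15, 1)
    G <- sample(2:4, 1)
    groups <- sample(sprintf("g%d", 1:G), n, replace = TRUE)
    while (length(unique(groups)) < G) {
      groups <- sample(sprintf("g%d", 1:G), n, replace = TRUE)
    }
    m <- matrix(rbinom(n * n_taxa, 1, runif(1, 0.2, 0.8)), n)
    tab <- as_table(m)
    labels <- tibble::tibble(sample_id = tab$sample_id, group = groups)
    pm <- presence_matrix(tab)
    taxa <- setdiff(names(tab), "sample_id")
    sets <- lapply(sprintf("g%d", 1:G), function(g)
      sample(taxa, sample(1:n_taxa, 1)))
    names(sets) <- sprintf("g%d", 1:G)
    sigs <- structure(list(threshold = 0.8, groups = names(sets),
                           sets = sets, exclusive = sets,
                           regions = tibble::tibble(taxon = character(),
                                                    region = character(),
                                                    n_groups = integer())),
                      class = "microsig_signatures")
    theta <- runif(1, 0.1, 0.9)
    pres <- m == 1; rownames(pres) <- tab$sample_id; colnames(pres) <- taxa
    for (pol in c("all", "others")) {
      lik <- suppressWarnings(
        consortium_likelihood(pm, labels, sigs, theta = theta,
                              denominator = pol))
      for (g in names(sets)) {
        o <- oracle_likelihood(pres, groups, sets[[g]], g, theta, pol)
        row <- lik[lik$group == g, ]
        expect_identical(row$numerator, o$numerator)
        expect_identical(row$denominator, o$denominator)
        expect_identical(row$likelihood, o$likelihood)
      }
    }
  }
})

test_that("qualification counts are non-increasing in theta", {
  coh <- generate_cohort(tiny_spec(seed = 12, p_within = 0.9, p_without = 0.2))
  pm <- presence_matrix(coh$table)
  sigs <- group_signatures(prevalence(pm, coh$labels), tau = 0.6)
  prev_num <- Inf; prev_den <- Inf
  for (theta in c(0.2, 0.4, 0.6, 0.8)) {
    lik <- suppressWarnings(
      consortium_likelihood(pm, coh$labels, sigs, theta = theta))
    expect_true(all(lik$numerator <= prev_num))
    expect_true(all(lik$denominator <= prev_den))
    prev_num <- lik$numerator; prev_den <- lik$denominator
  }
})

test_that("planted consortia are recovered on the study design", {
  ok <- 0L
  for (s in 1:5) {
    coh <- generate_cohort(cohort_spec(seed = 100 + s))
    sigs <- group_signatures(
      prevalence(presence_matrix(coh$table), coh$labels), tau = 0.8)
    rec <- all(mapply(setequal, sigs$exclusive,
                      coh$truth$signature_taxa[names(sigs$exclusive)]))
    ok <- ok + rec
  }
  expect_gte(ok, 4L)
})
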