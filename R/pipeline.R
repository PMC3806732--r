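#' Assemble and validate a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object that serializes losslessly to JSON (see [run_pipeline()]).
#' When `table_path`/`labels_path` are `NULL` the pipeline simulates a
#' cohort from `cohort` instead of reading files.
#'
#' @param min_frac t-RFLP proportion floor in \[0, 1).
#' @param tau Signature prevalence threshold in (0, 1].
#' @param core_tau Core-microbiome prevalence threshold in (0, 1].
#' @param theta Consortium coverage threshold in (0, 1).
#' @param test_frac Held-out fraction for classification, in (0, 1).
#' @param repeats Classification repeats.
#' @param seed Integer seed for every stochastic stage.
#' @param denominator Likelihood denominator policy, `"all"`/`"others"`.
#' @param consortium Consortium choice, `"exclusive"`/`"full"`.
#' @param adjust Multiplicity adjustment method for per-taxon tests.
#' @param noise_sd t-RFLP peak noise (log scale) for simulated profiles.
#' @param trflp_collision_rate Fragment-length collision rate for
#'   simulated profiles.
#' @param nmds_k,nmds_restarts Ordination dimension and restarts.
#' @param num_trees Random-forest size.
#' @param table_path,labels_path Optional input files (TSV; table may be
#'   BIOM).
#' @param cohort A [cohort_spec()] or argument list for it, used when no
#'   input files are given.
#' @return A `microsig_config` list.
#' @export
pipeline_config <- function(min_frac = 0.01, tau = 0.8, core_tau = 1.0,
                            theta = 0.8, test_frac = 0.25, repeats = 1,
                            seed = 1, denominator = "all",
                            consortium = "exclusive", adjust = "BH",
                            noise_sd = 0.1, trflp_collision_rate = 0.1,
                            nmds_k = 2, nmds_restarts = 8, num_trees = 500,
                            table_path = NULL, labels_path = NULL,
                            cohort = list()) {
  check_fraction(min_frac, "min_frac", lo = 0, hi = 1, hi_open = TRUE)
  check_fraction(tau, "tau", lo = 0, hi = 1, lo_open = TRUE)
  check_fraction(core_tau, "core_tau", lo = 0, hi = 1, lo_open = TRUE)
  check_fraction(theta, "theta", lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  check_fraction(test_frac, "test_frac", lo = 0, hi = 1,
                 lo_open = TRUE, hi_open = TRUE)
  repeats <- check_count(repeats, "repeats", min = 1L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  if (!denominator %in% c("all", "others")) abort("`denominator` must be 'all' or 'others'.")
  if (!consortium %in% c("exclusive", "full")) abort("`consortium` must be 'exclusive' or 'full'.")
  if (!adjust %in% stats::p.adjust.methods) abort("unknown `adjust` method.")
  check_fraction(trflp_collision_rate, "trflp_collision_rate",
                 lo = 0, hi = 1, hi_open = TRUE)
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  nmds_k <- check_count(nmds_k, "nmds_k", min = 1L)
  nmds_restarts <- check_count(nmds_restarts, "nmds_restarts", min = 1L)
  num_trees <- check_count(num_trees, "num_trees", min = 1L)
  if (inherits(cohort, "microsig_cohort_spec")) cohort <- unclass(cohort)
  structure(
    list(min_frac = min_frac, tau = tau, core_tau = core_tau, theta = theta,
         test_frac = test_frac, repeats = repeats, seed = seed,
         denominator = denominator, consortium = consortium, adjust = adjust,
         noise_sd = noise_sd, trflp_collision_rate = trflp_collision_rate,
         nmds_k = nmds_k, nmds_restarts = nmds_restarts, num_trees = num_trees,
         table_path = table_path, labels_path = labels_path,
         cohort = cohort),
    class = "microsig_config")
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file produced by [save_config()].
#' @return A validated `microsig_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$schema_version <- NULL
  do.call(pipeline_config, raw)
}

#' @rdname load_config
#' @param config A `microsig_config`.
#' @export
save_config <- function(config, path) {
  write_report(unclass(config), path)
}

#' Run the full signature-discovery pipeline
#'
#' Orchestrates every stage on one cohort: simulate (when no input table
#' is configured) -> t-RFLP profile generation and standardization
#' (simulated cohorts only) -> per-sample diversity -> per-taxon ANOVA on
#' the variance-stabilized scale -> prevalence, core microbiome and group
#' signatures -> consortium likelihoods -> random-forest classification
#' -> Bray-Curtis ordination with a cluster-separation summary. Every
#' stage logs its parameters and outputs to `run.log`; result payloads
#' carry no timestamps, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config A `microsig_config` from [pipeline_config()] (or a JSON
#'   path for [load_config()]).
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages?
#' @return Invisibly, a named list with the per-stage result objects and
#'   a `files` vector of everything written.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "microsig_config")) {
    abort("`config` must be a `microsig_config` or a path to one.")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), line),
               log_con)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      say("stage %s: FAILED (%s)", name, conditionMessage(e))
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  files <- character()
  out <- function(name) {
    p <- file.path(outdir, name)
    files <<- c(files, p)
    p
  }

  save_config(config, out("config.json"))
  simulated <- is.null(config$table_path)

  res <- list()
  if (simulated) {
    coh <- stage("simulate", {
      spec <- do.call(cohort_spec, modifyList(config$cohort,
                                              list(seed = config$seed)))
      generate_cohort(spec)
    })
    say("simulate: %d samples x %d taxa (seed %d)",
        nrow(coh$table), ncol(coh$table) - 1L, config$seed)
    table <- coh$table
    labels <- coh$labels
    write_abundance_table(table, out("otu_table.tsv"))
    write_labels(labels, out("labels.tsv"))
    write_report(coh$truth[c("core_taxa", "signature_taxa", "background_taxa")],
                 out("planted_truth.json"))
    res$cohort <- coh

    res$trflp <- stage("trflp", {
      fmap <- random_fragment_map(setdiff(names(table), "sample_id"),
                                  collision_rate = config$trflp_collision_rate,
                                  seed = config$seed)
      peaks <- generate_trflp(table, fmap, noise_sd = config$noise_sd,
                              seed = config$seed)
      write_peaks(peaks, out("peaks.csv"))
      std <- standardize_peaks(peaks, min_frac = config$min_frac)
      tm <- transform_matrix(std)
      readr::write_tsv(tm, out("trflp_transformed.tsv"), progress = FALSE)
      tm
    })
  } else {
    table <- stage("read", read_abundance_table(config$table_path))
    labels <- stage("read", read_labels(config$labels_path))
    align_labels(labels, as.character(table$sample_id))
  }

  div <- stage("diversity", diversity_table(table))
  readr::write_tsv(div, out("diversity.tsv"), progress = FALSE)
  res$diversity <- div

  tm_taxa <- stage("compare", transform_matrix(relative_abundance(table)))
  comp <- stage("compare", adjust_p(taxon_anova(tm_taxa, labels),
                                    method = config$adjust))
  readr::write_tsv(comp, out("compare_anova.tsv"), progress = FALSE)
  res$comparisons <- comp

  sig <- stage("signatures", {
    pm <- presence_matrix(table)
    prev <- prevalence(pm, labels)
    readr::write_tsv(prev, out("prevalence.tsv"), progress = FALSE)
    core <- core_microbiome(prev, tau = config$core_tau)
    sigs <- group_signatures(prev, tau = config$tau)
    write_report(list(tau = config$tau, core_tau = config$core_tau,
                      core = core, sets = sigs$sets,
                      exclusive = sigs$exclusive),
                 out("signatures.json"))
    list(pm = pm, prev = prev, core = core, sigs = sigs)
  })
  res$signatures <- sig

  lik <- stage("likelihood",
    consortium_likelihood(sig$pm, labels, sig$sigs, theta = config$theta,
                          consortium = config$consortium,
                          denominator = config$denominator))
  write_report(list(likelihoods = lik), out("likelihood.json"))
  res$likelihood <- lik

  cls <- stage("classify",
    classify_cohort(table, labels, test_frac = config$test_frac,
                    seed = config$seed, repeats = config$repeats,
                    num_trees = config$num_trees))
  if (inherits(cls, "microsig_classification")) {
    write_report(list(confusion = as.data.frame(cls$confusion),
                      metrics = cls$metrics,
                      accuracy = cls$accuracy,
                      macro_sensitivity = cls$macro_sensitivity,
                      macro_specificity = cls$macro_specificity,
                      params = cls$params),
                 out("classification.json"))
  } else {
    write_report(list(results = cls$results, summary = cls$summary,
                      params = cls$params),
                 out("classification.json"))
  }
  res$classification <- cls

  ord <- stage("ordinate", {
    D <- bray_curtis(table)
    write_dissimilarity(D, out("bray_curtis.tsv"))
    o <- nmds(D, k = config$nmds_k, seed = config$seed,
              n_restarts = config$nmds_restarts)
    readr::write_tsv(o$points, out("ordination.tsv"), progress = FALSE)
    write_report(list(stress = o$stress, k = o$k, seed = o$seed,
                      n_restarts = o$n_restarts,
                      cluster_separation = cluster_separation(D, labels)),
                 out("ordination.json"))
    o
  })
  res$ordination <- ord

  say("done: %d files in %s", length(files), outdir)
  res$files <- files
  invisible(res)
}
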