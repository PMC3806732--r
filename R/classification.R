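#' Stratified train/test split
#'
#' Splits samples into disjoint, exhaustive train and test sets preserving
#' per-group proportions. The per-group test counts follow a
#' floor-then-largest-remainder rule: each group contributes
#' `floor(n_g * test_frac)` test samples, and the remaining slots (up to
#' the rounded cohort-wide target) go to the groups with the largest
#' fractional remainders, ties broken by group order.
#'
#' @param labels Tibble `sample_id`, `group`; every group needs >= 2
#'   samples.
#' @param test_frac Fraction of samples held out, in (0, 1).
#' @param seed Integer seed; the split is deterministic per seed.
#' @return List with character vectors `train` and `test` of sample ids.
#' @export
stratified_split <- function(labels, test_frac = 0.25, seed = 1) {
  check_fraction(test_frac, "test_frac", lo = 0, hi = 1,
                 lo_open = TRUE, hi_open = TRUE)
  ids <- as.character(labels$sample_id)
  g <- align_labels(labels, ids)
  groups <- levels(g)
  sizes <- as.integer(table(g)[groups])
  if (any(sizes < 2L)) {
    abort(sprintf("group(s) too small to stratify (< 2 samples): %s",
                  paste(groups[sizes < 2L], collapse = ", ")))
  }
  target <- sizes * test_frac
  base <- pmin(floor(target), sizes - 1L)  # keep >= 1 training sample
  extra <- round(sum(target)) - sum(base)
  n_test <- base
  if (extra > 0) {
    order_rem <- order(-(target - base), seq_along(groups))
    take <- head(order_rem[n_test[order_rem] < sizes[order_rem] - 1L], extra)
    n_test[take] <- n_test[take] + 1L
  }
  test <- withr::with_seed(seed, {
    unlist(lapply(seq_along(groups), function(i) {
      pool <- ids[g == groups[i]]
      sample(pool, n_test[i])
    }), use.names = FALSE)
  })
  list(train = setdiff(ids, test), test = test)
}

#' Fit a random-forest classifier and predict held-out samples
#'
#' Trains a random forest (ranger, single-threaded for reproducibility) on
#' the training samples and predicts the group of each test sample.
#' Features default to arcsine-square-root-transformed relative abundances
#' (the variance-stabilized scale); raw proportions or presence/absence
#' are available by flag. Train and test must share the same taxon
#' columns.
#'
#' @param train,test Samples-by-taxa tibbles (counts or proportions),
#'   first column `sample_id`, identical taxon universes.
#' @param labels Tibble `sample_id`, `group` covering the training
#'   samples.
#' @param seed Integer seed for the forest.
#' @param features `"arcsine"`, `"proportion"` or `"presence"`.
#' @param num_trees Number of trees.
#' @param ... Further arguments passed to [ranger::ranger()].
#' @return Tibble `sample_id`, `predicted` (factor over the training
#'   groups).
#' @export
fit_predict <- function(train, test, labels, seed = 1,
                        features = c("arcsine", "proportion", "presence"),
                        num_trees = 500, ...) {
  features <- match.arg(features)
  mtr <- abundance_matrix(train, arg = "train")
  mte <- abundance_matrix(test, arg = "test")
  unseen <- setdiff(colnames(mte), colnames(mtr))
  if (length(unseen) > 0L) {
    abort(sprintf("test has feature columns unseen in training: %s",
                  paste(head(unseen, 5), collapse = ", ")))
  }
  missing <- setdiff(colnames(mtr), colnames(mte))
  if (length(missing) > 0L) {
    abort(sprintf("test is missing training feature columns: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  mte <- mte[, colnames(mtr), drop = FALSE]
  y <- align_labels(labels, rownames(mtr))
  if (any(table(y) < 2L)) {
    warn("some group(s) have fewer than 2 training samples; estimates will be unstable.")
  }
  featurize <- switch(features,
    arcsine = function(m) arcsine_sqrt(relabund_matrix(m)),
    proportion = function(m) relabund_matrix(m),
    presence = function(m) (m > 0) * 1)
  xtr <- as.data.frame(featurize(mtr))
  xte <- as.data.frame(featurize(mte))
  fit <- ranger::ranger(x = xtr, y = y, num.trees = num_trees,
                        seed = seed, num.threads = 1L, ...)
  pred <- stats::predict(fit, data = xte, num.threads = 1L, seed = seed)
  tibble::tibble(sample_id = rownames(mte), predicted = pred$predictions)
}

#' Score predicted against true group labels
#'
#' Builds the confusion matrix and the standard multi-class metrics:
#' overall accuracy, and one-vs-rest sensitivity (TP / (TP + FN)) and
#' specificity (TN / (TN + FP)) per class, macro-averaged over the
#' classes present in the test set. Classes absent from the test set get
#' `NA` sensitivity.
#'
#' @param truth,predicted Equal-length label vectors (factors or
#'   characters); `predicted` must not contain classes unknown to the
#'   union of both vectors' levels.
#' @return A `microsig_classification` object: `confusion` (true x
#'   predicted counts), `metrics` tibble (per class), `accuracy`,
#'   `macro_sensitivity`, `macro_specificity`, `n`.
#' @export
score_classification <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  if (length(truth) == 0L) abort("empty label vectors.")
  classes <- sort(unique(c(as.character(truth), levels(factor(predicted)),
                           as.character(predicted))))
  t_f <- factor(as.character(truth), levels = classes)
  p_f <- factor(as.character(predicted), levels = classes)
  if (anyNA(t_f) || anyNA(p_f)) abort("labels contain missing values.")
  conf <- table(truth = t_f, predicted = p_f)
  n <- sum(conf)
  metrics <- purrr::map_dfr(classes, function(cl) {
    tp <- conf[cl, cl]
    fn <- sum(conf[cl, ]) - tp
    fp <- sum(conf[, cl]) - tp
    tn <- n - tp - fn - fp
    tibble::tibble(
      class = cl,
      n_test = as.integer(tp + fn),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  present <- metrics$n_test > 0
  structure(
    list(confusion = conf,
         metrics = metrics,
         accuracy = sum(diag(conf)) / n,
         macro_sensitivity = mean(metrics$sensitivity[present]),
         macro_specificity = mean(metrics$specificity[present]),
         n = as.integer(n)),
    class = "microsig_classification")
}

#' @export
print.microsig_classification <- function(x, ...) {
  cat(sprintf("<microsig_classification> n = %d, accuracy = %.3f\n", x$n, x$accuracy))
  cat(sprintf("macro sensitivity = %.3f, macro specificity = %.3f\n",
              x$macro_sensitivity, x$macro_specificity))
  print(x$confusion)
  invisible(x)
}

#' @rdname score_classification
#' @param x A `microsig_classification` object.
#' @param ... Unused.
#' @return `tidy()`: the per-class metrics tibble; `glance()`: a one-row
#'   summary.
#' @method tidy microsig_classification
#' @export
tidy.microsig_classification <- function(x, ...) x$metrics

#' @rdname score_classification
#' @method glance microsig_classification
#' @export
glance.microsig_classification <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_sensitivity = x$macro_sensitivity,
                 macro_specificity = x$macro_specificity,
                 n = x$n)
}

#' Discriminate group membership from microbial profiles
#'
#' End-to-end evaluation of how well a cohort's microbial profiles predict
#' group membership: stratified split, random-forest fit on the training
#' portion, prediction of the held-out samples, and scoring. With
#' `repeats > 1` the split/fit/score cycle is repeated with consecutive
#' sub-seeds and per-repeat metrics are summarized as mean and sd.
#'
#' @param table Samples-by-taxa tibble, first column `sample_id`.
#' @param labels Tibble `sample_id`, `group`.
#' @param test_frac Held-out fraction, in (0, 1).
#' @param seed Integer seed (repeat r uses `seed + r - 1`).
#' @param repeats Number of split/fit/score repetitions.
#' @param features Feature scale, see [fit_predict()].
#' @param num_trees Number of trees per forest.
#' @return For `repeats = 1`, a `microsig_classification` with the split
#'   and parameters attached (`$params`). Otherwise a
#'   `microsig_classification_repeated`: per-repeat `results` tibble and a
#'   one-row `summary` (mean/sd of each metric).
#' @export
classify_cohort <- function(table, labels, test_frac = 0.25, seed = 1,
                            repeats = 1, features = "arcsine",
                            num_trees = 500) {
  repeats <- check_count(repeats, "repeats", min = 1L)
  params <- list(test_frac = test_frac, seed = seed, repeats = repeats,
                 features = features, num_trees = num_trees)
  one <- function(s) {
    split <- stratified_split(labels, test_frac = test_frac, seed = s)
    train <- dplyr::filter(table, .data$sample_id %in% split$train)
    test <- dplyr::filter(table, .data$sample_id %in% split$test)
    pred <- fit_predict(train, test, labels, seed = s,
                        features = features, num_trees = num_trees)
    truth <- align_labels(labels, pred$sample_id)
    rep <- score_classification(truth, pred$predicted)
    rep$split <- split
    rep$seed <- s
    rep
  }
  if (repeats == 1L) {
    rep <- one(seed)
    rep$params <- params
    return(rep)
  }
  runs <- lapply(seed + seq_len(repeats) - 1L, one)
  results <- purrr::map_dfr(runs, function(r)
    dplyr::mutate(glance(r), seed = r$seed, .before = 1))
  summary <- tibble::tibble(
    repeats = repeats,
    accuracy_mean = mean(results$accuracy),
    accuracy_sd = sd(results$accuracy),
    macro_sensitivity_mean = mean(results$macro_sensitivity),
    macro_sensitivity_sd = sd(results$macro_sensitivity),
    macro_specificity_mean = mean(results$macro_specificity),
    macro_specificity_sd = sd(results$macro_specificity))
  structure(list(results = results, summary = summary, params = params),
            class = "microsig_classification_repeated")
}

#' @export
print.microsig_classification_repeated <- function(x, ...) {
  cat(sprintf("<microsig_classification_repeated> %d repeats, accuracy = %.3f +/- %.3f\n",
              x$summary$repeats, x$summary$accuracy_mean, x$summary$accuracy_sd))
  invisible(x)
}

#' @method tidy microsig_classification_repeated
#' @export
tidy.microsig_classification_repeated <- function(x, ...) x$results

#' @method glance microsig_classification_repeated
#' @export
glance.microsig_classification_repeated <- function(x, ...) x$summary
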