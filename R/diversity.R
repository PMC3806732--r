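#' Shannon diversity of a relative-abundance vector
#'
#' H = -sum over detected taxa of p * ln(p), in nats. Zero for a
#' mono-species community; maximal (ln S) at the uniform distribution.
#'
#' @param p Nonnegative numeric vector summing to 1 (within 1e-9).
#' @return Shannon index H (nats).
#' @examples
#' shannon_diversity(c(0.5, 0.25, 0.25))
#' @export
shannon_diversity <- function(p) {
  p <- check_relabund_vector(p)
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

#' Shannon equitability (evenness)
#'
#' J = H / ln(S), the ratio of the observed Shannon index to its maximum
#' for the observed richness S; 1 at perfect evenness. Undefined for a
#' mono-species community (S = 1), reported as `NA`.
#'
#' @inheritParams shannon_diversity
#' @return Equitability J in \[0, 1\], or `NA` when S = 1.
#' @export
equitability <- function(p) {
  p <- check_relabund_vector(p)
  S <- sum(p > 0)
  if (S < 2L) return(NA_real_)
  shannon_diversity(p) / log(S)
}

check_relabund_vector <- function(p) {
  if (!is.numeric(p) || length(p) == 0L) abort("`p` must be a non-empty numeric vector.")
  if (any(!is.finite(p)) || any(p < 0)) abort("`p` must be finite and nonnegative.")
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("`p` must sum to 1 (got %.12g).", sum(p)))
  }
  p
}

#' Per-sample diversity summary
#'
#' Computes richness (number of detected taxa), Shannon diversity and
#' equitability for every sample of an abundance table. Counts are
#' converted to relative abundances per sample first.
#'
#' @param table Samples-by-taxa tibble, first column `sample_id`.
#' @return Tibble with columns `sample_id`, `richness`, `shannon`,
#'   `equitability` (`NA` for mono-species samples).
#' @export
diversity_table <- function(table) {
  rel <- relabund_matrix(abundance_matrix(table))
  tibble::tibble(
    sample_id = rownames(rel),
    richness = as.integer(rowSums(rel > 0)),
    shannon = unname(apply(rel, 1L, shannon_diversity)),
    equitability = unname(apply(rel, 1L, equitability)))
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities d(u, v) =
#' 1 - 2 sum(min(u_i, v_i)) / (sum u + sum v), computed on row-normalized
#' relative abundances, so d is in \[0, 1\] with 0 for identical
#' compositions and 1 for disjoint support. Stored as dissimilarity
#' (1 - similarity) because ordination consumes distances.
#'
#' @param table Samples-by-taxa tibble, first column `sample_id`; every
#'   row must have positive total abundance.
#' @return A symmetric `dist` object labelled with sample ids.
#' @export
bray_curtis <- function(table) {
  rel <- relabund_matrix(abundance_matrix(table))
  vegan::vegdist(rel, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Embeds samples in k dimensions by minimizing Kruskal stress-1 of the
#' monotone-regressed distances (vegan's `monoMDS` engine). One start is
#' metric (principal-coordinate) scaling and the remainder are random;
#' the lowest-stress solution is returned. Deterministic for a fixed
#' `(D, k, seed, n_restarts)`.
#'
#' @param D A `dist` or symmetric numeric matrix of dissimilarities.
#' @param k Embedding dimension, `1 <= k < n`.
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Total number of starts (>= 1).
#' @return A `microsig_nmds` object with elements `points` (tibble
#'   `sample_id`, `NMDS1`, ...), `stress`, `k`, `seed`, `n_restarts`.
#' @export
nmds <- function(D, k = 2, seed = 1, n_restarts = 8) {
  D <- as_dissimilarity(D)
  k <- check_count(k, "k", min = 1L)
  n_restarts <- check_count(n_restarts, "n_restarts", min = 1L)
  n <- attr(D, "Size")
  if (k >= n) abort("`k` must be smaller than the number of samples.")

  fits <- withr::with_seed(seed, {
    y0 <- cmdscale(D, k = k)
    if (is.null(dim(y0)) || ncol(y0) < k) {
      # degenerate PCoA (e.g. tied points); pad with small jitter
      y0 <- cbind(y0, matrix(rnorm(n * (k - ncol(y0)), 0, 1e-4), n))
    }
    lapply(seq_len(n_restarts), function(i) {
      if (i == 1L) {
        vegan::monoMDS(D, y = y0, k = k, model = "global",
                       maxit = 500, smin = 1e-12, sfgrmin = 1e-14)
      } else {
        vegan::monoMDS(D, k = k, model = "global",
                       maxit = 500, smin = 1e-12, sfgrmin = 1e-14)
      }
    })
  })
  best <- fits[[which.min(vapply(fits, function(f) f$stress, numeric(1)))]]
  pts <- best$points
  colnames(pts) <- sprintf("NMDS%d", seq_len(k))
  structure(
    list(points = dplyr::bind_cols(
           tibble::tibble(sample_id = attr(D, "Labels") %||%
                            as.character(seq_len(n))),
           tibble::as_tibble(pts)),
         stress = best$stress, k = k, seed = seed, n_restarts = n_restarts),
    class = "microsig_nmds")
}

as_dissimilarity <- function(D) {
  if (inherits(D, "dist")) {
    if (any(is.na(D))) abort("`D` contains missing values.")
    return(D)
  }
  if (is.matrix(D)) {
    if (any(is.na(D))) abort("`D` contains missing values.")
    if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8)) {
      abort("`D` must be a symmetric square matrix.")
    }
    return(stats::as.dist(D))
  }
  abort("`D` must be a `dist` object or a symmetric matrix.")
}

#' @export
print.microsig_nmds <- function(x, ...) {
  cat(sprintf("<microsig_nmds> %d samples in %d dimensions, stress = %.6g\n",
              nrow(x$points), x$k, x$stress))
  invisible(x)
}

#' @rdname nmds
#' @param x A `microsig_nmds` object.
#' @param ... Unused.
#' @method tidy microsig_nmds
#' @export
tidy.microsig_nmds <- function(x, ...) x$points

#' @rdname nmds
#' @method glance microsig_nmds
#' @export
glance.microsig_nmds <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, n = nrow(x$points),
                 seed = x$seed, n_restarts = x$n_restarts)
}

#' Between-group minus within-group mean dissimilarity
#'
#' A scalar summary of how strongly samples cluster by group in a
#' dissimilarity matrix: the mean dissimilarity of between-group pairs
#' minus that of within-group pairs. Positive values indicate
#' group-specific clustering; 0 is the expectation under no structure.
#'
#' @param D A `dist` or symmetric matrix of dissimilarities.
#' @param labels Tibble with `sample_id`, `group` covering all samples.
#' @return A single number (positive means clustering).
#' @export
cluster_separation <- function(D, labels) {
  D <- as_dissimilarity(D)
  m <- as.matrix(D)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  g <- align_labels(labels, ids)
  if (nlevels(g) < 2L) abort("need at least 2 groups.")
  sizes <- table(g)
  if (any(sizes < 2L)) {
    abort(sprintf("group(s) with fewer than 2 samples: %s",
                  paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  same <- outer(g, g, "==")
  ut <- upper.tri(m)
  mean(m[ut & !same]) - mean(m[ut & same])
}
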