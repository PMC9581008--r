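#' Represent samples as points in peptide space
#'
#' Each sample becomes a point whose coordinates are its intensity values
#' across the selected peptides. Dendrograms use a [select_subset()] list
#' (default `by_both`); k-means and PCA use all peptides.
#'
#' @param table A `synoptic_table` (or `intensity_matrix`).
#' @param peptides Optional character vector of spot/peptide IDs selecting
#'   the coordinate set; `NULL` uses all peptides.
#' @return A numeric matrix, one row per sample (rownames = sample IDs,
#'   ordered control block then treatment block), one column per peptide;
#'   the cohort labels are attached as attribute `"cohort"`.
#' @export
sample_vectors <- function(table, peptides = NULL) {
  samples <- attr(table, "samples")
  stopifnot(!is.null(samples))
  ids <- if (inherits(table, "synoptic_table")) table$spot_id else table$peptide_id
  if (!is.null(peptides)) {
    missing <- setdiff(peptides, ids)
    if (length(missing)) {
      abort(sprintf("Peptide(s) not present in the table: %s.",
                    paste(head(missing, 10L), collapse = ", ")),
            class = "immunosig_validation_error")
    }
    rows <- match(peptides, ids)
  } else rows <- seq_along(ids)
  m <- t(as.matrix(tibble::as_tibble(table)[rows, samples$sample_id]))
  colnames(m) <- ids[rows]
  attr(m, "cohort") <- setNames(samples$cohort, samples$sample_id)
  m
}

new_cluster_result <- function(labels, method, tree = NULL, seed = NULL,
                               centers = NULL, tot_withinss = NULL) {
  structure(list(labels = labels, method = method, tree = tree, seed = seed,
                 centers = centers, tot_withinss = tot_withinss),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> method %s: %d samples in %d cluster(s)\n",
              x$method, length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' Hierarchical clustering of samples (UPGMA)
#'
#' Agglomerative clustering with unweighted average linkage on Euclidean
#' distance. The two-group labels come from cutting the tree at its root
#' bifurcation. Samples are ordered lexicographically by ID before
#' clustering so equal-height merges resolve identically on every platform.
#'
#' @param points Matrix from [sample_vectors()] (rows = samples).
#' @return A `cluster_result` with `labels` (named, in the input row order)
#'   and `tree` (an `hclust` object with non-decreasing merge heights).
#' @export
upgma_tree <- function(points) {
  if (nrow(points) < 2L) {
    abort("UPGMA needs at least 2 samples.", class = "immunosig_validation_error")
  }
  ord <- order(rownames(points))
  hc <- hclust(dist(points[ord, , drop = FALSE], method = "euclidean"),
               method = "average")
  labels <- cutree(hc, k = 2)[rownames(points)]
  new_cluster_result(labels, "upgma_cut", tree = hc)
}

#' k-means clustering of samples with k = 2
#'
#' Lloyd's algorithm with k fixed at 2 (the two-cohort design), 10 seeded
#' random restarts, keeping the solution with the smallest total
#' within-cluster sum of squares. Deterministic given the seed.
#'
#' @param points Matrix from [sample_vectors()].
#' @param seed Integer seed, recorded in the result.
#' @return A `cluster_result` with `labels`, `centers`, `tot_withinss`,
#'   `seed`.
#' @export
kmeans2 <- function(points, seed = 1L) {
  if (nrow(points) < 2L) {
    abort("k-means needs at least 2 samples.", class = "immunosig_validation_error")
  }
  if (nrow(unique(points)) < 2L) {
    warn("Fewer than 2 distinct points; returning a single-cluster result.")
    return(new_cluster_result(setNames(rep(1L, nrow(points)), rownames(points)),
                              "kmeans", seed = seed,
                              centers = points[1, , drop = FALSE],
                              tot_withinss = 0))
  }
  km <- withr::with_seed(seed,
    kmeans(points, centers = 2L, nstart = 10L, algorithm = "Lloyd",
           iter.max = 100L))
  new_cluster_result(setNames(km$cluster, rownames(points)), "kmeans",
                     seed = seed, centers = km$centers,
                     tot_withinss = km$tot.withinss)
}

#' Project samples onto the first two principal axes
#'
#' Mean-centered (unscaled) PCA of the sample points; when the point cloud
#' has rank 1 the second axis is zero-filled.
#'
#' @param points Matrix from [sample_vectors()].
#' @return A tibble with `sample_id`, `cohort`, `pc1`, `pc2`, and the
#'   explained-variance fractions as attribute `"var_explained"`.
#' @export
pca_embed <- function(points) {
  stopifnot(nrow(points) >= 2L)
  pc <- prcomp(points, center = TRUE, scale. = FALSE)
  scores <- pc$x
  pc1 <- scores[, 1]
  pc2 <- if (ncol(scores) >= 2L) scores[, 2] else rep(0, nrow(scores))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  ve2 <- c(ve, 0)[1:2]
  cohort <- attr(points, "cohort")
  out <- tibble::tibble(sample_id = rownames(points),
                        cohort = unname(cohort[rownames(points)]),
                        pc1 = unname(pc1), pc2 = unname(pc2))
  attr(out, "var_explained") <- ve2
  out
}

#' Clustering quality indices
#'
#' Davies-Bouldin, mean Silhouette width (via `cluster::silhouette`), and
#' Calinski-Harabasz, all under the Euclidean metric, for a two-cluster
#' labelling of the sample points. Indices that are undefined for a
#' degenerate clustering (coincident centroids, singleton-only clusters)
#' are reported as `NA` rather than raising.
#'
#' @param points Matrix from [sample_vectors()].
#' @param labels Integer cluster labels, one per row of `points`.
#' @return A one-row tibble: `davies_bouldin`, `silhouette`,
#'   `calinski_harabasz`.
#' @export
quality_indices <- function(points, labels) {
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  stopifnot(length(labels) == nrow(points), k >= 2L)
  n <- nrow(points)
  centroids <- rowsum(points, labels) / as.vector(table(labels))
  grand <- colMeans(points)

  # within-cluster scatter (mean distance to centroid) and separations
  s_i <- vapply(seq_len(k), function(i) {
    pts <- points[labels == i, , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, centroids[i, ])^2)))
  }, 0)
  d_cent <- as.matrix(dist(centroids))
  db <- if (any(d_cent[upper.tri(d_cent)] == 0)) NA_real_ else {
    mean(vapply(seq_len(k), function(i) {
      max(vapply(setdiff(seq_len(k), i),
                 function(j) (s_i[i] + s_i[j]) / d_cent[i, j], 0))
    }, 0))
  }

  sil <- if (all(table(labels) == 1L)) NA_real_ else {
    mean(cluster::silhouette(labels, dist(points))[, "sil_width"])
  }

  wss <- sum(vapply(seq_len(k), function(i) {
    pts <- points[labels == i, , drop = FALSE]
    sum(sweep(pts, 2, centroids[i, ])^2)
  }, 0))
  bss <- sum(as.vector(table(labels)) *
               rowSums(sweep(centroids, 2, grand)^2))
  ch <- if (wss == 0) NA_real_ else (bss / (k - 1)) / (wss / (n - k))

  tibble::tibble(davies_bouldin = db, silhouette = sil, calinski_harabasz = ch)
}

#' @rdname quality_indices
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(sample_id = names(x$labels), cluster = unname(x$labels),
                 method = x$method)
}

#' @rdname quality_indices
#' @param points Matrix of sample points used for `glance()` quality
#'   scoring.
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, points, ...) {
  qi <- quality_indices(points, x$labels)
  dplyr::bind_cols(tibble::tibble(method = x$method), qi)
}
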