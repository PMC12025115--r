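#' Pairwise (weighted) Aitchison distances
#'
#' Builds the full sample-by-sample distance matrix in log-ratio geometry.
#' With `weights = NULL` this is the classic Aitchison distance (Euclidean on
#' CLR); with part weights it is the weighted log-ratio metric. Distances are
#' computed as Euclidean distances of the coordinates
#' `(wclr_j) * sqrt(w_j)`, which is algebraically identical to the pairwise
#' definition and lets `stats::dist` do the work.
#'
#' @inheritParams wclr_transform
#' @return A `stats::dist` object labelled by sample ids.
#' @seealso [ward_linkage()], [aitchison_distance()]
#' @export
pairwise_distances <- function(data, parts = coda_parts(data), weights = NULL) {
  y <- logratio_coords(data, parts, weights)
  stats::dist(y)
}

#' Euclidean embedding of the (weighted) log-ratio metric
#'
#' Coordinates whose ordinary Euclidean distances equal the (weighted)
#' Aitchison distances: weighted CLR scaled column-wise by `sqrt(w_j)`.
#' @inheritParams wclr_transform
#' @return Numeric matrix, rows labelled by sample id.
#' @export
logratio_coords <- function(data, parts = coda_parts(data), weights = NULL) {
  w <- .check_weights(weights, parts)
  z <- if (is.null(weights)) clr_transform(data, parts)
       else wclr_transform(data, parts, weights)
  m <- .part_matrix(z, parts)
  if (!is.null(weights)) m <- sweep(m, 2, sqrt(w), `*`)
  m
}

#' Agglomerative Ward clustering of a distance matrix
#'
#' Ward's minimum-variance agglomeration in its D2 form: the Lance--Williams
#' update acts on squared distances and reported merge heights are their
#' square roots, the convention consistent with a Euclidean (log-ratio)
#' metric. On a metric input the merge heights are non-decreasing. Given the
#' same input order the result is deterministic.
#'
#' @param d A `stats::dist` object (e.g. from [pairwise_distances()]) or a
#'   symmetric matrix with zero diagonal.
#' @return An `hclust` object (merge order, heights, leaf ordering, labels).
#' @export
ward_linkage <- function(d) {
  if (is.matrix(d)) {
    if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0)) {
      abort("Distance matrix must be symmetric with zero diagonal.",
            class = "spicoda_validation_error")
    }
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist")) abort("d must be a dist object or matrix.",
                                  class = "spicoda_validation_error")
  if (attr(d, "Size") < 2) abort("Need at least 2 samples.",
                                 class = "spicoda_validation_error")
  stats::hclust(d, method = "ward.D2")
}

#' Cut a cluster tree into k groups
#'
#' Cuts the merge tree at `k` clusters and relabels the groups `1..k` by
#' decreasing size (ties broken by the earliest member in input order), so
#' labels are reproducible across runs.
#'
#' @param tree An `hclust` object from [ward_linkage()].
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A tibble `sample_id`, `cluster` (factor with levels `1..k`).
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n) {
    abort(paste0("k must be in [1, ", n, "]."),
          class = "spicoda_validation_error")
  }
  raw <- stats::cutree(tree, k = k)
  ids <- names(raw) %||% as.character(seq_len(n))
  sizes <- table(raw)
  first <- tapply(seq_len(n), raw, min)
  ord <- order(-as.integer(sizes), as.integer(first))
  relab <- stats::setNames(seq_len(k), names(sizes)[ord])
  tibble(sample_id = ids,
         cluster = factor(relab[as.character(raw)], levels = seq_len(k)))
}

#' Select the number of clusters
#'
#' Scores each candidate `k` in the same metric the tree was built in:
#' average silhouette width (via `cluster::silhouette` on the distance
#' matrix) or the Calinski--Harabasz pseudo-F on the log-ratio coordinates.
#' This is advisory — for reproducing a published cut, pass `k` explicitly
#' downstream.
#'
#' @param tree An `hclust` object.
#' @param d The `dist` the tree was built from.
#' @param k_range Integer vector of candidate cluster counts, within
#'   `[2, n - 1]`.
#' @param criterion `"silhouette"` (default) or `"calinski"`.
#' @return A `k_selection` object: list with `best_k` (arg-max of the
#'   criterion, smallest k on ties) and `scores` (tibble `k`, `score`).
#' @export
select_k <- function(tree, d, k_range = 2:8,
                     criterion = c("silhouette", "calinski")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(tree, "hclust"), inherits(d, "dist"))
  n <- attr(d, "Size")
  k_range <- as.integer(k_range)
  if (length(k_range) == 0) abort("Empty k_range.",
                                  class = "spicoda_validation_error")
  if (any(k_range < 2 | k_range > n - 1)) {
    abort("k_range must lie within [2, n - 1].",
          class = "spicoda_validation_error")
  }
  if (max(d) == 0) {
    abort("All samples are identical: cluster criteria are undefined.",
          class = "spicoda_validation_error")
  }
  dm <- as.matrix(d)
  scores <- vapply(k_range, function(k) {
    cl <- as.integer(cut_tree(tree, k)$cluster)
    if (criterion == "silhouette") {
      mean(cluster::silhouette(cl, dmatrix = dm)[, "sil_width"])
    } else {
      .calinski_from_dist(dm, cl)
    }
  }, numeric(1))
  if (any(!is.finite(scores))) {
    abort("Criterion undefined for some k (degenerate clustering).",
          class = "spicoda_validation_error")
  }
  structure(list(best_k = k_range[which.max(scores)],
                 criterion = criterion,
                 scores = tibble(k = k_range, score = scores)),
            class = "k_selection")
}

# Calinski-Harabasz from squared distances (valid in any Euclidean embedding):
# within-group SS via the pairwise identity W = sum_g (1/n_g) sum_{i<j in g} d_ij^2.
.calinski_from_dist <- function(dm, cl) {
  n <- nrow(dm)
  k <- length(unique(cl))
  d2 <- dm^2
  tot <- sum(d2[upper.tri(d2)]) / n
  wss <- sum(vapply(unique(cl), function(g) {
    idx <- which(cl == g)
    if (length(idx) < 2) return(0)
    s <- d2[idx, idx, drop = FALSE]
    sum(s[upper.tri(s)]) / length(idx)
  }, numeric(1)))
  bss <- tot - wss
  if (wss <= 0) return(Inf)
  (bss / (k - 1)) / (wss / (n - k))
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Cluster-number selection (", x$criterion, ")\n", sep = "")
  print(x$scores, n = nrow(x$scores))
  cat("Best k:", x$best_k, "\n")
  invisible(x)
}

#' Export a cluster tree as a Newick string
#'
#' Serialises the dendrogram ultrametrically: each leaf sits at depth
#' `height/2` below its parent merge, the convention of `ape`'s
#' `hclust`-to-`phylo` conversion, so a 2-leaf tree merged at height `h`
#' becomes `(A:h/2,B:h/2);`. Parsing the string back (e.g. with
#' `ape::read.tree`) recovers topology and heights.
#'
#' @param tree An `hclust` object.
#' @return A single Newick string (with trailing semicolon).
#' @export
export_dendrogram <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  if (is.null(tree$labels)) tree$labels <- as.character(seq_along(tree$order))
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy)
}
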