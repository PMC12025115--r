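#' Summarize one cluster of compositions
#'
#' Bundles the descriptive statistics reported per cluster: size, the
#' compositional center (percent), total variance (unweighted by default),
#' the variation matrix, and the pairwise ratio table (minimum, geometric
#' mean, maximum of every ordered part ratio). The ratio-table geometric
#' mean for `(i, j)` equals `center_i / center_j` exactly, and the `(j, i)`
#' entry is its elementwise reciprocal with min and max swapped.
#'
#' @inheritParams wclr_transform
#' @param name Cluster name carried into the summary.
#' @param denominator Variance denominator, `"n-1"` or `"n"`.
#' @return A `cluster_summary` object: list with `name`, `n`, `center`
#'   (one-row tibble), `total_variance`, `variation` (matrix), `ratio_table`
#'   (tibble `num`, `den`, `min`, `mean`, `max`).
#' @export
summarize_cluster <- function(data, parts = coda_parts(data), name = "cluster",
                              weights = NULL, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (nrow(data) == 0) abort("Empty cluster.",
                             class = "spicoda_validation_error")
  validate_composition(data, parts, require_positive = TRUE)
  x <- .part_matrix(data, parts)
  lx <- log(x)
  pr <- expand.grid(num = parts, den = parts, stringsAsFactors = FALSE)
  pr <- pr[pr$num != pr$den, ]
  ratio_table <- purrr::pmap_dfr(pr, function(num, den) {
    r <- x[, num] / x[, den]
    tibble(num = num, den = den, min = min(r),
           mean = exp(mean(log(r))), max = max(r))
  })
  structure(list(
    name = name, n = nrow(data),
    center = composition_center(data, parts),
    total_variance = if (nrow(data) >= 2)
      total_variance(data, parts, weights, denominator) else 0,
    variation = if (nrow(data) >= 2)
      variation_matrix(data, parts, denominator) else
      matrix(0, length(parts), length(parts), dimnames = list(parts, parts)),
    ratio_table = ratio_table), class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, digits = 4, ...) {
  cat("Cluster", x$name, "- n =", x$n,
      "- total variance =", signif(x$total_variance, digits), "\n")
  cat("Center (%):\n")
  print(as.data.frame(x$center), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Summarize all clusters of a labelled table
#'
#' @inheritParams summarize_cluster
#' @param cluster Grouping column name or vector, as in [fit_ilr_model()].
#' @return A named list of `cluster_summary` objects, one per cluster level.
#' @export
summarize_clusters <- function(data, cluster = "cluster",
                               parts = coda_parts(data), weights = NULL,
                               denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  g <- if (is.character(cluster) && length(cluster) == 1 &&
           cluster %in% names(data)) data[[cluster]] else cluster
  g <- factor(g)
  out <- lapply(levels(g), function(l) {
    summarize_cluster(data[g == l, , drop = FALSE], parts, name = l,
                      weights = weights, denominator = denominator)
  })
  stats::setNames(out, levels(g))
}

#' Cluster center table (percent scale)
#'
#' One row per cluster, mirroring a published center table: size, center
#' components and total variance.
#' @param summaries A list of `cluster_summary` objects from
#'   [summarize_clusters()].
#' @return A tibble.
#' @export
center_table <- function(summaries) {
  purrr::map_dfr(summaries, function(s) {
    dplyr::bind_cols(tibble(cluster = s$name, n = s$n), s$center,
                     tibble(total_variance = s$total_variance))
  })
}

#' Pairwise ratio summary across clusters
#'
#' The min / geometric-mean / max of every ordered part ratio, per cluster;
#' the twin of a published pairwise-ratio table. "Mean" is the geometric
#' mean of per-sample ratios (exp of the mean log ratio), so it reproduces
#' the ratio of the cluster-center components exactly. Values are full
#' precision; round only for display.
#'
#' @inheritParams summarize_clusters
#' @return A tibble: `cluster`, `num`, `den`, `min`, `mean`, `max`.
#' @export
ratio_summary <- function(data, cluster = "cluster",
                          parts = coda_parts(data)) {
  s <- summarize_clusters(data, cluster, parts)
  purrr::map_dfr(s, function(x) {
    dplyr::bind_cols(tibble(cluster = x$name), x$ratio_table)
  })
}

#' Ternary coordinates for a part pair against the remaining geometric mean
#'
#' Builds the 3-part pseudo-composition `(a, b, g)` with `g` the geometric
#' mean of all remaining parts, closes it, optionally centers the samples by
#' perturbing with the inverse of their own compositional center (so the
#' data's center maps to the barycenter), and projects to 2D barycentric
#' coordinates: vertex `a` at (0,0), `b` at (1,0), `g` at (1/2, sqrt(3)/2).
#'
#' @inheritParams validate_composition
#' @param pair Character vector of 2 distinct part names `(a, b)`.
#' @param centered Center by the compositional mean first? (default `TRUE`).
#' @return A tibble: metadata columns, `a`, `b`, `g` (closed pseudo-parts),
#'   `x`, `y` (plot coordinates), with vertex labels in attribute
#'   `"vertices"`.
#' @export
ternary_coordinates <- function(data, pair, parts = coda_parts(data),
                                centered = TRUE) {
  if (length(pair) != 2 || pair[1] == pair[2] || !all(pair %in% parts)) {
    abort("pair must be 2 distinct part names.",
          class = "spicoda_validation_error")
  }
  if (length(parts) < 3) abort("Need at least 3 parts.",
                               class = "spicoda_validation_error")
  validate_composition(data, parts, require_positive = TRUE)
  x <- .part_matrix(data, parts)
  rest <- setdiff(parts, pair)
  m <- cbind(a = x[, pair[1]],
             b = x[, pair[2]],
             g = exp(rowMeans(log(x[, rest, drop = FALSE]))))
  m <- m / rowSums(m)
  if (centered) {
    ctr <- exp(colMeans(log(m)))
    m <- sweep(m, 2, ctr, `/`)
    m <- m / rowSums(m)
  }
  meta <- data[, setdiff(names(data), parts), drop = FALSE]
  out <- dplyr::bind_cols(meta, as_tibble(m))
  out$x <- m[, "b"] + 0.5 * m[, "g"]
  out$y <- sqrt(3) / 2 * m[, "g"]
  attr(out, "vertices") <- c(a = pair[1], b = pair[2],
                             g = paste0("g(", paste(rest, collapse = ","), ")"))
  out
}

#' Boxplot statistics of pairwise log ratios per cluster
#'
#' Five-number summaries of every `ln(x_i/x_j)` within each cluster:
#' median, quartiles (type-7 linear interpolation), whiskers at the most
#' extreme observations within 1.5 IQR of the quartiles, and outliers.
#'
#' @inheritParams summarize_clusters
#' @return A tibble: `cluster`, `num`, `den`, `ymin`, `lower`, `middle`,
#'   `upper`, `ymax`, `outliers` (list-column).
#' @export
logratio_boxstats <- function(data, cluster = "cluster",
                              parts = coda_parts(data)) {
  g <- if (is.character(cluster) && length(cluster) == 1 &&
           cluster %in% names(data)) data[[cluster]] else cluster
  g <- factor(g)
  lr <- pairwise_logratios(data, parts, ordered = FALSE)
  lr$cluster <- g[match(lr$sample_id, .sample_ids(data))]
  lr |>
    dplyr::group_by(.data$cluster, .data$num, .data$den) |>
    dplyr::summarise(.box = list(.box_stats(.data$logratio)),
                     .groups = "drop") |>
    tidyr::unnest(".box")
}

.box_stats <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- v[v >= lo & v <= hi]
  tibble(ymin = min(inside), lower = q[1], middle = q[2], upper = q[3],
         ymax = max(inside), outliers = list(sort(v[v < lo | v > hi])))
}

#' Log-ratio biplot coordinates (compositional PCA)
#'
#' Singular value decomposition of the column-centered (weighted) log-ratio
#' matrix. Sample scores are principal coordinates `U d / sqrt(n - 1)`, part
#' loadings the right singular vectors; per-axis explained variances
#' `d_k^2 / (n - 1)` sum to the (matching-convention) total variance. Signs
#' are fixed by making each axis's largest-magnitude loading positive, so
#' output is deterministic.
#'
#' @inheritParams wclr_transform
#' @return A `coda_biplot` object: list with `scores` (tibble), `loadings`
#'   (tibble), `explained` (per-axis variance), `prop_explained`.
#' @export
logratio_biplot_coords <- function(data, parts = coda_parts(data),
                                   weights = NULL) {
  if (nrow(data) < 3 || length(parts) < 3) {
    abort("Need at least 3 samples and 3 parts.",
          class = "spicoda_validation_error")
  }
  y <- logratio_coords(data, parts, weights)
  y <- sweep(y, 2, colMeans(y))
  if (max(abs(y)) == 0) abort("Zero-variance data: biplot undefined.",
                              class = "spicoda_validation_error")
  s <- svd(y)
  n <- nrow(y)
  flip <- vapply(seq_len(ncol(s$v)), function(k) {
    sign(s$v[which.max(abs(s$v[, k])), k])
  }, numeric(1))
  flip[flip == 0] <- 1
  u <- sweep(s$u, 2, flip, `*`)
  v <- sweep(s$v, 2, flip, `*`)
  scores <- u %*% diag(s$d, length(s$d)) / sqrt(n - 1)
  expl <- s$d^2 / (n - 1)
  ids <- .sample_ids(data)
  structure(list(
    scores = dplyr::bind_cols(
      tibble(sample_id = ids),
      as_tibble(stats::setNames(as.data.frame(scores[, 1:2]), c("axis1", "axis2")))),
    loadings = dplyr::bind_cols(
      tibble(part = parts),
      as_tibble(stats::setNames(as.data.frame(v[, 1:2]), c("axis1", "axis2")))),
    explained = expl,
    prop_explained = expl / sum(expl)), class = "coda_biplot")
}

#' @export
print.coda_biplot <- function(x, ...) {
  cat("Log-ratio biplot: first two axes explain",
      paste0(round(100 * x$prop_explained[1:2], 1), "%", collapse = " + "),
      "of total variance\n")
  invisible(x)
}
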