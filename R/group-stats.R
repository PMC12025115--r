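#' Fit a multivariate group model in ILR coordinates
#'
#' The linear model "composition ~ group", expressed in orthonormal balance
#' coordinates where ordinary multivariate normal theory applies. Stores the
#' per-group ILR means, the pooled within-group covariance (denominator
#' `n - g`), group sizes and the basis; these are sufficient statistics for
#' the global Wilks test and all pairwise Hotelling tests. The
#' back-transformed group mean (inverse ILR, closed) is exactly the group's
#' compositional center.
#'
#' @inheritParams validate_composition
#' @param cluster Grouping: a column name in `data`, or a vector of length
#'   `nrow(data)`.
#' @param basis Optional `coda_basis`; `NULL` uses the default pivot basis on
#'   `parts`.
#' @return An `ilr_model` object with elements `basis`, `group_means`,
#'   `pooled_cov`, `group_sizes`, `residual_df`, `ilr` (the coordinates),
#'   `groups` (the factor).
#' @export
fit_ilr_model <- function(data, cluster = "cluster",
                          parts = coda_parts(data), basis = NULL) {
  g <- if (is.character(cluster) && length(cluster) == 1 &&
           cluster %in% names(data)) data[[cluster]] else cluster
  if (length(g) != nrow(data)) {
    abort("cluster must name a column or match nrow(data).",
          class = "spicoda_validation_error")
  }
  g <- factor(g)
  if (nlevels(g) < 2) {
    abort("Need at least 2 groups to contrast.",
          class = "spicoda_validation_error")
  }
  if (is.null(basis)) basis <- make_sbp_basis(parts)
  z <- ilr_transform(data, parts, basis)
  y <- as.matrix(z[, paste0("ilr", seq_len(nrow(basis))), drop = FALSE])
  n <- nrow(y); p <- ncol(y); glev <- levels(g)
  sizes <- as.integer(table(g))
  means <- do.call(rbind, lapply(glev, function(l) colMeans(y[g == l, , drop = FALSE])))
  rownames(means) <- glev
  resid <- y - means[as.integer(g), , drop = FALSE]
  df <- n - length(glev)
  if (df < 1) abort("No residual degrees of freedom.",
                    class = "spicoda_validation_error")
  structure(list(basis = basis, group_means = means,
                 pooled_cov = crossprod(resid) / df,
                 group_sizes = stats::setNames(sizes, glev),
                 residual_df = df, ilr = y, groups = g,
                 n = n, p = p),
            class = "ilr_model")
}

#' @export
print.ilr_model <- function(x, ...) {
  cat("ILR group model:", length(x$group_sizes), "groups,",
      x$n, "samples,", x$p, "balance coordinates\n")
  cat("Group sizes:", paste(names(x$group_sizes), x$group_sizes,
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an ILR group model
#'
#' One row per group per balance coordinate, plus the back-transformed
#' compositional center of each group.
#' @param x An `ilr_model`.
#' @param ... Unused.
#' @return A tibble: `group`, `coordinate`, `mean`.
#' @method tidy ilr_model
#' @export
tidy.ilr_model <- function(x, ...) {
  m <- x$group_means
  cn <- colnames(m) %||% paste0("ilr", seq_len(ncol(m)))
  tibble(group = rep(rownames(m), times = ncol(m)),
         coordinate = rep(cn, each = nrow(m)),
         mean = as.vector(m))
}

#' @rdname tidy.ilr_model
#' @return `glance()`: one-row tibble with sample size, group count,
#'   coordinate count and residual df.
#' @method glance ilr_model
#' @export
glance.ilr_model <- function(x, ...) {
  tibble(n = x$n, n_groups = length(x$group_sizes),
         n_coordinates = x$p, residual_df = x$residual_df)
}

#' Group compositional centers from a fitted ILR model
#'
#' @param fit An `ilr_model`.
#' @param kappa Closure constant.
#' @return Tibble with `group` and one column per part.
#' @export
group_centers <- function(fit, kappa = 100) {
  comp <- ilr_inverse(fit$group_means, fit$basis, kappa)
  dplyr::bind_cols(tibble(group = rownames(fit$group_means)), comp)
}

# Moore-Penrose pseudo-inverse via SVD; degenerates gracefully when the
# pooled covariance is singular (e.g. duplicated rows).
.pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 1e-300)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Wilks' lambda and its Rao F approximation for a one-way layout.
.wilks_stat <- function(y, g) {
  g <- factor(g)
  n <- nrow(y); p <- ncol(y); k <- nlevels(g)
  grand <- colMeans(y)
  means <- rowsum(y, g) / as.integer(table(g))
  resid <- y - means[as.integer(g), , drop = FALSE]
  E <- crossprod(resid)
  centered <- y - rep(grand, each = n)
  Tm <- crossprod(centered)
  H <- Tm - E
  lambda <- det(E) / det(E + H)
  list(lambda = lambda, p = p, q = k - 1, v = n - k)
}

.wilks_rao_f <- function(lambda, p, q, v) {
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  t <- v - (p - q + 1) / 2
  df1 <- p * q
  df2 <- t * s - p * q / 2 + 1
  lam_s <- lambda^(1 / s)
  f <- (1 - lam_s) / lam_s * df2 / df1
  p_value <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(statistic = f, df1 = df1, df2 = df2, p_value = p_value)
}

#' Global multivariate test of group differences
#'
#' Tests whether the mean composition differs between groups. Parametric
#' mode: Wilks' lambda for the one-way MANOVA in ILR coordinates with Rao's
#' F approximation. Permutation mode: the same lambda statistic recomputed
#' under random relabelings, `p = (1 + #\{lambda_perm <= lambda_obs\}) /
#' (1 + n_perm)`. Both are invariant to the choice of orthonormal ILR basis
#' (bases differ by a rotation, which leaves lambda unchanged).
#'
#' @param fit An `ilr_model` from [fit_ilr_model()].
#' @param mode `"parametric"` or `"permutation"`.
#' @param n_perm Number of permutations (permutation mode).
#' @param seed Integer seed; mandatory in permutation mode for
#'   reproducibility.
#' @return One-row tibble: `statistic_name`, `statistic` (Wilks lambda),
#'   `f_value`, `df1`, `df2`, `p_value`, `method`, `n_permutations`.
#' @export
global_test <- function(fit, mode = c("parametric", "permutation"),
                        n_perm = 9999, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "ilr_model"))
  if (any(fit$group_sizes < 2)) {
    abort("Groups of size 1 present: use permutation mode on a pooled fit or merge groups.",
          class = "spicoda_validation_error")
  }
  w <- .wilks_stat(fit$ilr, fit$groups)
  rao <- .wilks_rao_f(w$lambda, w$p, w$q, w$v)
  if (mode == "parametric") {
    if (fit$residual_df < fit$p) {
      abort("Too few residual df for the parametric test; use permutation mode.",
            class = "spicoda_validation_error")
    }
    return(tibble(statistic_name = "Wilks lambda", statistic = w$lambda,
                  f_value = rao$statistic, df1 = rao$df1, df2 = rao$df2,
                  p_value = rao$p_value, method = "parametric",
                  n_permutations = NA_integer_))
  }
  if (is.null(seed)) {
    abort("Permutation mode requires an explicit seed.",
          class = "spicoda_validation_error")
  }
  set.seed(seed)
  y <- fit$ilr; g <- fit$groups
  hits <- 0L
  for (b in seq_len(n_perm)) {
    lam <- .wilks_stat(y, g[sample.int(length(g))])$lambda
    if (lam <= w$lambda) hits <- hits + 1L
  }
  tibble(statistic_name = "Wilks lambda", statistic = w$lambda,
         f_value = rao$statistic, df1 = rao$df1, df2 = rao$df2,
         p_value = (1 + hits) / (1 + n_perm), method = "permutation",
         n_permutations = as.integer(n_perm))
}

#' Pairwise multivariate group comparisons
#'
#' Hotelling's T-squared for every pair of groups, using the pooled
#' within-group covariance of the full fit (the multivariate analogue of
#' estimated-marginal-means contrasts). Parametric p-values come from the F
#' transform of T-squared; permutation p-values relabel the two groups'
#' samples. Adjustment for multiplicity is Holm by default.
#'
#' @inheritParams global_test
#' @param adjust `"holm"` (default), `"bonferroni"`, or `"none"`.
#' @return Tibble with one row per pair: `group1`, `group2`, `statistic`
#'   (T-squared), `f_value`, `df1`, `df2`, `p_value`, `p_adjusted`,
#'   `method`, `n_permutations`.
#' @export
pairwise_tests <- function(fit, adjust = c("holm", "bonferroni", "none"),
                           mode = c("parametric", "permutation"),
                           n_perm = 9999, seed = NULL) {
  adjust <- match.arg(adjust)
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "ilr_model"))
  if (mode == "permutation" && is.null(seed)) {
    abort("Permutation mode requires an explicit seed.",
          class = "spicoda_validation_error")
  }
  glev <- names(fit$group_sizes)
  prs <- utils::combn(glev, 2, simplify = FALSE)
  p <- fit$p; v <- fit$residual_df
  Sinv <- .pinv(fit$pooled_cov)
  t2_of <- function(mi, mj, ni, nj, S_inv) {
    dm <- mi - mj
    as.numeric(ni * nj / (ni + nj) * t(dm) %*% S_inv %*% dm)
  }
  if (mode == "permutation") set.seed(seed)
  rows <- purrr::map_dfr(prs, function(pr) {
    i <- pr[1]; j <- pr[2]
    ni <- fit$group_sizes[[i]]; nj <- fit$group_sizes[[j]]
    t2 <- t2_of(fit$group_means[i, ], fit$group_means[j, ], ni, nj, Sinv)
    fdf2 <- v - p + 1
    fval <- t2 * fdf2 / (v * p)
    if (mode == "parametric") {
      if (fdf2 < 1) abort("Too few residual df; use permutation mode.",
                          class = "spicoda_validation_error")
      pv <- stats::pf(fval, p, fdf2, lower.tail = FALSE)
      nperm_out <- NA_integer_
    } else {
      idx <- which(fit$groups %in% c(i, j))
      y <- fit$ilr
      hits <- 0L
      for (b in seq_len(n_perm)) {
        gp <- fit$groups
        gp[idx] <- gp[idx][sample.int(length(idx))]
        gp <- droplevels(gp)
        mp <- rowsum(y, gp) / as.integer(table(gp))
        residp <- y - mp[as.integer(gp), , drop = FALSE]
        Sp <- crossprod(residp) / (nrow(y) - nlevels(gp))
        t2p <- t2_of(mp[i, ], mp[j, ], sum(gp == i), sum(gp == j), .pinv(Sp))
        if (t2p >= t2) hits <- hits + 1L
      }
      pv <- (1 + hits) / (1 + n_perm)
      nperm_out <- as.integer(n_perm)
    }
    tibble(group1 = i, group2 = j, statistic = t2,
           f_value = fval, df1 = p, df2 = v - p + 1, p_value = pv,
           method = mode, n_permutations = nperm_out)
  })
  rows$p_adjusted <- stats::p.adjust(rows$p_value, method = adjust)
  rows[, c("group1", "group2", "statistic", "f_value", "df1", "df2",
           "p_value", "p_adjusted", "method", "n_permutations")]
}
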