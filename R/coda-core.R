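#' Centered log-ratio (CLR) transform
#'
#' Maps each composition to `ln(x_j / g(x))`, where `g(x)` is the row
#' geometric mean. CLR rows sum to zero and are invariant to row scaling, so
#' closed and unclosed data give identical output.
#'
#' @inheritParams validate_composition
#' @return A tibble with the metadata columns of `data` and the part columns
#'   replaced by their CLR coordinates.
#' @examples
#' clr_transform(tibble::tibble(a = 50, b = 30, c = 20))
#' @export
clr_transform <- function(data, parts = coda_parts(data)) {
  validate_composition(data, parts, require_positive = TRUE)
  x <- log(.part_matrix(data, parts))
  .set_parts(data, x - rowMeans(x))
}

#' Weighted log-ratio coordinates
#'
#' The weighted analogue of CLR: `ln(x_j) - sum_k w_k ln(x_k)` with positive
#' part weights `w` summing to 1. With uniform weights this reduces to CLR.
#' These are the coordinates underlying the weighted Aitchison metric used
#' for clustering.
#'
#' @inheritParams validate_composition
#' @param weights Named numeric vector of positive part weights summing to 1,
#'   or `NULL` for uniform weights. See [part_weights()].
#' @return A tibble like [clr_transform()].
#' @export
wclr_transform <- function(data, parts = coda_parts(data), weights = NULL) {
  validate_composition(data, parts, require_positive = TRUE)
  w <- .check_weights(weights, parts)
  x <- log(.part_matrix(data, parts))
  .set_parts(data, x - drop(x %*% w))
}

.check_weights <- function(weights, parts) {
  if (is.null(weights)) return(rep(1 / length(parts), length(parts)))
  if (is.null(names(weights)) && length(weights) == length(parts)) {
    names(weights) <- parts
  }
  if (!all(parts %in% names(weights))) {
    abort("weights must be named by the parts.",
          class = "spicoda_validation_error")
  }
  w <- as.numeric(weights[parts])
  if (any(w <= 0)) abort("weights must be positive.",
                         class = "spicoda_validation_error")
  if (abs(sum(w) - 1) > 1e-8) {
    abort("weights must sum to 1.", class = "spicoda_validation_error")
  }
  w / sum(w)
}

#' Column-mean part weights
#'
#' The default weights of the weighted log-ratio metric: each part's mean
#' proportion over the analysed table. Abundant parts (O, Ca) thus weigh more
#' than trace parts, which damps the influence of noisy low-abundance ratios.
#'
#' @inheritParams validate_composition
#' @return Named numeric vector of positive weights summing to 1.
#' @export
part_weights <- function(data, parts = coda_parts(data)) {
  validate_composition(data, parts)
  x <- .part_matrix(data, parts)
  p <- x / rowSums(x)
  w <- colMeans(p)
  w / sum(w)
}

#' Build an orthonormal ILR balance basis from a sequential binary partition
#'
#' A sequential binary partition (SBP) recursively splits the parts into a
#' numerator and a denominator group; each split yields one balance
#' coordinate. The rows of the returned contrast matrix are orthonormal and
#' sum to zero (they live in the CLR plane). The default partition is the
#' pivot sequence: part 1 vs the rest, part 2 vs the remaining rest, and so
#' on.
#'
#' @param parts Ordered character vector of part names (length `D`).
#' @param partition Optional list of `D - 1` numeric vectors of length `D`
#'   with entries +1 (numerator), -1 (denominator), 0 (absent), encoding a
#'   valid full binary splitting. `NULL` for the pivot sequence.
#' @return A `coda_basis` object: the `(D-1) x D` contrast matrix with
#'   `parts` and `partition` attributes.
#' @examples
#' make_sbp_basis(c("Ca", "Mg", "O", "C", "Traces"))
#' @export
make_sbp_basis <- function(parts, partition = NULL) {
  D <- length(parts)
  if (D < 2) abort("Need at least 2 parts.", class = "spicoda_validation_error")
  if (is.null(partition)) {
    partition <- lapply(seq_len(D - 1), function(i) {
      s <- numeric(D)
      s[i] <- 1
      s[(i + 1):D] <- -1
      s
    })
  }
  if (length(partition) != D - 1 ||
      !all(vapply(partition, length, 0L) == D)) {
    abort("partition must be a list of D-1 sign vectors of length D.",
          class = "spicoda_validation_error")
  }
  basis <- matrix(0, D - 1, D, dimnames = list(NULL, parts))
  for (i in seq_len(D - 1)) {
    s <- partition[[i]]
    if (!all(s %in% c(-1, 0, 1)) || !any(s > 0) || !any(s < 0)) {
      abort("Each split needs a +1 group and a -1 group.",
            class = "spicoda_validation_error")
    }
    r <- sum(s > 0); q <- sum(s < 0)
    basis[i, s > 0] <- sqrt(q / (r * (r + q)))
    basis[i, s < 0] <- -sqrt(r / (q * (r + q)))
  }
  G <- basis %*% t(basis)
  if (max(abs(G - diag(D - 1))) > 1e-10) {
    abort("partition does not define an orthonormal basis (not a valid SBP).",
          class = "spicoda_validation_error")
  }
  structure(basis, parts = parts, partition = partition,
            class = c("coda_basis", "matrix", "array"))
}

#' @export
print.coda_basis <- function(x, ...) {
  cat("ILR balance basis for parts:",
      paste(attr(x, "parts"), collapse = ", "), "\n")
  print(unclass(x)[, , drop = FALSE], digits = 4)
  invisible(x)
}

#' Isometric log-ratio (ILR) transform
#'
#' Projects the CLR coordinates onto the orthonormal balance basis:
#' `ilr = clr %*% t(basis)`. Euclidean distances between ILR rows equal the
#' (unweighted) Aitchison distances between the samples, which makes ILR the
#' natural coordinate system for multivariate linear models on compositions.
#'
#' @inheritParams validate_composition
#' @param basis A `coda_basis` from [make_sbp_basis()] whose parts match
#'   `parts` in order; `NULL` builds the default pivot basis.
#' @return A tibble with the metadata columns of `data` plus columns
#'   `ilr1 ... ilr(D-1)`.
#' @export
ilr_transform <- function(data, parts = coda_parts(data), basis = NULL) {
  if (is.null(basis)) basis <- make_sbp_basis(parts)
  if (!identical(attr(basis, "parts"), parts)) {
    abort("Basis parts do not match table parts (order matters).",
          class = "spicoda_validation_error")
  }
  clr <- clr_transform(data, parts)
  z <- .part_matrix(clr, parts) %*% t(unclass(basis))
  colnames(z) <- paste0("ilr", seq_len(ncol(z)))
  meta <- data[, setdiff(names(data), parts), drop = FALSE]
  out <- dplyr::bind_cols(meta, as_tibble(z))
  attr(out, "basis") <- basis
  out
}

#' Invert ILR coordinates back to closed compositions
#'
#' @param coords Matrix or data frame of ILR coordinates (columns
#'   `ilr1 ...` or any `D - 1` numeric columns in basis order).
#' @param basis The `coda_basis` used for the forward transform.
#' @param kappa Closure constant of the output.
#' @return A tibble of closed compositions with the basis part names.
#' @export
ilr_inverse <- function(coords, basis, kappa = 100) {
  parts <- attr(basis, "parts")
  z <- as.matrix(as.data.frame(coords)[, seq_len(nrow(basis)), drop = FALSE])
  x <- exp(z %*% unclass(basis))
  x <- x * (kappa / rowSums(x))
  colnames(x) <- parts
  as_tibble(x)
}

#' All pairwise log ratios
#'
#' For every ordered pair of parts `(i, j)` returns `ln(x_i / x_j)`. The
#' table is antisymmetric in the pair order and, by subcompositional
#' coherence, any single ratio is unchanged by amalgamating or dropping
#' *other* parts.
#'
#' @inheritParams validate_composition
#' @param ordered If `FALSE`, only the pairs with `i < j` (upper triangle).
#' @return A long tibble: `sample_id`, `num`, `den`, `logratio`.
#' @export
pairwise_logratios <- function(data, parts = coda_parts(data), ordered = TRUE) {
  validate_composition(data, parts, require_positive = TRUE)
  x <- log(.part_matrix(data, parts))
  ids <- .sample_ids(data)
  pr <- expand.grid(num = parts, den = parts, stringsAsFactors = FALSE)
  pr <- pr[pr$num != pr$den, ]
  if (!ordered) {
    pr <- pr[match(pr$num, parts) < match(pr$den, parts), ]
  }
  purrr::pmap_dfr(pr, function(num, den) {
    v <- unname(x[, num] - x[, den])
    tibble(sample_id = ids, num = num, den = den, logratio = v)
  })
}

#' Compositional center (closed geometric means)
#'
#' The compositional analogue of the mean: part-wise geometric means over
#' samples, closed to `kappa`. Ratios of center components equal geometric
#' means of the per-sample ratios, which is why printed cluster-center ratios
#' reproduce the "mean ratio" entries of pairwise ratio tables exactly.
#'
#' @inheritParams validate_composition
#' @param kappa Closure constant (100 for percent).
#' @return A one-row tibble with one column per part.
#' @export
composition_center <- function(data, parts = coda_parts(data), kappa = 100) {
  validate_composition(data, parts, require_positive = TRUE)
  g <- exp(colMeans(log(.part_matrix(data, parts))))
  as_tibble(as.list(g * (kappa / sum(g))))
}

#' Variation matrix
#'
#' Entry `(i, j)` is the variance over samples of `ln(x_i / x_j)`: zero on
#' the diagonal, symmetric, and near-zero entries flag parts that are almost
#' proportional across samples.
#'
#' @inheritParams validate_composition
#' @param denominator `"n-1"` (sample variance, default) or `"n"`.
#' @return A symmetric `D x D` matrix with part dimnames.
#' @export
variation_matrix <- function(data, parts = coda_parts(data),
                             denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  validate_composition(data, parts, require_positive = TRUE)
  x <- log(.part_matrix(data, parts))
  n <- nrow(x)
  if (n < 2) abort("Need at least 2 samples.",
                   class = "spicoda_validation_error")
  D <- length(parts)
  v <- matrix(0, D, D, dimnames = list(parts, parts))
  for (i in seq_len(D - 1)) {
    for (j in (i + 1):D) {
      v[i, j] <- v[j, i] <- stats::var(x[, i] - x[, j])
    }
  }
  if (denominator == "n") v <- v * (n - 1) / n
  v
}

#' Total (metric) variance
#'
#' A single-number spread measure for compositions. Unweighted, it is the
#' sum over parts of the variances of the CLR coordinates, identically equal
#' to `1/(2D)` times the sum of the variation matrix. Weighted, it is
#' `sum_j w_j var(wclr_j)` with the weighted log-ratio coordinates.
#'
#' @inheritParams wclr_transform
#' @param denominator `"n-1"` (default) or `"n"` variance denominator.
#' @return Non-negative scalar.
#' @export
total_variance <- function(data, parts = coda_parts(data), weights = NULL,
                           denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (nrow(data) < 2) abort("Need at least 2 samples.",
                            class = "spicoda_validation_error")
  z <- if (is.null(weights)) {
    clr_transform(data, parts)
  } else {
    wclr_transform(data, parts, weights)
  }
  w <- .check_weights(weights, parts)
  m <- .part_matrix(z, parts)
  v <- apply(m, 2, stats::var)
  if (denominator == "n") v <- v * (nrow(m) - 1) / nrow(m)
  if (is.null(weights)) sum(v) else sum(w * v)
}

#' Aitchison distance between two compositions
#'
#' Unweighted: the Euclidean norm of the difference of CLR vectors — the
#' natural metric of the simplex (scale-invariant, perturbation-invariant,
#' subcompositionally dominant). Weighted: the `w`-weighted Euclidean norm of
#' the difference of weighted log-ratio coordinates.
#'
#' @param x,y Numeric vectors of positive parts (same parts, same order), or
#'   one-row data frames.
#' @param weights Optional named weights as in [wclr_transform()].
#' @return Non-negative scalar distance.
#' @examples
#' aitchison_distance(c(50, 50), c(25, 75))  # log(3)/sqrt(2)
#' @export
aitchison_distance <- function(x, y, weights = NULL) {
  x <- .as_comp_vector(x)
  y <- .as_comp_vector(y)
  if (length(x) != length(y)) {
    abort("x and y must have the same parts.",
          class = "spicoda_validation_error")
  }
  if (!is.null(names(x)) && !is.null(names(y)) &&
      !identical(names(x), names(y))) {
    abort("x and y part names differ.", class = "spicoda_validation_error")
  }
  if (any(x <= 0) || any(y <= 0)) {
    abort("Compositions must be strictly positive.",
          class = "spicoda_validation_error")
  }
  parts <- names(x) %||% paste0("p", seq_along(x))
  w <- .check_weights(weights, parts)
  lx <- log(x); ly <- log(y)
  dx <- (lx - sum(w * lx)) - (ly - sum(w * ly))
  if (is.null(weights)) {
    sqrt(sum(dx^2))
  } else {
    sqrt(sum(w * dx^2))
  }
}

.as_comp_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- unlist(x[, vapply(x, is.numeric, logical(1)), drop = FALSE])
  }
  stopifnot(is.numeric(x))
  x
}
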