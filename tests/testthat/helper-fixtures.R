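# Shared fixtures: all built in code, no files on disk.

# A 7-element spicule-style table on the percent scale.
make_raw_table <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    specimen = "Om1",
    prep = "section",
    C = c(10, 12, 9), O = c(60, 58, 62), Ca = c(25, 24, 24.5),
    Mg = c(3, 3.5, 2.5), Cl = c(1, 1.2, 1), F = c(0.5, 0.8, 0.6),
    P = c(0.5, 0.5, 0.4))
}

elem_parts <- c("C", "O", "Ca", "Mg", "Cl", "F", "P")

# Random strictly positive composition table, closed to 100.
random_table <- function(n, D, seed) {
  set.seed(seed)
  x <- matrix(exp(stats::rnorm(n * D, 0, 1)), n, D)
  x <- x / rowSums(x) * 100
  colnames(x) <- paste0("p", seq_len(D))
  dplyr::bind_cols(tibble::tibble(sample_id = sprintf("r%02d", seq_len(n))),
                   tibble::as_tibble(as.data.frame(x)))
}

# Brute-force minimum-ESS-increase agglomeration on coordinates; the
# independent oracle for Ward.D2 (heights are sqrt(2 * deltaESS)).
ess_agglomerate <- function(y) {
  groups <- as.list(seq_len(nrow(y)))
  heights <- numeric(0)
  partitions <- list()
  while (length(groups) > 1) {
    best <- NULL; best_cost <- Inf
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        a <- groups[[i]]; b <- groups[[j]]
        ca <- colMeans(y[a, , drop = FALSE])
        cb <- colMeans(y[b, , drop = FALSE])
        cost <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
    }
    heights <- c(heights, sqrt(2 * best_cost))
    groups[[best[1]]] <- sort(c(groups[[best[1]]], groups[[best[2]]]))
    groups[[best[2]]] <- NULL
    partitions[[length(partitions) + 1]] <- lapply(groups, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Partition of 1..n induced by cutting an hclust tree, as a sorted list of
# sorted member sets (label-free comparison).
canonical_partition <- function(cl) {
  sets <- unname(lapply(split(seq_along(cl), cl), sort))
  sets[order(vapply(sets, min, 0L))]
}

# Independent type-7 quantile: h = (n-1)p + 1 with linear interpolation.
quantile7_oracle <- function(v, p) {
  v <- sort(v); n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
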