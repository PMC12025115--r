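test_that("CLR matches the direct log-geometric-mean formula and its invariances", {
  d <- tibble::tibble(a = 50, b = 30, c = 20)
  z <- clr_transform(d)
  g <- prod(c(50, 30, 20))^(1 / 3)
  expect_equal(unlist(z), c(a = log(50 / g), b = log(30 / g), c = log(20 / g)),
               tolerance = 1e-12)
  expect_equal(unlist(z), c(a = 0.4757, b = -0.0351, c = -0.4406),
               tolerance = 1e-4)
  expect_equal(sum(z), 0, tolerance = 1e-12)
  # uniform composition maps to the origin
  expect_equal(unlist(clr_transform(tibble::tibble(a = 25, b = 25, c = 25, d = 25))),
               c(a = 0, b = 0, c = 0, d = 0))
  # scale invariance: multiplying a raw row by 7 changes nothing
  expect_equal(clr_transform(tibble::tibble(a = 350, b = 210, c = 140)), z)
  # non-positive input names the sample and part
  expect_error(clr_transform(tibble::tibble(sample_id = "x", a = 0, b = 1)),
               "a.*x|x.*a", class = "spicoda_validation_error")
})

test_that("SBP basis rows are orthonormal, zero-sum, and match closed forms", {
  b2 <- make_sbp_basis(c("a", "b"))
  expect_equal(b2[1, ], c(a = 1, b = -1) / sqrt(2))
  b3 <- make_sbp_basis(c("a", "b", "c"))
  expect_equal(b3[1, ], c(a = sqrt(2 / 3), b = -1 / sqrt(6), c = -1 / sqrt(6)))
  expect_equal(b3[2, ], c(a = 0, b = 1 / sqrt(2), c = -1 / sqrt(2)))
  # invariants hold for an arbitrary non-pivot partition
  part <- list(c(1, 1, -1, -1), c(1, -1, 0, 0), c(0, 0, 1, -1))
  b4 <- make_sbp_basis(letters[1:4], part)
  expect_equal(unclass(b4) %*% t(unclass(b4)), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(rowSums(b4), rep(0, 3), tolerance = 1e-10)
  # malformed partitions rejected
  expect_error(make_sbp_basis(letters[1:3], list(c(1, 1, 1), c(0, 1, -1))),
               class = "spicoda_validation_error")
  expect_error(make_sbp_basis(letters[1:4],
                              list(c(1, -1, 0, 0), c(0, 0, 1, -1),
                                   c(1, -1, 1, -1))),
               class = "spicoda_validation_error")
})

test_that("ILR closed form, uniform zero, and isometry with Aitchison distance", {
  z <- ilr_transform(tibble::tibble(a = 75, b = 25))
  expect_equal(z$ilr1, log(3) / sqrt(2), tolerance = 1e-12)
  expect_equal(unlist(ilr_transform(tibble::tibble(a = 20, b = 20, c = 20))[,
                                    c("ilr1", "ilr2")]),
               c(ilr1 = 0, ilr2 = 0), tolerance = 1e-12)
  # isometry: ||ilr(x) - ilr(y)|| = unweighted Aitchison distance, D <= 8
  for (D in c(3, 5, 8)) {
    tab <- random_table(10, D, seed = 100 + D)
    parts <- coda_parts(tab)
    z <- as.matrix(ilr_transform(tab, parts)[, paste0("ilr", 1:(D - 1))])
    for (i in c(1, 4)) {
      for (j in c(2, 9)) {
        expect_equal(sqrt(sum((z[i, ] - z[j, ])^2)),
                     aitchison_distance(unlist(tab[i, parts]),
                                        unlist(tab[j, parts])),
                     tolerance = 1e-10)
      }
    }
  }
  # mismatched basis rejected
  b <- make_sbp_basis(c("x", "y"))
  expect_error(ilr_transform(tibble::tibble(a = 1, b = 2), basis = b),
               class = "spicoda_validation_error")
})

test_that("pairwise log ratios are antisymmetric and subcompositionally coherent", {
  lr <- pairwise_logratios(tibble::tibble(sample_id = "s", a = 50, b = 25))
  expect_equal(lr$logratio[lr$num == "a" & lr$den == "b"], log(2))
  expect_equal(lr$logratio[lr$num == "b" & lr$den == "a"], -log(2))
  # constant composition: all ratios zero
  lr0 <- pairwise_logratios(tibble::tibble(a = 7, b = 7, c = 7))
  expect_equal(lr0$logratio, rep(0, 6))
  # ratio of two parts unchanged by amalgamating other parts
  tab <- make_raw_table()
  before <- pairwise_logratios(tab, elem_parts)
  after <- pairwise_logratios(amalgamate(tab, c("Cl", "F", "P")))
  pick <- function(x) x$logratio[x$num == "Ca" & x$den == "Mg"]
  expect_equal(pick(after), pick(before), tolerance = 1e-12)
})

test_that("compositional center is the closed geometric mean with the ratio identity", {
  d <- tibble::tibble(a = c(40, 10), b = c(40, 60), c = c(20, 30))
  ctr <- composition_center(d)
  g <- c(sqrt(40 * 10), sqrt(40 * 60), sqrt(20 * 30))
  expect_equal(unlist(ctr), setNames(g / sum(g) * 100, c("a", "b", "c")),
               tolerance = 1e-12)
  expect_equal(unlist(ctr), c(a = 21.40, b = 52.41, c = 26.20),
               tolerance = 1e-3)
  # single sample: its own closure
  expect_equal(unlist(composition_center(tibble::tibble(a = 2, b = 6))),
               c(a = 25, b = 75))
  # center-ratio identity: center_i/center_j = exp(mean log ratio), all pairs
  tab <- random_table(15, 5, seed = 7)
  parts <- coda_parts(tab)
  ctr <- unlist(composition_center(tab, parts))
  lx <- log(as.matrix(tab[, parts]))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(ctr[i] / ctr[j], exp(mean(lx[, i] - lx[, j])),
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("variation matrix matches hand computation and flags constant ratios", {
  d <- tibble::tibble(a = c(30, 30), b = c(30, 90))
  v <- variation_matrix(d)
  expect_equal(v["a", "b"], stats::var(c(0, log(1 / 3))))
  expect_equal(v["a", "b"], 0.6035, tolerance = 1e-4)
  expect_true(isSymmetric(v))
  expect_equal(diag(v), c(a = 0, b = 0))
  # n denominator option
  vn <- variation_matrix(d, denominator = "n")
  expect_equal(vn["a", "b"], v["a", "b"] / 2)
  # identical samples: all zero; constant ratio: exact zero entry
  same <- tibble::tibble(a = c(10, 10, 10), b = c(20, 20, 20), c = c(5, 5, 5))
  expect_equal(variation_matrix(same), matrix(0, 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  cr <- tibble::tibble(a = c(10, 20, 5), b = c(20, 40, 10), c = c(5, 9, 30))
  # a/b is constant across samples; the entry vanishes to rounding error
  expect_lt(abs(variation_matrix(cr)["a", "b"]), 1e-30)
  expect_error(variation_matrix(tibble::tibble(a = 1, b = 2)),
               class = "spicoda_validation_error")
})

test_that("total variance obeys the 1/(2D) variation-matrix sum rule", {
  same <- tibble::tibble(a = c(10, 10), b = c(20, 20))
  expect_equal(total_variance(same), 0)
  for (seed in 1:5) {
    tab <- random_table(12, 4 + seed %% 3, seed = seed)
    parts <- coda_parts(tab)
    D <- length(parts)
    expect_equal(total_variance(tab, parts),
                 sum(variation_matrix(tab, parts)) / (2 * D),
                 tolerance = 1e-10)
  }
  # with uniform explicit weights the weighted form reduces to (1/D) * unweighted
  tab <- random_table(10, 5, seed = 9)
  parts <- coda_parts(tab)
  w <- setNames(rep(0.2, 5), parts)
  expect_equal(total_variance(tab, parts, weights = w),
               total_variance(tab, parts) / 5, tolerance = 1e-10)
})

test_that("Aitchison distance closed form, axioms, and invariances", {
  expect_equal(aitchison_distance(c(50, 50), c(25, 75)), log(3) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(aitchison_distance(c(10, 20, 70), c(10, 20, 70)), 0)
  set.seed(21)
  for (r in 1:10) {
    x <- exp(rnorm(5)); y <- exp(rnorm(5)); p <- exp(rnorm(5))
    # perturbation invariance
    expect_equal(aitchison_distance(p * x, p * y), aitchison_distance(x, y),
                 tolerance = 1e-10)
    # triangle inequality
    z <- exp(rnorm(5))
    expect_lte(aitchison_distance(x, y),
               aitchison_distance(x, z) + aitchison_distance(z, y) + 1e-12)
    # subcompositional dominance: dropping parts never increases distance
    expect_lte(aitchison_distance(x[1:3], y[1:3]),
               aitchison_distance(x, y) + 1e-12)
  }
  # weighted metric with column-mean weights is still a metric and
  # symmetric
  tab <- random_table(2, 4, seed = 3)
  parts <- coda_parts(tab)
  w <- part_weights(tab, parts)
  dxy <- aitchison_distance(unlist(tab[1, parts]), unlist(tab[2, parts]), w)
  dyx <- aitchison_distance(unlist(tab[2, parts]), unlist(tab[1, parts]), w)
  expect_equal(dxy, dyx)
  expect_gt(dxy, 0)
  expect_error(aitchison_distance(c(1, 2), c(1, 2, 3)),
               class = "spicoda_validation_error")
})

test_that("part weights are the column mean proportions, positive, summing to 1", {
  tab <- random_table(20, 5, seed = 12)
  parts <- coda_parts(tab)
  w <- part_weights(tab, parts)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
  m <- as.matrix(tab[, parts])
  expect_equal(unname(w), unname(colMeans(m / rowSums(m))), tolerance = 1e-12)
})
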