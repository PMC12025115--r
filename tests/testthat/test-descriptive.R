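test_that("cluster summary components cohere: center, ratios, reciprocals", {
  tab <- random_table(12, 5, seed = 14)
  parts <- coda_parts(tab)
  s <- summarize_cluster(tab, parts, name = "test")
  expect_equal(s$n, 12)
  expect_equal(sum(s$center), 100, tolerance = 1e-9)
  # ratio-table geometric mean equals the center component ratio, all pairs
  ctr <- unlist(s$center)
  for (r in seq_len(nrow(s$ratio_table))) {
    expect_equal(s$ratio_table$mean[r],
                 unname(ctr[s$ratio_table$num[r]] / ctr[s$ratio_table$den[r]]),
                 tolerance = 1e-9)
  }
  # reciprocal consistency with min/max swapped
  ab <- s$ratio_table[s$ratio_table$num == "p1" & s$ratio_table$den == "p2", ]
  ba <- s$ratio_table[s$ratio_table$num == "p2" & s$ratio_table$den == "p1", ]
  expect_equal(ba$mean, 1 / ab$mean, tolerance = 1e-12)
  expect_equal(ba$min, 1 / ab$max, tolerance = 1e-12)
  expect_equal(ba$max, 1 / ab$min, tolerance = 1e-12)
  # identical rows: zero variance, degenerate ratios
  same <- tibble::tibble(a = rep(12, 4), b = rep(48, 4), c = rep(40, 4))
  s0 <- summarize_cluster(same, c("a", "b", "c"))
  expect_equal(s0$total_variance, 0)
  expect_equal(s0$ratio_table$min, s0$ratio_table$max)
  expect_equal(s0$ratio_table$min, s0$ratio_table$mean)
  expect_error(summarize_cluster(same[0, ], c("a", "b", "c")),
               class = "spicoda_validation_error")
})

test_that("a cluster generated at a published center recovers it closely", {
  spec <- section_cluster_specs()[[2]]  # n = 41, tv 0.2553
  sim <- generate_clusters(list(spec), seed = 20240201)
  parts <- names(spec$center)
  s <- summarize_cluster(sim, parts, name = spec$name)
  expect_true(all(abs(unlist(s$center) - spec$center) < 1.5))
  expect_lt(abs(s$total_variance - spec$total_variance), 0.08)
})

test_that("ratio summary uses geometric means across clusters", {
  tab <- tibble::tibble(sample_id = c("u", "v"),
                        a = c(20, 80), b = c(10, 10), c = c(70, 10),
                        cluster = "one")
  rs <- ratio_summary(tab, "cluster", c("a", "b", "c"))
  row <- rs[rs$num == "a" & rs$den == "b", ]
  expect_equal(row$min, 2)
  expect_equal(row$mean, sqrt(2 * 8))  # geometric mean of {2, 8}
  expect_equal(row$max, 8)
  # single sample: min = mean = max
  one <- ratio_summary(tab[1, ], "cluster", c("a", "b", "c"))
  expect_equal(one$min, one$max)
  expect_equal(one$min, one$mean)
})

test_that("ternary coordinates map the simplex to the reference triangle", {
  # a = b = g lands on the barycenter
  tab <- tibble::tibble(a = 20, b = 20, c = 20, d = 20)
  tc <- ternary_coordinates(tab, c("a", "b"), centered = FALSE)
  expect_equal(tc$x, 0.5, tolerance = 1e-12)
  expect_equal(tc$y, sqrt(3) / 6, tolerance = 1e-12)
  # (50, 25, 25) against the independent barycentric formula
  tab2 <- tibble::tibble(a = 50, b = 25, c = 25)
  tc2 <- ternary_coordinates(tab2, c("a", "b"), centered = FALSE)
  a <- 50; b <- 25; g <- 25
  expect_equal(tc2$x, 0.5 * (2 * b + g) / (a + b + g), tolerance = 1e-12)
  expect_equal(tc2$y, sqrt(3) / 2 * g / (a + b + g), tolerance = 1e-12)
  # centering maps the data's own center to the barycenter
  tab3 <- random_table(9, 5, seed = 15)
  tc3 <- ternary_coordinates(tab3, c("p1", "p2"), centered = TRUE)
  m <- as.matrix(tc3[, c("a", "b", "g")])
  ctr <- exp(colMeans(log(m)))
  ctr <- ctr / sum(ctr)
  expect_equal(unname(ctr), rep(1 / 3, 3), tolerance = 1e-10)
  expect_error(ternary_coordinates(tab3, c("p1", "p1")),
               class = "spicoda_validation_error")
  expect_error(ternary_coordinates(tibble::tibble(a = 1, b = 2), c("a", "b")),
               class = "spicoda_validation_error")
})

test_that("log-ratio box statistics match the type-7 order-statistics oracle", {
  # symmetric 5-point set: median is the middle value, no outliers
  tab <- tibble::tibble(sample_id = paste0("s", 1:5),
                        a = c(10, 20, 30, 40, 50), b = rep(10, 5),
                        cluster = "k")
  bs <- logratio_boxstats(tab, "cluster", c("a", "b"))
  row <- bs[bs$num == "a" & bs$den == "b", ]
  expect_equal(row$middle, log(3))
  expect_equal(length(row$outliers[[1]]), 0)
  # all-equal ratios give a zero-width box
  same <- tibble::tibble(a = c(10, 20), b = c(10, 20), cluster = "k")
  bs0 <- logratio_boxstats(same, "cluster", c("a", "b"))
  expect_equal(bs0$lower, bs0$upper)
  # random data against the independent quantile oracle
  tab2 <- random_table(23, 3, seed = 16)
  tab2$cluster <- "all"
  bs2 <- logratio_boxstats(tab2, "cluster", coda_parts(tab2))
  v <- log(tab2$p1 / tab2$p2)
  row2 <- bs2[bs2$num == "p1" & bs2$den == "p2", ]
  expect_equal(row2$lower, quantile7_oracle(v, 0.25), tolerance = 1e-12)
  expect_equal(row2$middle, quantile7_oracle(v, 0.5), tolerance = 1e-12)
  expect_equal(row2$upper, quantile7_oracle(v, 0.75), tolerance = 1e-12)
  iqr <- row2$upper - row2$lower
  inside <- v[v >= row2$lower - 1.5 * iqr & v <= row2$upper + 1.5 * iqr]
  expect_equal(row2$ymin, min(inside))
  expect_equal(row2$ymax, max(inside))
  expect_equal(row2$outliers[[1]], sort(v[v < row2$lower - 1.5 * iqr |
                                            v > row2$upper + 1.5 * iqr]))
})

test_that("biplot axes partition the total variance with deterministic signs", {
  # 1-dimensional log-ratio structure: axis 1 explains everything
  t_line <- tibble::tibble(a = c(10, 20, 40), b = c(10, 10, 10),
                           c = c(80, 70, 50))
  t_line <- close_composition(t_line)
  bp <- logratio_biplot_coords(close_composition(
    tibble::tibble(a = exp(c(0, 0.5, 1)), b = 1, c = 1)))
  expect_equal(bp$prop_explained[1], 1, tolerance = 1e-10)
  # explained variances sum to the total variance (matching convention)
  tab <- random_table(14, 5, seed = 17)
  parts <- coda_parts(tab)
  bp2 <- logratio_biplot_coords(tab, parts)
  expect_equal(sum(bp2$explained), total_variance(tab, parts),
               tolerance = 1e-10)
  w <- part_weights(tab, parts)
  bp3 <- logratio_biplot_coords(tab, parts, w)
  expect_equal(sum(bp3$explained), total_variance(tab, parts, w),
               tolerance = 1e-10)
  # sign convention: the largest-magnitude loading on each axis is positive
  for (ax in c("axis1", "axis2")) {
    expect_gt(bp2$loadings[[ax]][which.max(abs(bp2$loadings[[ax]]))], 0)
  }
  # degenerate data refused
  same <- tibble::tibble(a = rep(10, 5), b = rep(20, 5), c = rep(30, 5))
  expect_error(logratio_biplot_coords(same, c("a", "b", "c")),
               class = "spicoda_validation_error")
})
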