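test_that("TFCE transform equals the brute-force integral oracle", {
  adj5 <- chain_adjacency(5)
  tmap <- c(0.53, 2.11, 2.34, 0.92, -1.73)
  expect_equal(tfce_transform(tmap, adj5), tfce_reference(tmap, adj5),
               tolerance = 1e-9)

  # random maps on a chain and on a coordinate graph
  set.seed(21)
  coords <- matrix(rnorm(9 * 3, sd = 10), 9, 3)
  adj9 <- coord_adjacency(coords, 15)
  for (i in 1:5) {
    tm <- rnorm(9, sd = 2)
    expect_equal(tfce_transform(tm, adj9), tfce_reference(tm, adj9),
                 tolerance = 1e-9)
    tm5 <- rnorm(5, sd = 3)
    expect_equal(tfce_transform(tm5, adj5, E = 1, H = 1.5, step = 0.05),
                 tfce_reference(tm5, adj5, E = 1, H = 1.5, step = 0.05),
                 tolerance = 1e-9)
  }
})

test_that("TFCE permutation test: identical conditions, p-rank invariance", {
  set.seed(31)
  a <- matrix(rnorm(10 * 6), 10, 6)
  adj <- chain_adjacency(6)
  same <- tfce_permutation_test(a, a, adj, n_perm = 200, seed = 2)
  expect_true(all(same$p_map == 1))          # observed TFCE is exactly zero
  expect_identical(nrow(same$clusters), 0L)

  # positive monotone rescaling of the data leaves the p-map unchanged
  b <- a + matrix(rnorm(10 * 6, sd = 0.5), 10, 6)
  t1 <- tfce_permutation_test(a, b, adj, n_perm = 300, seed = 5)
  t2 <- tfce_permutation_test(3 * a + 7, 3 * b + 7, adj, n_perm = 300, seed = 5)
  expect_equal(t1$p_map, t2$p_map, tolerance = 1e-12)
  expect_equal(t1$t_map, t2$t_map, tolerance = 1e-9)

  # a strong concentrated effect is detected
  eff <- b + matrix(rnorm(10 * 6, sd = 0.4), 10, 6)
  eff[, 3] <- eff[, 3] + 2
  t3 <- tfce_permutation_test(eff, b, adj, n_perm = 500, seed = 6)
  expect_lt(t3$p_map[3], 0.05)
  expect_gte(nrow(t3$clusters), 1L)
  expect_warning(tfce_permutation_test(a, b, adj, n_perm = 50, seed = 1),
                 "randomizations")
})

test_that("paired test: branch choice, effect sizes, enumeration oracle", {
  # normal differences: dependent-sample t with Cohen's d
  set.seed(41)
  x <- rnorm(20); y <- x - 0.8 + rnorm(20, sd = 0.5)
  pt <- paired_test(x, y)
  expect_identical(pt$method, "paired t")
  expect_identical(pt$effect_type, "cohens_d")
  d <- x - y
  expect_equal(pt$effect_size, mean(d) / sd(d), tolerance = 1e-12)

  # Cohen's d sign matches the sign of mean(a - b)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    res <- paired_test(a, b)
    if (res$effect_type == "cohens_d")
      expect_identical(sign(res$effect_size), sign(mean(a - b)))
  }

  # non-normal differences with all pairs positive: Wilcoxon, r_C = 1
  skewed <- c(0.01, 0.02, 0.03, 0.04, 100)
  pw <- paired_test(skewed, rep(0, 5))
  expect_identical(pw$method, "wilcoxon signed-rank")
  expect_identical(pw$effect_size, 1)

  # exact Wilcoxon p at n = 5 equals enumeration over all 2^5 sign patterns
  expect_equal(pw$p.value, wilcoxon_enum_p(skewed), tolerance = 1e-12)
  mixed <- c(0.5, -0.2, 3.1, 0.9, -40)   # also forces the Wilcoxon branch
  if (shapiro.test(mixed)$p.value < 0.05) {
    pm <- paired_test(mixed, rep(0, 5))
    expect_equal(pm$p.value, wilcoxon_enum_p(mixed), tolerance = 1e-12)
  }

  expect_error(paired_test(rep(1, 6), rep(0, 6)), "degenerate")
  expect_error(paired_test(1:4, 2:5), "5 pairs")
})

test_that("exact Wilcoxon p agrees with the large-sample approximation at n = 25", {
  set.seed(51)
  for (i in 1:5) {
    d <- rexp(25) - 0.7
    v <- sum(rank(abs(d))[d > 0])
    n <- 25
    p_exact <- suppressWarnings(
      wilcox.test(d, exact = TRUE)$p.value)
    z <- (v - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
    p_norm <- 2 * pnorm(-abs(z))
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})
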