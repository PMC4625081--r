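test_that("comparison sets follow the CCA intersection and SVI imputation rules", {
  dims <- c(10L, 1L, 1L)
  mvol <- array(TRUE, dim = dims); mvol[9:10] <- FALSE
  mask <- brain_mask(mvol)
  set.seed(1)
  A <- toy_zmap(rnorm(10), dims)
  B <- apply_threshold(toy_zmap(rnorm(10, sd = 2), dims), 1.5)

  cca <- build_comparison_set(A, B, "cca", mask)
  surviving <- which(!is.na(B$volume[1:8]))
  expect_equal(cca$index, surviving)
  expect_equal(cca$n, length(surviving))
  expect_equal(cca$x, A$volume[surviving])

  svi <- build_comparison_set(A, B, "svi", mask)
  expect_equal(svi$n, 8L) # the whole mask, out-of-mask voxels excluded
  yB <- B$volume[1:8]; yB[is.na(yB)] <- 0
  expect_equal(svi$y, yB)

  # fully empty target
  Bempty <- apply_threshold(B, 100)
  expect_equal(build_comparison_set(A, Bempty, "cca", mask)$n, 0L)
  # CCA drops exact zeros in either image
  A0 <- toy_zmap(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9), dims)
  B0 <- toy_zmap(c(1, 0, 2, 3, 4, 5, 6, 7, 8, 9), dims)
  expect_equal(build_comparison_set(A0, B0, "cca", mask)$n, 6L)
})

test_that("positive-only direction filters both images, including the query", {
  dims <- c(6L, 1L, 1L)
  mask <- full_mask(dims)
  A <- toy_zmap(c(-2, -1, 1, 2, 3, 4), dims)
  B <- toy_zmap(c(3, 2, -1, 1, 2, 3), dims)
  cca <- build_comparison_set(A, B, "cca", mask, direction = "positive")
  # voxels where both are positive: indices 4, 5, 6
  expect_equal(cca$index, 4:6)
  svi <- build_comparison_set(A, B, "svi", mask, direction = "positive")
  expect_equal(svi$x, c(0, 0, 1, 2, 3, 4)) # query negatives imputed to 0
  expect_equal(svi$y, c(3, 2, 0, 1, 2, 3))
})

test_that("pearson and spearman match brute-force oracles, including ties", {
  expect_equal(pearson_score(1:5, 1:5), 1)
  expect_equal(pearson_score(1:5, -(1:5)), -1)
  expect_equal(pearson_score(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               pearson_bf(c(1, 2, 3, 4), c(2, 1, 4, 3)), tolerance = 1e-15)
  expect_equal(pearson_bf(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)

  x <- c(0.3, 1.7, 2.1, 5.5); y <- exp(x)
  expect_equal(spearman_score(x, y), 1)   # strictly monotone increasing
  expect_equal(spearman_score(x, -y), -1) # strictly monotone decreasing
  xt <- c(1, 1, 2, 3); yt <- c(4, 3, 2, 1)
  expect_equal(spearman_score(xt, yt), spearman_bf(xt, yt), tolerance = 1e-12)
  expect_equal(spearman_bf(xt, yt), -4.5 / sqrt(4.5 * 5)) # hand-assigned ranks

  set.seed(33)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_score(x, y), pearson_bf(x, y), tolerance = 1e-12)
    expect_equal(spearman_score(x, y), spearman_bf(x, y), tolerance = 1e-10)
    xi <- sample(0:4, n, replace = TRUE); yi <- sample(0:4, n, replace = TRUE)
    if (sd(xi) > 0 && sd(yi) > 0)
      expect_equal(spearman_score(xi, yi), spearman_bf(xi, yi),
                   tolerance = 1e-10)
  }

  # degenerate-input policy: short or constant vectors are not comparable
  expect_true(is.na(pearson_score(c(1, 2), c(3, 4))))
  expect_true(is.na(pearson_score(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(spearman_score(c(2, 2, 2, 2), c(1, 2, 3, 4))))
})

test_that("compare_maps applies the not-comparable rules and records voxel counts", {
  dims <- c(8L, 1L, 1L)
  mask <- full_mask(dims)
  set.seed(9)
  A <- toy_zmap(rnorm(8), dims)

  # overlap of exactly 2 voxels -> not comparable
  y <- rep(NA_real_, 8); y[c(2, 5)] <- c(1.2, -0.7)
  B2 <- threshsim:::zstat_map(array(y, dim = dims), "c2", "B")
  sc <- compare_maps(A, B2, "cca", "pearson", mask)
  expect_true(is.na(sc$value))
  expect_equal(sc$n_voxels, 2L)

  # fully empty target -> not comparable under both strategies
  Bnone <- threshsim:::zstat_map(array(NA_real_, dim = dims), "c3", "B")
  expect_true(is.na(compare_maps(A, Bnone, "cca", "pearson", mask)$value))
  expect_true(is.na(compare_maps(A, Bnone, "svi", "pearson", mask)$value))

  # self-similarity through a T = 0 / both threshold is exactly 1
  Bself <- apply_threshold(threshsim:::zstat_map(A$volume, "c1", "B"),
                           threshold_spec(0, "both"))
  expect_equal(compare_maps(A, Bself, "cca", "pearson", mask)$value, 1)

  # thresholded queries are rejected
  Athr <- apply_threshold(A, 1)
  expect_error(compare_maps(Athr, B2, "cca", "pearson", mask), "unthresholded")
})

test_that("CCA and SVI match brute-force recomputation and coincide at full survival", {
  set.seed(14)
  dims <- c(6L, 5L, 4L)
  mask <- ellipsoid_mask(dims)
  A <- random_zmap(dims, mask)
  B <- apply_threshold(random_zmap(dims, mask, sd = 1.5), 0.8)

  idx <- which(mask$volume)
  xa <- A$volume[idx]; xb <- B$volume[idx]
  keep <- !is.na(xa) & !is.na(xb) & xa != 0 & xb != 0
  cca_oracle <- pearson_bf(xa[keep], xb[keep])
  xa0 <- ifelse(is.na(xa), 0, xa); xb0 <- ifelse(is.na(xb), 0, xb)
  svi_oracle <- pearson_bf(xa0, xb0)

  cca <- compare_maps(A, B, "cca", "pearson", mask)
  svi <- compare_maps(A, B, "svi", "pearson", mask)
  expect_equal(cca$value, cca_oracle, tolerance = 1e-12)
  expect_equal(svi$value, svi_oracle, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cca$value, svi$value)))
  expect_lte(cca$n_voxels, svi$n_voxels)

  # full survival and nonzero maps: the strategies coincide exactly
  Bfull <- random_zmap(dims, mask)
  c1 <- compare_maps(A, Bfull, "cca", "pearson", mask)
  s1 <- compare_maps(A, Bfull, "svi", "pearson", mask)
  expect_equal(c1$value, s1$value)
  expect_equal(c1$n_voxels, s1$n_voxels)
})

test_that("scores are bounded and invariant under positive affine rescaling", {
  set.seed(77)
  dims <- c(5L, 5L, 3L)
  mask <- full_mask(dims)
  for (i in 1:10) {
    A <- random_zmap(dims)
    B <- apply_threshold(random_zmap(dims, sd = 2), 1)
    for (met in c("pearson", "spearman")) {
      v <- compare_maps(A, B, "cca", met, mask)$value
      if (!is.na(v)) expect_lte(abs(v), 1)
      A2 <- threshsim:::zstat_map(3.7 * A$volume + 0.4, "c1", "A")
      v2 <- compare_maps(A2, B, "cca", met, mask)$value
      expect_equal(v2, v, tolerance = 1e-10)
    }
  }
  # CCA voxel count is non-increasing in the threshold level
  A <- random_zmap(dims)
  Z <- random_zmap(dims, sd = 2)
  n_prev <- Inf
  for (T in 0:4) {
    n <- compare_maps(A, apply_threshold(Z, T), "cca", "pearson", mask)$n_voxels
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
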