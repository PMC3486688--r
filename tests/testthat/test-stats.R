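test_that("gaussian smoothing is the identity at sigma 0 and conserves mass", {
  set.seed(2)
  m <- array(runif(6 * 6 * 6), c(6, 6, 6))
  expect_identical(gaussian_smooth(m, 0), m)
  expect_error(gaussian_smooth(m, -1), ">= 0")
  # interior impulse spreads into a kernel that sums to 1
  imp <- array(0, c(15, 15, 15))
  imp[8, 8, 8] <- 1
  sm <- gaussian_smooth(imp, sigma_mm = 1.2)
  expect_equal(sum(sm), 1, tolerance = 1e-4)
  expect_equal(which.max(sm), which.max(imp))
  # constant maps are unchanged despite boundary truncation
  const <- array(3.5, c(7, 7, 7))
  expect_equal(gaussian_smooth(const, 2), const, tolerance = 1e-12)
})

test_that("the sigma = 4 mm kernel has the reported ~9.4 mm FWHM", {
  expect_equal(fwhm_from_sigma(4), 9.4, tolerance = 0.01)
})

test_that("TFCE integrates height and extent as h^H * e^E * dh", {
  # isolated unit-height voxel: integral of h^2 dh from 0 to 1 ~ 1/3
  co <- cbind(c(1, 5, 6), c(1, 1, 1), c(1, 1, 1))
  v <- c(1, 0, 0)
  e <- tfce_enhance(v, co, dims = c(8, 1, 1), dh = 1 / 400)
  expect_equal(e[1], 1 / 3, tolerance = 0.02)
  expect_equal(e[2:3], c(0, 0))
  # a two-voxel cluster of the same height gains the extent factor 2^0.5
  v2 <- c(0, 1, 1)
  e2 <- tfce_enhance(v2, co, dims = c(8, 1, 1), dh = 1 / 400)
  expect_equal(e2[2] / (1 / 3), sqrt(2), tolerance = 0.03)
  # enhancement is monotone in height
  v3 <- c(0.5, 0, 0)
  e3 <- tfce_enhance(v3, co, dims = c(8, 1, 1), dh = 1 / 400)
  expect_lt(e3[1], e[1])
})

test_that("a voxel equal to the regressor attains the minimal corrected p", {
  set.seed(42)
  n <- 13
  V <- 50
  x <- rnorm(n)
  Y <- matrix(rnorm(n * V), n, V)
  Y[, 25] <- 3 * x + rnorm(n, 0, 1e-6)
  des <- design_spec(x, n_permutations = 500)
  res <- permutation_correlate(Y, des, coords = cbind(1:V, 1, 1),
                               dims = c(V, 1, 1), seed = 7)
  expect_equal(res$p_corrected[25], 1 / 501)
  expect_equal(which(res$significant), 25L)
  # permutation p-values can never be zero
  expect_true(all(res$p_corrected >= 1 / 501))
})

test_that("permutation inference is deterministic given the seed", {
  set.seed(9)
  Y <- matrix(rnorm(13 * 20), 13, 20)
  x <- rnorm(13)
  des <- design_spec(x, n_permutations = 200)
  a <- permutation_correlate(Y, des, coords = cbind(1:20, 1, 1),
                             dims = c(20, 1, 1), seed = 3)
  b <- permutation_correlate(Y, des, coords = cbind(1:20, 1, 1),
                             dims = c(20, 1, 1), seed = 3)
  expect_identical(a$p_corrected, b$p_corrected)
})

test_that("zero-variance voxels are excluded and rank deficiency rejected", {
  set.seed(10)
  Y <- matrix(rnorm(13 * 10), 13, 10)
  Y[, 4] <- 5
  x <- rnorm(13)
  des <- design_spec(x, n_permutations = 100)
  res <- permutation_correlate(Y, des, coords = cbind(1:10, 1, 1),
                               dims = c(10, 1, 1), seed = 1)
  expect_true(res$excluded[4])
  expect_equal(res$p_corrected[4], 1)
  des2 <- design_spec(x, nuisance = cbind(x), n_permutations = 100)
  expect_error(permutation_correlate(Y, des2, coords = cbind(1:10, 1, 1),
                                     dims = c(10, 1, 1), seed = 1),
               "rank")
})

test_that("the GLM t-statistic matches lm() with nuisance covariates", {
  set.seed(77)
  n <- 13
  x <- rnorm(n)
  age <- rnorm(n, 25, 4)
  Y <- matrix(rnorm(n * 5), n, 5)
  des <- design_spec(x, nuisance = age, n_permutations = 100)
  res <- permutation_correlate(Y, des, coords = cbind(1:5, 1, 1),
                               dims = c(5, 1, 1), seed = 1)
  for (v in 1:5) {
    ref <- summary(lm(Y[, v] ~ x + age))$coefficients["x", "t value"]
    expect_equal(res$stat[v], ref, tolerance = 1e-10)
  }
})

test_that("partial correlation matches the residualize-then-correlate oracle", {
  set.seed(55)
  n <- 13
  age <- rnorm(n, 25, 5)
  x <- 0.4 * age + rnorm(n)
  y <- -0.3 * age + 0.8 * x + rnorm(n)
  pc <- partial_correlation(x, y, age)
  # independent oracle via explicit residuals
  rx <- resid(lm(x ~ age))
  ry <- resid(lm(y ~ age))
  expect_equal(pc$r, pearson_oracle(rx, ry), tolerance = 1e-12)
  ref <- cor.test(rx, ry)
  expect_equal(pc$r, unname(ref$estimate), tolerance = 1e-12)
  # y = x gives r = 1; orthogonal covariate leaves plain r unchanged
  expect_equal(partial_correlation(x, x + 0 * age, age)$r, 1, tolerance = 1e-12)
  # covariate orthogonal to x and y by construction: partial r = plain r
  z <- rep(c(-1, 1), length.out = n)
  xo <- resid(lm(x ~ z))
  yo <- resid(lm(y ~ z))
  expect_equal(partial_correlation(xo, yo, z)$r,
               pearson_oracle(xo, yo), tolerance = 1e-10)
})

test_that("partial correlation is invariant to affine rescaling", {
  set.seed(66)
  x <- rnorm(13)
  y <- rnorm(13)
  age <- rnorm(13)
  r0 <- partial_correlation(x, y, age)$r
  expect_equal(partial_correlation(5 * x - 3, y / 7 + 2, 10 * age + 1)$r,
               r0, tolerance = 1e-12)
  expect_error(partial_correlation(rep(1, 13), y, age), "zero residual")
})

test_that("ROI extraction returns per-subject means and honors provenance", {
  maps <- list(array(2, c(4, 4, 4)), array(7, c(4, 4, 4)))
  roi <- array(FALSE, c(4, 4, 4))
  roi[2, 2, 2] <- TRUE
  expect_equal(extract_roi(maps, roi), c(2, 7))
  maps[[1]][2, 2, 2] <- 9
  expect_equal(extract_roi(maps, roi), c(9, 7))
  expect_error(extract_roi(maps, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("provenance sampling reads companion maps at projected locations", {
  grid <- c(16L, 10L, 10L)
  f <- array(0, grid)
  for (i in 1:16) f[i, , ] <- 0.85 * exp(-0.5 * (i - 8.5)^2 / 1.4^2)
  spec <- phantom_spec(grid, voxel_mm = 1,
                       bundles = list(bundle_field("sheet", c(0, 0, 1), f)))
  sm <- scalar_maps(fit_tensor(simulate_dwi(spec, seed = 1)))
  sk <- build_skeleton(sm$fa)
  pr <- project_to_skeleton(sm$fa, sk, search_mm = 2, voxel_mm = 1)
  roi <- rep(TRUE, length(sk$idx))
  v <- extract_roi(list(sm$rd), roi, skeleton = sk, projections = list(pr))
  expect_equal(v, mean(tmstdti:::.interp3(sm$rd, pr$positions)))
})
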