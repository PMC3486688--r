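make_tube_fit <- function(noise_sd = 0) {
  fit_tensor(simulate_dwi(single_tube_phantom(noise_sd = noise_sd), seed = 1))
}

test_that("planar masks set exactly one slice", {
  m <- planar_mask(c(16, 16, 16), "z", 5)
  expect_equal(sum(m), 256)
  idx <- which(m, arr.ind = TRUE)
  expect_true(all(idx[, 3] == 5))
  expect_identical(planar_mask(c(16, 16, 16), "x", 3),
                   planar_mask(c(16, 16, 16), "x", 3))
  expect_error(planar_mask(c(16, 16, 16), "y", 20), "outside")
})

test_that("deterministic tracking on a straight tube retains everything in the tube", {
  fit <- make_tube_fit()
  dims <- fit$dims
  seed_mask <- array(FALSE, dims)
  seed_mask[6:7, 6:7, 8] <- TRUE
  wp <- list(planar_mask(dims, "z", 2), planar_mask(dims, "z", 15))
  st <- tracking_settings(samples_per_seed_voxel = 200,
                          dispersion_kappa = Inf, seed = 4)
  vm <- track(fit, list(seed = seed_mask, waypoints = wp), st)
  expect_equal(vm$n_launched, 200 * 4)
  expect_equal(vm$n_retained, vm$n_launched)   # retention fraction 1
  idx <- which(vm$counts > 0, arr.ind = TRUE)
  expect_true(all(abs(idx[, 1] - 6.5) <= 1.5))  # confined to the tube core
  expect_true(all(abs(idx[, 2] - 6.5) <= 1.5))
  # every retained streamline crossed the perpendicular waypoint planes
  expect_true(all(vm$counts[, , 2][seed_mask[, , 8]] > 0))
})

test_that("an exclusion plane between seed and waypoint rejects all streamlines", {
  fit <- make_tube_fit()
  dims <- fit$dims
  seed_mask <- array(FALSE, dims)
  seed_mask[6:7, 6:7, 8] <- TRUE
  wp <- list(planar_mask(dims, "z", 2), planar_mask(dims, "z", 15))
  ex <- planar_mask(dims, "z", 5, mode = "exclusion")
  st <- tracking_settings(samples_per_seed_voxel = 50,
                          dispersion_kappa = Inf, seed = 4)
  vm <- track(fit, list(seed = seed_mask, waypoints = wp,
                        exclusions = list(ex)), st)
  expect_equal(vm$n_retained, 0)
  expect_equal(vm$n_rejected_exclusion, vm$n_launched)
  expect_true(all(vm$counts == 0))
})

test_that("streamline bookkeeping is exhaustive and masks act monotonically", {
  fit <- make_tube_fit()
  dims <- fit$dims
  seed_mask <- array(FALSE, dims)
  seed_mask[6:7, 6:7, 8] <- TRUE
  st <- tracking_settings(samples_per_seed_voxel = 100,
                          dispersion_kappa = 30, seed = 8)
  base <- track(fit, list(seed = seed_mask), st)
  expect_equal(base$n_launched, 100 * sum(seed_mask))
  expect_equal(base$n_retained + base$n_rejected_exclusion +
                 base$n_failed_waypoint, base$n_launched)
  wp <- list(planar_mask(dims, "z", 3))
  with_wp <- track(fit, list(seed = seed_mask, waypoints = wp), st)
  expect_lte(with_wp$n_retained, base$n_retained)
  ex <- list(planar_mask(dims, "x", 2, mode = "exclusion"))
  with_ex <- track(fit, list(seed = seed_mask, waypoints = wp,
                             exclusions = ex), st)
  expect_lte(with_ex$n_retained, with_wp$n_retained)
  expect_equal(with_ex$n_retained + with_ex$n_rejected_exclusion +
                 with_ex$n_failed_waypoint, with_ex$n_launched)
})

test_that("tracking is reproducible given the seed and scales with samples", {
  fit <- make_tube_fit()
  dims <- fit$dims
  seed_mask <- array(FALSE, dims)
  seed_mask[6:7, 6:7, 8] <- TRUE
  st <- tracking_settings(samples_per_seed_voxel = 150,
                          dispersion_kappa = 40, seed = 12)
  a <- track(fit, list(seed = seed_mask), st)
  b <- track(fit, list(seed = seed_mask), st)
  expect_identical(a$counts, b$counts)
  st4 <- tracking_settings(samples_per_seed_voxel = 600,
                           dispersion_kappa = 40, seed = 12)
  big <- track(fit, list(seed = seed_mask), st4)
  expect_equal(sum(big$counts) / sum(a$counts), 4, tolerance = 0.2)
})

test_that("mirrored geometry yields the mirrored visitation map", {
  grid <- c(16L, 12L, 16L)
  mk <- function(cx) {
    spec <- phantom_spec(grid, voxel_mm = 2,
                         bundles = list(bundle_tube("t", "z", c(cx, 6.5),
                                                    radius_vox = 2.5,
                                                    max_fraction = 0.85)))
    fit_tensor(simulate_dwi(spec, seed = 1))
  }
  fitL <- mk(5.5)
  fitR <- mk(16 + 1 - 5.5)
  seedL <- array(FALSE, grid)
  seedL[5:6, 6:7, 8] <- TRUE
  seedR <- seedL[grid[1]:1, , ]
  st <- tracking_settings(samples_per_seed_voxel = 100,
                          dispersion_kappa = Inf, seed = 3)
  vmL <- track(fitL, list(seed = seedL), st)
  vmR <- track(fitR, list(seed = seedR), st)
  mirrored <- vmR$counts[grid[1]:1, , ]
  # random in-voxel start positions differ between the two runs, so allow
  # boundary-crossing sampling noise of a few streamlines per voxel
  expect_lt(sum(abs(mirrored - vmL$counts)) / sum(vmL$counts), 0.05)
  expect_equal(vmR$n_retained, vmL$n_retained)
})

test_that("averaging and 10%-of-max thresholding removes weak spurious branches", {
  a <- array(0, c(8, 8, 8))
  a[4, 4, ] <- 100                    # main trunk
  a[4, 5, 1:2] <- 4                   # spurious branch at 4% of max
  b <- a
  b[4, 4, ] <- 120
  m <- average_and_threshold(list(a, b), fraction = 0.10)
  expect_equal(m[4, 4, 3], 110)
  expect_true(all(m[4, 5, ] == 0))    # branch removed
  expect_identical(average_and_threshold(list(a), fraction = 0),
                   a)
  expect_equal(average_and_threshold(list(a, a), fraction = 0), a)
  expect_error(average_and_threshold(list(array(0, c(2, 2, 2)))), "zero")
})

test_that("axial and lateral target schemes dissociate the two crossing bundles", {
  spec <- default_phantom(noise_sd = 0)
  dwi <- simulate_dwi(spec, seed = 1)
  fit <- fit_tensor(dwi)
  dims <- fit$dims
  fr <- dwi$truth$fractions
  crossing <- fr$cst > 0.1 & fr$slf > 0.1
  f2 <- array(0, dims)
  f2[crossing] <- (fr$slf / (fr$cst + fr$slf))[crossing]
  fib2 <- list(dir = c(0, 1, 0), frac = f2)
  seed_mask <- array(FALSE, dims)
  seed_mask[8:9, 8:9, 8:9] <- TRUE
  st <- tracking_settings(samples_per_seed_voxel = 1000,
                          dispersion_kappa = 200, seed = 6)
  # axial (CST-style) targets: superior and inferior planes
  vmA <- track(fit, list(seed = seed_mask,
                         waypoints = list(planar_mask(dims, "z", 3),
                                          planar_mask(dims, "z", 14))),
               st, fibers2 = fib2)
  # lateral/anterior-posterior (SLF-style) targets
  vmB <- track(fit, list(seed = seed_mask,
                         waypoints = list(planar_mask(dims, "y", 3),
                                          planar_mask(dims, "y", 14))),
               st, fibers2 = fib2)
  expect_gt(vmA$n_retained, 0)
  expect_gt(vmB$n_retained, 0)
  thA <- average_and_threshold(list(vmA), 0.10)
  thB <- average_and_threshold(list(vmB), 0.10)
  iA <- which(thA > 0, arr.ind = TRUE)
  iB <- which(thB > 0, arr.ind = TRUE)
  # high-count voxels lie on the correct bundle: the axial scheme spans z
  # on the CST tube, the lateral scheme spans y on the SLF tube
  expect_true(all(abs(iA[, 1] - 8.5) <= 2.5))
  expect_true(all(abs(iA[, 2] - 8.5) <= 2.5))
  expect_gte(diff(range(iA[, 3])), 11)
  expect_true(all(abs(iB[, 1] - 8.5) <= 2.5))
  expect_true(all(abs(iB[, 3] - 8.5) <= 2.5))
  expect_gte(diff(range(iB[, 2])), 11)
})
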