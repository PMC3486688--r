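# Shared fixtures and independent oracles used across the suite.

# noiseless single-voxel DWI volume from an explicit tensor
single_voxel_dwi <- function(D, scheme = default_scheme(), s0 = 1000) {
  att <- exp(-scheme$bvals * colSums(scheme$bvecs * (D %*% scheme$bvecs)))
  structure(list(signal = array(s0 * att, c(1, 1, 1, length(att))),
                 scheme = scheme, mask = array(TRUE, c(1, 1, 1)),
                 voxel_mm = 2), class = "dwi_volume")
}

# single straight tube along z, noiseless by default
single_tube_phantom <- function(grid = c(12, 12, 16), noise_sd = 0,
                                max_fraction = 0.85, radius = 2.5) {
  c0 <- (grid + 1) / 2
  phantom_spec(grid_shape = grid, voxel_mm = 2,
               bundles = list(bundle_tube("tube", axis = "z",
                                          center = c0[1:2],
                                          radius_vox = radius,
                                          max_fraction = max_fraction)),
               noise_sd = noise_sd)
}

# independent closed-form FA from eigenvalues (oracle; distinct from the
# package's vectorized implementation path)
fa_oracle <- function(l) {
  lbar <- mean(l)
  den <- sqrt(sum(l^2))
  if (den == 0) return(0)
  sqrt(3 / 2) * sqrt(sum((l - lbar)^2)) / den
}

# independent Pearson r via explicit sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# build a one-trial record directly (element times + response times)
make_trial <- function(onsets, offsets, labels, press = NULL, release = NULL) {
  resp <- if (is.null(press)) data.frame(press_ms = numeric(0), release_ms = numeric(0))
  else data.frame(press_ms = press, release_ms = release)
  resp <- resp[order(resp$press_ms), , drop = FALSE]
  list(subject = "t", day = 1, run = 1, trial = 1,
       elements = data.frame(onset_ms = onsets, offset_ms = offsets,
                             label = labels, stringsAsFactors = FALSE),
       responses = resp)
}

# random symmetric positive-definite 3x3 tensor on a diffusivity scale
random_spd_tensor <- function() {
  A <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(A))
  l <- sort(runif(3, 0.2e-3, 2e-3), decreasing = TRUE)
  Q %*% diag(l) %*% t(Q)
}

tensor_to_row <- function(D) c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
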