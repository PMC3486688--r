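#' Average repeated diffusion runs
#'
#' Volumewise arithmetic mean of repeated acquisitions. All runs must share
#' the grid and an identical scheme (same b-values and directions in the
#' same order; no reordering is attempted).
#'
#' @param runs list of `dwi_volume` objects.
#' @return a `dwi_volume` with averaged signal.
#' @export
average_runs <- function(runs) {
  if (!length(runs)) stop("no runs supplied")
  ref <- runs[[1]]
  for (r in runs[-1]) {
    if (!identical(dim(r$signal), dim(ref$signal)))
      stop("runs differ in grid or volume count")
    if (!isTRUE(all.equal(r$scheme$bvals, ref$scheme$bvals)) ||
        !isTRUE(all.equal(r$scheme$bvecs, ref$scheme$bvecs, tolerance = 1e-8)))
      stop("acquisition schemes do not align across runs")
  }
  out <- ref
  out$signal <- Reduce(`+`, lapply(runs, `[[`, "signal")) / length(runs)
  out
}

#' Fit the diffusion tensor per voxel
#'
#' Log-linear least squares on `log(S / S0)` with `S0` the per-voxel mean of
#' all b = 0 volumes; b = 0 rows are excluded from the design matrix.
#' Non-positive signal samples are replaced by a small positive epsilon
#' before the log (flagged in `qc$clipped_signal`); negative eigenvalues
#' are clamped to zero after decomposition (flagged in `qc$clamped_eval`).
#' A weighted variant (weights `S^2`, the usual WLS linearization) is
#' available via `weighted = TRUE`.
#'
#' @param dwi a `dwi_volume`.
#' @param weighted logical, use signal-squared weights.
#' @return a `tensor_fit`: list with `dims`, `voxel_mm`, `mask`,
#'   `tensors` (V x 6: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz over masked voxels),
#'   `evals` (V x 3, descending, clamped), `e1`, `e2`, `e3` (V x 3 unit),
#'   `idx` (linear indices of masked voxels) and `qc` flags.
#' @export
fit_tensor <- function(dwi, weighted = FALSE) {
  scheme <- dwi$scheme
  dwi_rows <- scheme$bvals > 0
  if (sum(dwi_rows) < 6) stop("need at least 6 diffusion-weighted volumes")
  g <- scheme$bvecs[, dwi_rows, drop = FALSE]
  b <- scheme$bvals[dwi_rows]
  X <- cbind(b * g[1, ]^2, b * g[2, ]^2, b * g[3, ]^2,
             2 * b * g[1, ] * g[2, ], 2 * b * g[1, ] * g[3, ],
             2 * b * g[2, ] * g[3, ])
  if (qr(X)$rank < 6) stop("gradient directions do not span 6 independent tensor components")

  dims <- dim(dwi$signal)[1:3]
  nvol <- dim(dwi$signal)[4]
  idx <- which(as.vector(dwi$mask))
  S <- matrix(dwi$signal, prod(dims), nvol)[idx, , drop = FALSE]
  s0 <- rowMeans(S[, !dwi_rows, drop = FALSE])
  Sd <- S[, dwi_rows, drop = FALSE]
  eps <- pmax(s0 * 1e-6, 1e-12)
  clipped <- Sd <= 0 | s0 <= 0
  s0 <- pmax(s0, 1e-12)
  Sd[Sd <= 0] <- eps[row(Sd)[Sd <= 0]]
  Y <- -log(Sd / s0)                       # m columns; Y = X %*% d

  if (!weighted) {
    P <- solve(crossprod(X), t(X))         # 6 x m
    Dv <- Y %*% t(P)                       # V x 6
  } else {
    Dv <- matrix(0, nrow(Y), 6)
    for (v in seq_len(nrow(Y))) {
      w <- Sd[v, ]^2
      XtW <- t(X * w)
      Dv[v, ] <- solve(XtW %*% X, XtW %*% Y[v, ])
    }
  }
  eig <- .eig3_sym(Dv)
  clamped <- eig$values < 0
  evals <- pmax(eig$values, 0)
  structure(list(dims = dims, voxel_mm = dwi$voxel_mm, mask = dwi$mask,
                 tensors = Dv, evals = evals,
                 e1 = eig$vectors$e1, e2 = eig$vectors$e2, e3 = eig$vectors$e3,
                 idx = idx,
                 qc = list(clipped_signal = rowSums(clipped) > 0,
                           clamped_eval = rowSums(clamped) > 0)),
            class = "tensor_fit")
}

#' Scalar maps from a tensor fit
#'
#' FA is the normalized eigenvalue dispersion
#' `sqrt(3/2) * sqrt(sum((l - lbar)^2)) / sqrt(sum(l^2))` (0 for an all-zero
#' tensor); MD the eigenvalue mean; axial diffusivity (AD) the diffusivity
#' along the axis of greatest diffusion (largest eigenvalue); radial
#' diffusivity (RD) the mean of the two perpendicular axes.
#'
#' @param fit a `tensor_fit`.
#' @return a `scalar_maps` object: list of 3D arrays `fa`, `md`, `ad`, `rd`
#'   (zero outside the mask) plus `dims`, `voxel_mm`, `mask`.
#' @export
scalar_maps <- function(fit) {
  l <- fit$evals
  lbar <- rowMeans(l)
  num <- sqrt(rowSums((l - lbar)^2))
  den <- sqrt(rowSums(l^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  to_map <- function(v) {
    m <- array(0, fit$dims)
    m[fit$idx] <- v
    m
  }
  structure(list(fa = to_map(pmin(fa, 1)), md = to_map(lbar),
                 ad = to_map(l[, 1]), rd = to_map((l[, 2] + l[, 3]) / 2),
                 dims = fit$dims, voxel_mm = fit$voxel_mm, mask = fit$mask),
            class = "scalar_maps")
}
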