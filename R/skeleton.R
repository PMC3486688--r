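# trilinear interpolation of a 3D array at continuous voxel coordinates
# (1-based, clamped to the grid); pts is n x 3
.interp3 <- function(vol, pts) {
  d <- dim(vol)
  x <- pmin(pmax(pts[, 1], 1), d[1])
  y <- pmin(pmax(pts[, 2], 1), d[2])
  z <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1); z0 <- pmin(floor(z), d[3] - 1)
  if (d[1] == 1) x0 <- rep(1, length(x))
  if (d[2] == 1) y0 <- rep(1, length(y))
  if (d[3] == 1) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  at <- function(i, j, k) vol[cbind(i, j, k)]
  at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y1, z0) * fx * fy * (1 - fz) +
    at(x1, y0, z1) * fx * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy * fz +
    at(x1, y1, z1) * fx * fy * fz
}

# finite-difference Hessian components of a 3D array (replicated edges)
.hessian3 <- function(vol) {
  d <- dim(vol)
  shift <- function(v, ax, by) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1), d[ax])
    do.call(`[`, c(list(v), idx))
  }
  d2 <- function(ax) shift(vol, ax, 1) - 2 * vol + shift(vol, ax, -1)
  dcross <- function(a1, a2) {
    (shift(shift(vol, a1, 1), a2, 1) - shift(shift(vol, a1, 1), a2, -1) -
       shift(shift(vol, a1, -1), a2, 1) + shift(shift(vol, a1, -1), a2, -1)) / 4
  }
  list(xx = d2(1), yy = d2(2), zz = d2(3),
       xy = dcross(1, 2), xz = dcross(1, 3), yz = dcross(2, 3))
}

#' Build an FA skeleton from a mean FA map
#'
#' Thins the mean FA map to a one-voxel-thick ridge of tract centers by
#' directional non-maximum suppression: a voxel above `fa_threshold` is
#' kept only if its FA is a local maximum along the tract-perpendicular
#' direction, estimated as the offset of the FA-weighted center of gravity
#' of its 3x3x3 neighborhood. Where that offset vanishes (the voxel sits
#' at the local center already) the direction of strongest negative
#' curvature of the lightly smoothed FA surface is used instead, and for
#' tube-like ridges (both perpendicular curvatures comparably negative)
#' suppression is applied along both so a cylindrical bundle thins to its
#' center line. The suppression direction is stored per voxel; it doubles
#' as the search direction for [project_to_skeleton()].
#'
#' @param mean_fa 3D array of mean FA in \[0, 1\].
#' @param fa_threshold retain only voxels with mean FA above this (default
#'   0.25, restricting analysis to regions where major tracts exist in all
#'   subjects).
#' @param presmooth_sigma_vox Gaussian presmoothing (voxels) applied before
#'   curvature estimation only; stabilizes the ridge direction.
#' @return a `fa_skeleton`: list with `dims`, `idx` (linear indices),
#'   `coords` (n x 3 voxel coordinates), `perp_dir` (n x 3 unit search
#'   directions), `fa` (mean FA at skeleton voxels), `mask` (3D logical).
#' @export
build_skeleton <- function(mean_fa, fa_threshold = 0.25, presmooth_sigma_vox = 0.8) {
  if (min(mean_fa) < 0 || max(mean_fa) > 1 + 1e-9)
    stop("mean FA must lie in [0, 1]")
  d <- dim(mean_fa)
  sm <- gaussian_smooth(mean_fa, sigma_mm = presmooth_sigma_vox, voxel_mm = 1)
  H <- .hessian3(sm)
  cand <- which(mean_fa > fa_threshold)
  if (!length(cand))
    stop("no voxels above the FA threshold; review the threshold or the mask")
  co <- arrayInd(cand, d)
  here <- sm[cand]
  # FA-weighted center-of-gravity offset of the 3x3x3 neighborhood
  g <- matrix(0, length(cand), 3)
  w <- numeric(length(cand))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    off <- c(dx, dy, dz)
    if (all(off == 0)) next
    v <- .interp3(sm, sweep(co, 2, off, `+`))
    g <- g + v %o% off
    w <- w + v
  }
  g <- g / pmax(w, 1e-12)
  gnorm <- sqrt(rowSums(g^2))
  at_center <- gnorm < 0.05
  dir <- g / ifelse(gnorm > 0, gnorm, 1)

  # curvature directions for voxels already at the local center
  M <- cbind(H$xx[cand], H$yy[cand], H$zz[cand],
             H$xy[cand], H$xz[cand], H$yz[cand])
  eig <- .eig3_sym(M)
  dir[at_center, ] <- eig$vectors$e3[at_center, , drop = FALSE]

  # tolerance keeps plateau ties (a ridge running between voxel centers)
  # from being suppressed by trilinear interpolation asymmetries
  tol <- 1e-3
  nms <- function(dd) here >= .interp3(sm, co + dd) - tol &
    here >= .interp3(sm, co - dd) - tol
  keep <- nms(dir)
  # tube-like centers curve away in two directions; suppress along both
  tubelike <- at_center & eig$values[, 3] < 0 &
    eig$values[, 2] < 0.25 * eig$values[, 3]
  if (any(tubelike)) {
    keep2 <- nms(eig$vectors$e2)
    keep <- keep & (!tubelike | keep2)
  }
  if (!any(keep))
    stop("skeleton is empty after non-maximum suppression; review the FA threshold")
  mask <- array(FALSE, d)
  mask[cand[keep]] <- TRUE
  structure(list(dims = d, idx = cand[keep], coords = co[keep, , drop = FALSE],
                 perp_dir = dir[keep, , drop = FALSE],
                 fa = mean_fa[cand[keep]], fa_threshold = fa_threshold,
                 mask = mask),
            class = "fa_skeleton")
}

#' Project a subject map onto the skeleton
#'
#' For each skeleton voxel, searches along the stored ridge-perpendicular
#' direction within `search_mm` of the center (both ways, in steps of half
#' a voxel) and takes the maximum of the subject map — absorbing small
#' residual misalignment of the subject's tract core. The argmax location
#' is retained so companion maps (axial/radial diffusivity) can be sampled
#' at the same place.
#'
#' @param subject_map 3D array on the skeleton grid.
#' @param skeleton a [build_skeleton()] result.
#' @param search_mm search half-width (mm); 0 samples exactly at the
#'   skeleton voxel.
#' @param voxel_mm voxel size (mm).
#' @return list with `values` (length n), `positions` (n x 3 continuous
#'   voxel coordinates of the argmax) and `offset_mm`.
#' @export
project_to_skeleton <- function(subject_map, skeleton, search_mm = 2, voxel_mm = 1) {
  if (!identical(dim(subject_map), skeleton$dims))
    stop("subject map and skeleton grids differ")
  n <- nrow(skeleton$coords)
  offs <- if (search_mm > 0)
    seq(-search_mm, search_mm, by = voxel_mm / 2) else 0
  vals <- matrix(NA_real_, n, length(offs))
  for (j in seq_along(offs)) {
    pts <- skeleton$coords + skeleton$perp_dir * (offs[j] / voxel_mm)
    vals[, j] <- .interp3(subject_map, pts)
  }
  best <- max.col(vals, ties.method = "first")
  pick <- cbind(seq_len(n), best)
  list(values = vals[pick],
       positions = skeleton$coords + skeleton$perp_dir * (offs[best] / voxel_mm),
       offset_mm = offs[best])
}

#' Project a cohort of maps onto a skeleton
#'
#' @param maps list of 3D arrays, one per subject.
#' @inheritParams project_to_skeleton
#' @return list with `values` (n_subjects x n_voxels matrix) and
#'   `projections` (per-subject output of [project_to_skeleton()]).
#' @export
project_cohort <- function(maps, skeleton, search_mm = 2, voxel_mm = 1) {
  pr <- lapply(maps, project_to_skeleton, skeleton = skeleton,
               search_mm = search_mm, voxel_mm = voxel_mm)
  list(values = do.call(rbind, lapply(pr, `[[`, "values")), projections = pr)
}
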