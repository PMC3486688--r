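#' Separable Gaussian smoothing of a 3D map
#'
#' Convolution with a normalized discrete Gaussian kernel truncated at
#' 4 sigma, applied separably along each axis. At the boundary the kernel
#' is renormalized over the in-volume support, so a constant map is left
#' unchanged. `sigma_mm = 0` is the identity.
#'
#' @param map 3D array.
#' @param sigma_mm kernel SD in mm.
#' @param voxel_mm voxel size in mm.
#' @export
gaussian_smooth <- function(map, sigma_mm, voxel_mm = 1) {
  if (sigma_mm < 0) stop("sigma must be >= 0")
  if (sigma_mm == 0) return(map)
  s <- sigma_mm / voxel_mm
  r <- max(1L, ceiling(4 * s))
  k <- exp(-0.5 * ((-r):r / s)^2)
  k <- k / sum(k)
  d <- dim(map)
  ones <- array(1, d)
  conv_axis <- function(v, ax) {
    out <- array(0, d)
    for (t in (-r):r) {
      idx_src <- lapply(d, seq_len)
      idx_dst <- lapply(d, seq_len)
      lo <- max(1, 1 - t); hi <- min(d[ax], d[ax] - t)
      if (lo > hi) next
      idx_dst[[ax]] <- lo:hi
      idx_src[[ax]] <- (lo:hi) + t
      add <- do.call(`[`, c(list(v), idx_src, drop = FALSE)) * k[t + r + 1]
      out <- do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(out), idx_dst, drop = FALSE)) + add)))
    }
    out
  }
  num <- map
  den <- ones
  for (ax in 1:3) {
    num <- conv_axis(num, ax)
    den <- conv_axis(den, ax)
  }
  num / den
}

#' Full width at half maximum of a Gaussian kernel
#' @param sigma_mm kernel SD (mm).
#' @return FWHM in mm (`2 sqrt(2 ln 2) sigma`).
#' @export
fwhm_from_sigma <- function(sigma_mm) 2 * sqrt(2 * log(2)) * sigma_mm

#' Threshold-free cluster enhancement
#'
#' Integrates cluster-like support over statistic heights:
#' `tfce(v) = sum_h h^H * e(h, v)^E * dh`, where `e(h, v)` is the size of
#' the connected component containing `v` at threshold `h`. Connectivity is
#' 26-neighborhood among the supplied voxels (a skeleton's own neighborhood
#' when applied to skeleton data).
#'
#' @param values non-negative statistic per voxel.
#' @param coords n x 3 integer voxel coordinates.
#' @param dims grid dimensions.
#' @param H,E height and extent exponents (canonical 2 and 0.5).
#' @param dh integration step; `NULL` uses `max(values) / 100`.
#' @return enhanced values (same length).
#' @export
tfce_enhance <- function(values, coords, dims, H = 2, E = 0.5, dh = NULL) {
  stopifnot(length(values) == nrow(coords))
  if (all(values <= 0)) return(numeric(length(values)))
  if (is.null(dh)) dh <- max(values) / 100
  tfce_enhance_cpp(as.numeric(values), as.matrix(coords) - 1L,
                   as.integer(dims), H, E, dh)
}

#' Design for a permutation partial-correlation analysis
#'
#' @param interest per-subject regressor of interest (e.g. final PSYN).
#' @param nuisance per-subject nuisance covariates (vector, matrix or
#'   data.frame; e.g. age, optionally gender), or `NULL`.
#' @param n_permutations number of random permutations (default 5000).
#' @param alpha corrected significance level (default 0.05).
#' @param tfce list with `H`, `E`, `dh`.
#' @param tail `"two-sided"`, `"positive"` or `"negative"`.
#' @export
design_spec <- function(interest, nuisance = NULL, n_permutations = 5000,
                        alpha = 0.05, tfce = list(H = 2, E = 0.5, dh = NULL),
                        tail = c("two-sided", "positive", "negative")) {
  tail <- match.arg(tail)
  interest <- as.numeric(interest)
  Z <- if (is.null(nuisance)) NULL else as.matrix(nuisance)
  n <- length(interest)
  k <- if (is.null(Z)) 0 else ncol(Z)
  if (!is.null(Z) && nrow(Z) != n) stop("nuisance rows must match interest length")
  if (n < 3 + k) stop("need at least 3 + n_covariates subjects")
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  structure(list(interest = interest, nuisance = Z,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 tfce = tfce, tail = tail), class = "design_spec")
}

#' Voxelwise permutation correlation with TFCE correction
#'
#' Per voxel, the partial association between the regressor of interest and
#' the data after regressing out nuisance covariates (t statistic of the
#' interest coefficient in the full GLM). Inference uses Freedman-Lane
#' permutation: residuals from the nuisance-only model are row-permuted,
#' the statistic map is recomputed and TFCE-enhanced, and the family-wise
#' corrected p-value of each voxel is its enhanced value's rank in the
#' permutation distribution of the image-wide maximum:
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`.
#'
#' Zero-variance voxels are excluded from testing and flagged. Results are
#' deterministic given `seed`.
#'
#' @param Y n_subjects x n_voxels matrix (e.g. skeleton-projected FA), or a
#'   list of 3D arrays with `mask` supplied.
#' @param design a [design_spec()].
#' @param coords n_voxels x 3 voxel coordinates (for TFCE connectivity);
#'   required when `Y` is a matrix.
#' @param dims grid dimensions.
#' @param seed integer seed for the permutation draws.
#' @param mask 3D logical, required when `Y` is a list of maps.
#' @return a `stat_result`: list with `stat` (t per voxel), `partial_r`,
#'   `tfce`, `p_corrected`, `significant` (logical at `alpha`), `excluded`
#'   (zero-variance flags), `max_null` (permutation distribution), plus the
#'   design and geometry.
#' @export
permutation_correlate <- function(Y, design, coords = NULL, dims = NULL,
                                  seed = 1L, mask = NULL) {
  if (is.list(Y) && !is.matrix(Y)) {
    if (is.null(mask)) stop("mask required when Y is a list of maps")
    dims <- dim(Y[[1]])
    idx <- which(as.vector(mask))
    coords <- arrayInd(idx, dims)
    Y <- do.call(rbind, lapply(Y, function(m) as.vector(m)[idx]))
  }
  if (is.null(coords) || is.null(dims)) stop("coords and dims are required")
  n <- nrow(Y)
  x <- design$interest
  if (length(x) != n) stop("design does not match number of subjects")
  Z <- cbind(rep(1, n), design$nuisance)
  if (qr(cbind(x, Z))$rank < ncol(Z) + 1) stop("rank-deficient design matrix")

  keep <- apply(Y, 2, function(col) sd(col) > 0)
  Yk <- Y[, keep, drop = FALSE]
  ck <- coords[keep, , drop = FALSE]
  p_full <- ncol(Z) + 1
  df <- n - p_full

  Hz <- Z %*% solve(crossprod(Z), t(Z))
  Rz <- diag(n) - Hz
  xr <- as.vector(Rz %*% x)
  xx <- sum(xr^2)
  E <- Rz %*% Yk                      # reduced-model residuals

  t_of <- function(Ymat) {
    # full-model t for the interest regressor; nuisance effects removed by
    # working with Rz-projected data and regressor
    Er <- Rz %*% Ymat
    beta <- as.vector(crossprod(xr, Er)) / xx
    rss <- colSums(Er^2) - beta^2 * xx
    se <- sqrt(pmax(rss, 0) / df / xx)
    ifelse(se > 0, beta / se, 0)
  }
  tailed <- function(tv) switch(design$tail,
                                "two-sided" = abs(tv),
                                positive = pmax(tv, 0),
                                negative = pmax(-tv, 0))

  t_obs <- t_of(E)                    # E = Rz Y gives the same t as Y itself
  r_obs <- t_obs / sqrt(t_obs^2 + df)
  enh_obs <- tfce_enhance(tailed(t_obs), ck, dims,
                          H = design$tfce$H, E = design$tfce$E,
                          dh = design$tfce$dh)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.seed_combine(seed, "freedman-lane"))
  max_null <- numeric(design$n_permutations)
  for (p in seq_len(design$n_permutations)) {
    perm <- sample.int(n)
    tv <- t_of(E[perm, , drop = FALSE])
    enh <- tfce_enhance(tailed(tv), ck, dims,
                        H = design$tfce$H, E = design$tfce$E,
                        dh = design$tfce$dh)
    max_null[p] <- if (length(enh)) max(enh) else 0
  }
  p_corr_k <- vapply(enh_obs, function(e) (1 + sum(max_null >= e)) /
                       (1 + design$n_permutations), 0)

  expand <- function(v, fill) {
    out <- rep(fill, ncol(Y))
    out[keep] <- v
    out
  }
  structure(list(
    stat = expand(t_obs, NA_real_), partial_r = expand(r_obs, NA_real_),
    tfce = expand(enh_obs, 0), p_corrected = expand(p_corr_k, 1),
    significant = expand(p_corr_k < design$alpha, FALSE),
    excluded = !keep, max_null = max_null,
    coords = coords, dims = dims, design = design),
    class = "stat_result")
}

#' Per-subject mean of a scalar map within an ROI
#'
#' With `projections` supplied (the per-subject output of
#' [project_to_skeleton()]), each subject's map is sampled at that
#' subject's projected source locations for the ROI's skeleton voxels, so
#' companion maps (AD/RD) are read at the same place the FA projection
#' came from. Otherwise the plain mean over the ROI mask is returned.
#'
#' @param maps list of 3D arrays, one per subject.
#' @param roi logical: a 3D mask, or (with `skeleton`) a per-skeleton-voxel
#'   selection vector.
#' @param skeleton optional [build_skeleton()] result (required for
#'   provenance sampling).
#' @param projections optional list of per-subject projections.
#' @return numeric vector, one mean per subject.
#' @export
extract_roi <- function(maps, roi, skeleton = NULL, projections = NULL) {
  if (!is.null(projections)) {
    if (is.null(skeleton)) stop("skeleton required with projections")
    sel <- if (length(roi) == length(skeleton$idx)) which(as.logical(roi))
    else which(as.logical(roi[skeleton$idx]))
    if (!length(sel)) stop("empty ROI")
    vapply(seq_along(maps), function(s) {
      pts <- projections[[s]]$positions[sel, , drop = FALSE]
      mean(.interp3(maps[[s]], pts))
    }, 0)
  } else {
    idx <- which(as.logical(roi))
    if (!length(idx)) stop("empty ROI")
    vapply(maps, function(m) mean(m[idx]), 0)
  }
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on the covariates (plus intercept), with a two-sided p-value
#' from the t transform on `n - 2 - n_covariates` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates vector, matrix or data.frame of nuisance covariates,
#'   or `NULL` for a plain correlation.
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  k <- 0
  scale_x <- sd(x) + mean(abs(x))
  scale_y <- sd(y) + mean(abs(y))
  if (!is.null(covariates)) {
    Z <- cbind(1, as.matrix(covariates))
    k <- ncol(Z) - 1
    if (n <= k + 2) stop("need n > n_covariates + 2")
    Q <- Z %*% solve(crossprod(Z), t(Z))
    x <- x - as.vector(Q %*% x)
    y <- y - as.vector(Q %*% y)
  } else {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  if (sd(x) <= 1e-12 * max(scale_x, 1e-300) ||
      sd(y) <= 1e-12 * max(scale_y, 1e-300))
    stop("zero residual variance")
  r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  df <- n - 2 - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tval), df), df = df)
}
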