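#' One-voxel-thick planar mask
#'
#' @param dims grid dimensions.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param index 1-based slice index along the axis.
#' @param mode `"inclusion"` or `"exclusion"` (metadata only; stored as an
#'   attribute).
#' @return 3D logical array with one plane set.
#' @export
planar_mask <- function(dims, axis = c("x", "y", "z"), index,
                        mode = c("inclusion", "exclusion")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  ax <- match(axis, c("x", "y", "z"))
  if (index < 1 || index > dims[ax]) stop("plane index outside the grid")
  m <- array(FALSE, dims)
  if (ax == 1) m[index, , ] <- TRUE
  if (ax == 2) m[, index, ] <- TRUE
  if (ax == 3) m[, , index] <- TRUE
  attr(m, "mode") <- mode
  m
}

#' Tracking settings
#'
#' @param samples_per_seed_voxel streamline samples launched per seed voxel
#'   (default 10000).
#' @param step_mm propagation step (mm); `NULL` uses half a voxel.
#' @param max_steps per direction.
#' @param curvature_threshold_deg terminate when a step bends more than
#'   this angle.
#' @param dispersion_kappa concentration of the angular dispersion around
#'   the local principal direction; effective concentration scales with
#'   local FA, so uncertain (low-FA) voxels disperse more. `Inf` tracks
#'   deterministically along the eigenvector field.
#' @param fa_stop terminate when local FA falls below this.
#' @param visitation_threshold_fraction default fraction-of-maximum cut for
#'   [average_and_threshold()].
#' @param seed integer seed.
#' @export
tracking_settings <- function(samples_per_seed_voxel = 10000, step_mm = NULL,
                              max_steps = 2000, curvature_threshold_deg = 80,
                              dispersion_kappa = 60, fa_stop = 0.1,
                              visitation_threshold_fraction = 0.10,
                              seed = 1L) {
  if (samples_per_seed_voxel < 1) stop("samples_per_seed_voxel must be >= 1")
  if (!is.null(step_mm) && step_mm <= 0) stop("step_mm must be positive")
  if (visitation_threshold_fraction < 0 || visitation_threshold_fraction > 1)
    stop("visitation_threshold_fraction must lie in [0, 1]")
  structure(list(samples_per_seed_voxel = as.integer(samples_per_seed_voxel),
                 step_mm = step_mm, max_steps = as.integer(max_steps),
                 curvature_threshold_deg = curvature_threshold_deg,
                 dispersion_kappa = dispersion_kappa, fa_stop = fa_stop,
                 visitation_threshold_fraction = visitation_threshold_fraction,
                 seed = as.integer(seed)), class = "tracking_settings")
}

#' Probabilistic tractography with waypoint and exclusion masks
#'
#' Monte-Carlo streamline propagation from every seed voxel. Each sample
#' starts at a uniform random position inside its seed voxel and is
#' propagated bidirectionally (two opposite initial directions whose
#' combined trajectory forms one streamline) in steps of `step_mm` along
#' directions drawn from an angular dispersion model centered on the local
#' principal eigenvector, sign-aligned with the previous step. Streamlines
#' terminate on grid exit, `max_steps`, FA below `fa_stop`, or a curvature
#' violation. A streamline is retained only if it intersects every waypoint
#' mask and touches no exclusion mask (exclusion takes precedence in the
#' bookkeeping); retained streamlines increment each visited voxel once
#' ("particle count" semantics).
#'
#' In voxels carrying a known second fiber population (`fibers2`), the
#' propagation axis is drawn from either compartment with probability
#' proportional to its volume fraction, reproducing crossing-region
#' branching without a multi-fiber model fit.
#'
#' @param fit a `tensor_fit` (or list with `e1`, plus FA via
#'   `scalar_maps`).
#' @param masks list with `seed` (3D logical), `waypoints` (list of 3D
#'   logical; all must be crossed), `exclusions` (list; any touch rejects).
#' @param settings a [tracking_settings()].
#' @param fibers2 optional list with `dir` (V x 3 or 3-vector) and `frac`
#'   (3D array: probability of drawing the second population).
#' @return a `visitation_map`: list with `counts` (3D array),
#'   `n_launched`, `n_retained`, `n_rejected_exclusion`,
#'   `n_failed_waypoint`, and the settings used.
#' @export
track <- function(fit, masks, settings = tracking_settings(), fibers2 = NULL) {
  dims <- fit$dims
  V <- prod(dims)
  if (is.null(masks$seed) || !any(masks$seed)) stop("seed mask is empty")
  sm <- scalar_maps(fit)
  fa <- as.vector(sm$fa)
  e1 <- matrix(0, V, 3)
  e1[fit$idx, ] <- fit$e1
  seed_idx <- which(as.vector(masks$seed))
  zero_fa <- fa[seed_idx] < settings$fa_stop
  if (any(zero_fa)) {
    message(sprintf("skipping %d seed voxels with FA below fa_stop", sum(zero_fa)))
    seed_idx <- seed_idx[!zero_fa]
  }
  if (!length(seed_idx)) stop("no usable seed voxels (all below fa_stop)")
  step_mm <- if (is.null(settings$step_mm)) 0.5 * fit$voxel_mm else settings$step_mm
  wps <- lapply(if (is.null(masks$waypoints)) list() else masks$waypoints,
                function(m) as.logical(m))
  exs <- lapply(if (is.null(masks$exclusions)) list() else masks$exclusions,
                function(m) as.logical(m))
  d2 <- if (!is.null(fibers2)) {
    dm <- fibers2$dir
    if (is.null(dim(dm))) dm <- matrix(dm, V, 3, byrow = TRUE)
    dm
  } else matrix(0, 0, 3)
  f2 <- if (!is.null(fibers2)) as.numeric(fibers2$frac) else numeric(0)
  kappa <- settings$dispersion_kappa
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.seed_combine(settings$seed, "tractography"))
  res <- track_cpp(as.integer(dims), e1, fa, d2, f2,
                   as.integer(seed_idx - 1L), wps, exs,
                   settings$samples_per_seed_voxel,
                   step_mm / fit$voxel_mm, settings$max_steps,
                   cos(settings$curvature_threshold_deg * pi / 180),
                   if (is.finite(kappa)) kappa else -1,
                   settings$fa_stop)
  structure(list(counts = array(res$counts, dims),
                 n_launched = res$n_launched, n_retained = res$n_retained,
                 n_rejected_exclusion = res$n_rejected_exclusion,
                 n_failed_waypoint = res$n_failed_waypoint,
                 settings = settings, dims = dims),
            class = "visitation_map")
}

#' Average visitation maps across subjects and threshold
#'
#' Voxelwise mean of the per-subject particle counts; voxels below
#' `fraction` of the maximum mean count are zeroed, retaining only
#' consistently visited pathways.
#'
#' @param maps list of `visitation_map` objects (or 3D count arrays).
#' @param fraction fraction of the maximum (default 0.10).
#' @return 3D array of thresholded mean counts.
#' @export
average_and_threshold <- function(maps, fraction = 0.10) {
  if (!length(maps)) stop("no visitation maps supplied")
  arrs <- lapply(maps, function(m) if (is.list(m)) m$counts else m)
  mean_map <- Reduce(`+`, arrs) / length(arrs)
  mx <- max(mean_map)
  if (mx <= 0) stop("mean visitation map is identically zero")
  mean_map[mean_map < fraction * mx] <- 0
  mean_map
}
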