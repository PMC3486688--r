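#' Fiber bundle for a DWI phantom
#'
#' A straight tube running along one grid axis, with a Gaussian radial
#' profile of compartment volume fraction (peaking at `max_fraction` on the
#' tube axis) so the bundle has a well-defined FA ridge at its center line.
#' The compartment diffuses as an axially symmetric tensor
#' `D = ad * u u' + rd * (I - u u')` with `u` the bundle orientation.
#'
#' @param name bundle identifier (e.g. `"cst"`, `"slf"`).
#' @param axis grid axis the tube runs along: `"x"`, `"y"` or `"z"`.
#' @param center length-2 center of the tube in the two perpendicular axes
#'   (voxel units, in axis order with the tube axis removed).
#' @param radius_vox tube radius (voxels); fraction falls off as a Gaussian
#'   with SD `radius_vox / 1.5`.
#' @param ad,rd axial and radial compartment diffusivities (mm^2/s).
#' @param max_fraction peak volume fraction on the tube axis.
#' @export
bundle_tube <- function(name, axis = c("z", "x", "y"), center, radius_vox = 2.5,
                        ad = 1.7e-3, rd = 0.3e-3, max_fraction = 0.8) {
  axis <- match.arg(axis)
  if (ad <= 0 || rd <= 0) stop("diffusivities must be positive")
  if (max_fraction < 0 || max_fraction > 1) stop("max_fraction must lie in [0, 1]")
  structure(list(name = name, axis = axis, center = center,
                 radius_vox = radius_vox, ad = ad, rd = rd,
                 max_fraction = max_fraction), class = "dwi_bundle")
}

#' Fiber bundle with an explicit volume-fraction field
#'
#' Generalizes [bundle_tube()]: the spatial extent is given directly as a
#' per-voxel volume-fraction array and the orientation as an arbitrary
#' unit vector.
#'
#' @param name bundle identifier.
#' @param orientation unit 3-vector (principal diffusion direction).
#' @param fraction_field 3D array of volume fractions in \[0, 1\].
#' @inheritParams bundle_tube
#' @export
bundle_field <- function(name, orientation, fraction_field,
                         ad = 1.7e-3, rd = 0.3e-3) {
  if (abs(sqrt(sum(orientation^2)) - 1) > 1e-8)
    stop("orientation must be a unit vector")
  if (min(fraction_field) < 0 || max(fraction_field) > 1)
    stop("fraction_field must lie in [0, 1]")
  if (ad <= 0 || rd <= 0) stop("diffusivities must be positive")
  structure(list(name = name, orientation = orientation,
                 fraction_field = fraction_field, ad = ad, rd = rd),
            class = "dwi_bundle")
}

.bundle_orientation <- function(bundle) {
  if (!is.null(bundle$orientation)) return(bundle$orientation)
  switch(bundle$axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
}

.bundle_tensor <- function(bundle, ad = bundle$ad, rd = bundle$rd) {
  u <- .bundle_orientation(bundle)
  ad * tcrossprod(u) + rd * (diag(3) - tcrossprod(u))
}

.bundle_fraction_field <- function(bundle, grid) {
  if (!is.null(bundle$fraction_field)) {
    if (!identical(dim(bundle$fraction_field), as.integer(grid)))
      stop("fraction_field dimensions do not match the phantom grid")
    return(bundle$fraction_field)
  }
  ax <- match(bundle$axis, c("x", "y", "z"))
  perp <- setdiff(1:3, ax)
  co <- lapply(grid, function(n) seq_len(n))
  r2 <- outer((co[[perp[1]]] - bundle$center[1])^2,
              (co[[perp[2]]] - bundle$center[2])^2, `+`)
  sig <- bundle$radius_vox / 1.5
  f2d <- bundle$max_fraction * exp(-0.5 * r2 / sig^2)
  f <- array(0, grid)
  # broadcast the 2D cross-section along the tube axis
  if (ax == 1) for (i in seq_len(grid[1])) f[i, , ] <- f2d
  if (ax == 2) for (j in seq_len(grid[2])) f[, j, ] <- f2d
  if (ax == 3) for (k in seq_len(grid[3])) f[, , k] <- f2d
  f
}

#' DWI phantom specification
#'
#' A voxel grid populated with straight fiber bundles plus an isotropic
#' background compartment filling the remaining volume fraction in every
#' voxel. If bundle fractions sum above `max_total_fraction` anywhere
#' (crossing regions), they are rescaled proportionally in those voxels.
#'
#' @param grid_shape integer length-3 voxel grid (>= 8 per axis recommended
#'   for tractography).
#' @param voxel_mm isotropic voxel size (mm).
#' @param bundles list of [bundle_tube()] objects.
#' @param s0 baseline (b = 0) signal.
#' @param noise_sd noise SD in signal units (0 = noiseless).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param iso_diffusivity isotropic background diffusivity (mm^2/s).
#' @param max_total_fraction cap on the per-voxel sum of bundle fractions.
#' @export
phantom_spec <- function(grid_shape = c(16, 16, 16), voxel_mm = 2,
                         bundles = list(), s0 = 1000, noise_sd = 0,
                         noise_model = c("gaussian", "rician"),
                         iso_diffusivity = 0.8e-3, max_total_fraction = 0.95) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) stop("grid_shape must be 3 positive integers")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (iso_diffusivity <= 0) stop("iso_diffusivity must be positive")
  structure(list(grid_shape = grid_shape, voxel_mm = voxel_mm,
                 bundles = bundles, s0 = s0, noise_sd = noise_sd,
                 noise_model = noise_model, iso_diffusivity = iso_diffusivity,
                 max_total_fraction = max_total_fraction),
            class = "dwi_phantom_spec")
}

#' Default crossing-fiber phantom
#'
#' A 16^3 grid with two orthogonal tubes: a "CST-like" bundle running along
#' z and an "SLF-like" bundle running along y, intersecting near the grid
#' center. The crossing region emulates white matter beneath sensorimotor
#' cortex where projection and association fibers interdigitate.
#'
#' @param grid_shape voxel grid.
#' @param noise_sd signal noise SD (default `s0 / 30`, i.e. SNR 30 at b = 0).
#' @param s0 baseline signal.
#' @export
default_phantom <- function(grid_shape = c(16, 16, 16), s0 = 1000, noise_sd = s0 / 30) {
  c0 <- (grid_shape + 1) / 2
  phantom_spec(
    grid_shape = grid_shape, voxel_mm = 2,
    bundles = list(
      bundle_tube("cst", axis = "z", center = c0[1:2], radius_vox = 2.2,
                  max_fraction = 0.75),
      bundle_tube("slf", axis = "y", center = c0[c(1, 3)], radius_vox = 2.2,
                  max_fraction = 0.55)),
    s0 = s0, noise_sd = noise_sd)
}

# per-volume signal attenuation of one tensor compartment under a scheme
.tensor_attenuation <- function(D, scheme) {
  g <- scheme$bvecs
  quad <- colSums(g * (D %*% g))       # g' D g per volume
  exp(-scheme$bvals * quad)
}

.phantom_fractions <- function(spec) {
  fr <- lapply(spec$bundles, .bundle_fraction_field, grid = spec$grid_shape)
  if (length(fr)) {
    tot <- Reduce(`+`, fr)
    over <- tot > spec$max_total_fraction
    if (any(over)) {
      scale <- ifelse(over, spec$max_total_fraction / tot, 1)
      fr <- lapply(fr, function(f) f * scale)
    }
  }
  fr
}

#' Simulate one diffusion-weighted volume set from a phantom
#'
#' Multi-tensor forward model: per voxel,
#' `S(g, b) = s0 * (sum_i f_i exp(-b g' D_i g) + f_iso exp(-b d_iso))`,
#' with optional Gaussian or Rician noise.
#'
#' @param spec a [phantom_spec()].
#' @param scheme a [acquisition_scheme()].
#' @param seed integer seed for the noise draw.
#' @param bundle_overrides optional named list: per bundle name, a list with
#'   any of `ad`, `rd`, `fraction_scale` to perturb that bundle for this
#'   subject.
#' @param preserve_total with `fraction_scale` overrides, rescale the
#'   remaining bundles per voxel so the total bundle fraction is unchanged:
#'   the override then shifts the *relative* strength of crossing
#'   populations instead of displacing the isotropic background.
#' @return a `dwi_volume`: list with `signal` (4D array), `scheme`, `mask`,
#'   `voxel_mm` and `truth` (per-bundle fraction fields, tensors, isotropic
#'   fraction).
#' @export
simulate_dwi <- function(spec, scheme = default_scheme(), seed = 1L,
                         bundle_overrides = list(), preserve_total = FALSE) {
  fr <- .phantom_fractions(spec)
  names(fr) <- vapply(spec$bundles, `[[`, "", "name")
  fr0 <- fr
  scaled <- logical(length(fr))
  tensors <- list()
  for (i in seq_along(spec$bundles)) {
    b <- spec$bundles[[i]]
    ov <- bundle_overrides[[b$name]]
    ad <- if (!is.null(ov$ad)) ov$ad else b$ad
    rd <- if (!is.null(ov$rd)) ov$rd else b$rd
    if (ad <= 0 || rd <= 0) stop("overridden diffusivities must stay positive")
    if (!is.null(ov$fraction_scale)) {
      fr[[i]] <- pmin(1, fr[[i]] * ov$fraction_scale)
      scaled[i] <- TRUE
    }
    tensors[[b$name]] <- .bundle_tensor(b, ad, rd)
  }
  if (preserve_total && any(scaled) && any(!scaled)) {
    t0 <- Reduce(`+`, fr0)
    t_scaled <- Reduce(`+`, fr[scaled])
    t_rest <- Reduce(`+`, fr0[!scaled])
    adj <- ifelse(t_rest > 1e-12, pmax(t0 - t_scaled, 0) / pmax(t_rest, 1e-12), 1)
    for (i in which(!scaled)) fr[[i]] <- fr0[[i]] * adj
  }
  if (length(fr)) {
    tot <- Reduce(`+`, fr)
    over <- tot > 1
    if (any(over)) {
      sc <- ifelse(over, 1 / tot, 1)
      fr <- lapply(fr, function(f) f * sc)
    }
  }
  nvol <- length(scheme$bvals)
  V <- prod(spec$grid_shape)
  f_iso <- 1 - if (length(fr)) Reduce(`+`, fr) else array(0, spec$grid_shape)
  att_iso <- exp(-scheme$bvals * spec$iso_diffusivity)
  S <- as.vector(f_iso) %o% att_iso
  for (i in seq_along(fr))
    S <- S + as.vector(fr[[i]]) %o% .tensor_attenuation(tensors[[i]], scheme)
  S <- spec$s0 * S
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(.seed_combine(seed, "dwi-noise"))
    if (spec$noise_model == "gaussian") {
      S <- S + matrix(rnorm(V * nvol, 0, spec$noise_sd), V, nvol)
    } else {
      S <- sqrt((S + matrix(rnorm(V * nvol, 0, spec$noise_sd), V, nvol))^2 +
                  matrix(rnorm(V * nvol, 0, spec$noise_sd), V, nvol)^2)
    }
  }
  structure(list(
    signal = array(S, c(spec$grid_shape, nvol)),
    scheme = scheme,
    mask = array(TRUE, spec$grid_shape),
    voxel_mm = spec$voxel_mm,
    truth = list(fractions = fr, tensors = tensors, iso_fraction = f_iso,
                 iso_diffusivity = spec$iso_diffusivity)),
    class = "dwi_volume")
}

#' Simulate a cohort of DWI volumes with a structure-behavior link
#'
#' Per subject, one parameter of the target bundle is a linear function of
#' that subject's latent `integrity`, creating a known structure-behavior
#' association (or none, with `slope = 0`). By default the link is injected
#' through the radial compartment diffusivity of the target bundle,
#' mirroring the hypothesis that synchronization skill tracks association-
#' fiber integrity expressed as radial diffusivity.
#'
#' @param spec a [phantom_spec()].
#' @param profiles list of [subject_profile()].
#' @param scheme acquisition scheme.
#' @param link list: `bundle` (target bundle name), `param` (`"rd"` or
#'   `"fraction"`), `slope` (change in the parameter per unit integrity;
#'   mm^2/s for `"rd"`, relative scale for `"fraction"`), `ref` (integrity
#'   value mapping to the unperturbed bundle, default 0.5).
#' @param seed integer seed.
#' @return list with `volumes` (per subject `dwi_volume`), `profiles`,
#'   `link`, and `crossing_mask` (voxels where at least two bundle fractions
#'   exceed 0.1).
#' @export
generate_dwi_cohort <- function(spec, profiles, scheme = default_scheme(),
                                link = list(bundle = "slf", param = "rd",
                                            slope = 0.6e-3, ref = 0.5),
                                seed = 1L) {
  bnames <- vapply(spec$bundles, `[[`, "", "name")
  if (!link$bundle %in% bnames)
    stop(sprintf("link target bundle '%s' not present in phantom spec", link$bundle))
  ref <- if (is.null(link$ref)) 0.5 else link$ref
  target <- spec$bundles[[match(link$bundle, bnames)]]
  vols <- lapply(profiles, function(p) {
    delta <- link$slope * (p$integrity - ref)
    ov <- if (identical(link$param, "fraction")) {
      list(fraction_scale = max(0, 1 + delta))
    } else {
      list(rd = max(target$rd + delta, 1e-5))
    }
    overrides <- list(ov)
    names(overrides) <- link$bundle
    simulate_dwi(spec, scheme, seed = .seed_combine(seed, p$subject_id),
                 bundle_overrides = overrides,
                 preserve_total = identical(link$param, "fraction"))
  })
  fr <- .phantom_fractions(spec)
  crossing <- if (length(fr) >= 2) {
    n_over <- Reduce(`+`, lapply(fr, function(f) f > 0.1))
    n_over >= 2
  } else array(FALSE, spec$grid_shape)
  list(volumes = vols, profiles = profiles, link = link,
       crossing_mask = crossing)
}

#' Crossing-fiber fraction sweep
#'
#' Single-voxel experiment: two orthogonal fiber compartments with volume
#' fractions `1 - f` and `f`; for each `f` on a grid, forward-simulate the
#' noiseless signal, fit a single diffusion tensor and record its scalar
#' measures. Quantifies how the relative strength of a second crossing
#' population suppresses fitted FA and inflates fitted radial diffusivity.
#'
#' @param fractions numeric grid in \[0, 1\] for the second compartment.
#' @param scheme acquisition scheme.
#' @param ad,rd compartment diffusivities (shared by both compartments).
#' @param s0 baseline signal.
#' @return data.frame `fraction, fa, md, ad, rd` (fitted values).
#' @export
crossing_fraction_sweep <- function(fractions = seq(0, 0.5, by = 0.05),
                                    scheme = default_scheme(),
                                    ad = 1.7e-3, rd = 0.3e-3, s0 = 1000) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  D1 <- ad * tcrossprod(c(1, 0, 0)) + rd * (diag(3) - tcrossprod(c(1, 0, 0)))
  D2 <- ad * tcrossprod(c(0, 1, 0)) + rd * (diag(3) - tcrossprod(c(0, 1, 0)))
  a1 <- .tensor_attenuation(D1, scheme)
  a2 <- .tensor_attenuation(D2, scheme)
  rows <- lapply(fractions, function(f) {
    S <- s0 * ((1 - f) * a1 + f * a2)
    vol <- structure(list(signal = array(S, c(1, 1, 1, length(S))),
                          scheme = scheme, mask = array(TRUE, c(1, 1, 1)),
                          voxel_mm = 1), class = "dwi_volume")
    sm <- scalar_maps(fit_tensor(vol))
    data.frame(fraction = f, fa = sm$fa[1], md = sm$md[1],
               ad = sm$ad[1], rd = sm$rd[1])
  })
  do.call(rbind, rows)
}
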