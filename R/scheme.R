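#' Diffusion acquisition scheme
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x n matrix of gradient directions (unit norm for b > 0;
#'   zero vectors allowed for b = 0 volumes).
#' @return object of class `dwi_scheme`.
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3 || ncol(bvecs) != length(bvals))
    stop("bvecs must be 3 x length(bvals)")
  dwi <- bvals > 0
  if (sum(!dwi) < 1) stop("scheme needs at least one b = 0 volume")
  nrm <- sqrt(colSums(bvecs[, dwi, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("gradient directions must be unit norm for b > 0 volumes")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs,
                 n_b0 = sum(!dwi)), class = "dwi_scheme")
}

#' Default single-shell scheme
#'
#' 32 approximately uniform directions (spherical Fibonacci spiral) at
#' b = 1000 s/mm^2 preceded by one b = 0 volume per 32 directions.
#'
#' @param n_dirs number of diffusion directions.
#' @param b shell b-value (s/mm^2).
#' @param n_b0 number of b = 0 volumes (default one per 32 directions).
#' @export
default_scheme <- function(n_dirs = 32, b = 1000, n_b0 = max(1L, round(n_dirs / 32))) {
  i <- seq_len(n_dirs) - 0.5
  phi <- acos(1 - 2 * i / n_dirs)         # polar angle over the full sphere
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- rbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  bvecs <- cbind(matrix(0, 3, n_b0), dirs)
  acquisition_scheme(c(rep(0, n_b0), rep(b, n_dirs)), bvecs)
}

#' Read / write FSL-dialect bval and bvec files
#'
#' `bvals` is a single whitespace-separated row; `bvecs` has three rows
#' (x, y, z), one column per volume.
#'
#' @param scheme a `dwi_scheme`.
#' @param bval_path,bvec_path file paths.
#' @export
write_bvals_bvecs <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' @rdname write_bvals_bvecs
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  dimnames(bvecs) <- NULL
  acquisition_scheme(bvals, bvecs)
}
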