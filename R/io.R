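#' Write a 3D or 4D map as NIfTI
#'
#' A plain scaled-identity affine (voxel size on the diagonal) is used:
#' phantom grids are voxel-indexed and share a common space by
#' construction, so no registration metadata is needed.
#'
#' @param map numeric array (3D or 4D) or logical mask.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm isotropic voxel size (mm).
#' @export
write_nifti_map <- function(map, path, voxel_mm = 1) {
  img <- RNifti::asNifti(map * 1, pixdim = rep(voxel_mm, min(3, length(dim(map)))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_map
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "voxel_mm") <- RNifti::pixdim(img)[1]
  arr
}

#' Write a simulated DWI data set to disk
#'
#' Produces `<prefix>.nii.gz` (4D signal), `<prefix>.bval` and
#' `<prefix>.bvec` (FSL dialect) and `<prefix>_mask.nii.gz`.
#'
#' @param dwi a `dwi_volume`.
#' @param prefix output path prefix.
#' @export
write_dwi <- function(dwi, prefix) {
  write_nifti_map(dwi$signal, paste0(prefix, ".nii.gz"), dwi$voxel_mm)
  write_bvals_bvecs(dwi$scheme, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  write_nifti_map(dwi$mask, paste0(prefix, "_mask.nii.gz"), dwi$voxel_mm)
  invisible(prefix)
}

#' @rdname write_dwi
#' @export
read_dwi <- function(prefix) {
  sig <- read_nifti_map(paste0(prefix, ".nii.gz"))
  mask_path <- paste0(prefix, "_mask.nii.gz")
  mask <- if (file.exists(mask_path)) read_nifti_map(mask_path) > 0
  else array(TRUE, dim(sig)[1:3])
  structure(list(signal = sig,
                 scheme = read_bvals_bvecs(paste0(prefix, ".bval"),
                                           paste0(prefix, ".bvec")),
                 mask = mask, voxel_mm = attr(sig, "voxel_mm")),
            class = "dwi_volume")
}

#' Write scalar maps (FA/MD/AD/RD) as NIfTI files
#'
#' @param maps a `scalar_maps` object.
#' @param prefix output path prefix; files are `<prefix>_fa.nii.gz` etc.
#' @export
write_scalar_maps <- function(maps, prefix) {
  for (nm in c("fa", "md", "ad", "rd"))
    write_nifti_map(maps[[nm]], sprintf("%s_%s.nii.gz", prefix, nm), maps$voxel_mm)
  invisible(prefix)
}

#' Write the significant-cluster table of a stat result as TSV
#'
#' Clusters are connected components (26-neighborhood) of the significant
#' mask; each row reports the cluster id, peak statistic, peak voxel index
#' and size.
#'
#' @param result a `stat_result`.
#' @param path output TSV path.
#' @export
write_cluster_table <- function(result, path) {
  sig <- which(result$significant)
  if (!length(sig)) {
    df <- data.frame(cluster = integer(0), peak_stat = numeric(0),
                     peak_x = integer(0), peak_y = integer(0),
                     peak_z = integer(0), size = integer(0))
  } else {
    co <- result$coords[sig, , drop = FALSE]
    lab <- .label_components(co)
    df <- do.call(rbind, lapply(sort(unique(lab)), function(l) {
      members <- which(lab == l)
      stats <- result$stat[sig[members]]
      pk <- members[which.max(abs(stats))]
      data.frame(cluster = l, peak_stat = stats[which.max(abs(stats))],
                 peak_x = co[pk, 1], peak_y = co[pk, 2], peak_z = co[pk, 3],
                 size = length(members))
    }))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# 26-connected component labels for a set of voxel coordinates
.label_components <- function(coords) {
  n <- nrow(coords)
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  lut <- seq_len(n)
  names(lut) <- key
  lab <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i]) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (!dx && !dy && !dz) next
        k <- paste(coords[v, 1] + dx, coords[v, 2] + dy, coords[v, 3] + dz)
        j <- lut[k]
        if (!is.na(j) && !lab[j]) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}
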