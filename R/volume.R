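#' Voxel volume container
#'
#' A minimal container for a 3D scalar grid with isotropic voxel spacing.
#' Intensities are relative mass density in arbitrary units (a.u.): the
#' phase-retrieval scaling of the reconstruction is uncalibrated, so no
#' absolute density unit is ever attached.
#'
#' @param data numeric 3D array.
#' @param voxel_size isotropic voxel edge length in micrometres.
#' @return an object of class `voxel_volume`: a list with elements `data`
#'   (3D array) and `voxel_size` (um).
#' @export
voxel_volume <- function(data, voxel_size = 0.35) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (um)")
  structure(list(data = data, voxel_size = voxel_size),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %.3g um/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  intensity range [%.4g, %.4g] a.u.\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

as_volume_data <- function(x) {
  if (inherits(x, "voxel_volume")) x$data else x
}

#' Write a volume as a multi-page 32-bit float TIFF stack
#'
#' Pages are z-slices. Float TIFF samples must lie in [0, 1], so the data
#' are stored linearly rescaled; the intensity range and the voxel size go
#' to a small JSON sidecar `<path>.json` (the TIFF writer exposes no
#' free-text tag), from which [read_volume_tiff()] restores the original
#' scale.
#'
#' @param vol a [voxel_volume()].
#' @param path output file path (`.tif`).
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  lo <- min(vol$data)
  hi <- max(vol$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]),
                  function(z) (vol$data[, , z] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(voxel_size_um = vol$voxel_size, dim = d,
                            intensity_min = lo, intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path TIFF file path; `<path>.json` must carry `voxel_size_um` and
#'   the intensity scaling.
#' @return a [voxel_volume()].
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  arr <- array(0, dim = c(d2[1], d2[2], length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  meta_path <- paste0(path, ".json")
  vs <- 0.35; lo <- 0; scale <- 1
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    vs <- as.numeric(meta$voxel_size_um)
    if (!is.null(meta$intensity_min)) lo <- as.numeric(meta$intensity_min)
    if (!is.null(meta$intensity_scale))
      scale <- as.numeric(meta$intensity_scale)
  }
  voxel_volume(arr * scale + lo, voxel_size = vs)
}

#' 3D connected-component labelling
#'
#' Labels the maximal connected sets of a binary volume under 6-, 18- or
#' 26-adjacency. 26-connectivity (faces, edges and corners) is the
#' conventional choice for foreground pore objects.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of the same shape; 0 = background, components are
#'   numbered 1..n; the number of components is in attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  .cc_label_cpp(as.logical(mask), as.integer(dim(mask)),
                as.integer(connectivity))
}

#' Euclidean distance transform (voxel units)
#'
#' Exact Euclidean distance from every voxel to the nearest `TRUE` voxel of
#' `sites`, computed with the separable lower-envelope algorithm. Distances
#' are in voxels; multiply by the voxel size for micrometres.
#'
#' @param sites logical 3D array of target voxels.
#' @param squared return squared distances (default `FALSE`).
#' @return numeric array of distances; `Inf` where `sites` is empty.
#' @export
distance_transform <- function(sites, squared = FALSE) {
  stopifnot(is.array(sites), length(dim(sites)) == 3L)
  d2 <- .edt_sq_cpp(as.logical(sites), as.integer(dim(sites)))
  if (squared) d2 else sqrt(d2)
}

# Morphological helpers built on the EDT (ball structuring element, radius
# in voxels).
dilate_ball <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d2 <- .edt_sq_cpp(as.logical(mask), as.integer(dim(mask)))
  out <- d2 <= radius^2
  dim(out) <- dim(mask)
  out
}

erode_ball <- function(mask, radius) {
  if (radius <= 0) return(mask)
  !dilate_ball(!mask, radius)
}

# Closing with correct boundary behaviour: the volume is padded with
# background so dilation clipped at the grid faces cannot leave spurious
# closed regions along the boundary.
close_ball <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- dim(mask)
  p <- as.integer(ceiling(radius) + 1L)
  dp <- d + 2L * p
  padded <- array(FALSE, dim = dp)
  padded[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- mask
  closed <- erode_ball(dilate_ball(padded, radius), radius)
  closed[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]),
         drop = FALSE]
}
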