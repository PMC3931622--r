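#' Relative mass-density distribution (rDMD) within the bone domain
#'
#' Histogram of reconstructed intensities restricted to the bone mask,
#' normalized to unit area (a probability density over a.u. intensity).
#' Because the phase-retrieval scaling is uncalibrated, only relative
#' densities are meaningful; no absolute unit conversion is offered.
#'
#' @param volume a [voxel_volume()] or 3D array.
#' @param bone_mask logical array, non-empty.
#' @param n_bins number of bins (default 256).
#' @param bin_range intensity range covered by the bins; default the
#'   0.05th to 99.95th percentile of the masked intensities, wide enough
#'   that the 0.5th/99.5th percentile descriptors are interior (values
#'   outside the range are clamped into the end bins).
#' @return a `density_distribution`: list with `bin_edges`, `bin_centers`,
#'   `density` (per a.u.), `n_voxels`.
#' @export
compute_rdmd <- function(volume, bone_mask, n_bins = 256L,
                         bin_range = NULL) {
  x <- as_volume_data(volume)[bone_mask]
  if (length(x) == 0) stop("empty bone mask")
  if (is.null(bin_range))
    bin_range <- as.numeric(quantile(x, c(5e-4, 1 - 5e-4), names = FALSE))
  if (bin_range[1] >= bin_range[2])
    bin_range <- range(x) + c(-0.5, 0.5)   # constant input: widen
  edges <- seq(bin_range[1], bin_range[2], length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  width <- diff(edges)[1]
  structure(list(bin_edges = edges, bin_centers = centers,
                 density = counts / (length(x) * width),
                 n_voxels = length(x)),
            class = "density_distribution")
}

# linearly interpolated quantile of a binned density (cumulative curve
# through the bin edges)
binned_quantile <- function(dist, p) {
  w <- diff(dist$bin_edges)
  cum <- c(0, cumsum(dist$density * w))    # CDF at edges
  # first edge where CDF >= p, interpolate within that bin
  i <- findInterval(p, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(w))
  frac <- (p - cum[i]) / pmax(cum[i + 1] - cum[i], .Machine$double.eps)
  dist$bin_edges[i] + pmin(pmax(frac, 0), 1) * w[i]
}

#' Descriptors of a relative mass-density distribution
#'
#' The five BMDD-style descriptors: mean; peak (most frequent value = the
#' centre of the maximal bin); low and high (the 0.5th and 99.5th
#' percentiles, P = 0.005, by linear interpolation of the cumulative
#' curve); and FWHM (distance between the outermost crossings of half the
#' global maximum, linearly interpolated). For multi-modal distributions
#' the FWHM spans all modes; a `bimodal` flag reports whether more than one
#' local maximum survives light smoothing. Ties for the peak return the
#' lowest-intensity tied bin and set the `peak_tie` flag.
#'
#' @param dist a `density_distribution` from [compute_rdmd()].
#' @param p tail probability for low/high (default 0.005).
#' @return list: `mean_r`, `peak_r`, `low_r`, `high_r`, `fwhm_r` (a.u.),
#'   `bimodal`, `peak_tie`.
#' @export
rdmd_descriptors <- function(dist, p = 0.005) {
  stopifnot(inherits(dist, "density_distribution"))
  w <- diff(dist$bin_edges)
  area <- sum(dist$density * w)
  if (abs(area - 1) > 1e-6) stop("distribution is not unit area")
  ctr <- dist$bin_centers
  den <- dist$density

  mean_r <- sum(ctr * den * w)
  dmax <- max(den)
  peaks <- which(den == dmax)
  peak_tie <- length(peaks) > 1
  peak_r <- ctr[peaks[1]]

  low_r <- binned_quantile(dist, p)
  high_r <- binned_quantile(dist, 1 - p)

  # FWHM: outermost crossings of dmax/2
  half <- dmax / 2
  above <- den >= half
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  left <- if (i1 == 1) ctr[1] else {
    # interpolate between bins i1-1 (below) and i1 (above)
    ctr[i1 - 1] + (half - den[i1 - 1]) / (den[i1] - den[i1 - 1]) *
      (ctr[i1] - ctr[i1 - 1])
  }
  right <- if (i2 == length(den)) ctr[length(den)] else {
    ctr[i2] + (den[i2] - half) / (den[i2] - den[i2 + 1]) *
      (ctr[i2 + 1] - ctr[i2])
  }
  fwhm_r <- right - left

  # bimodality: count strict local maxima after 5-bin moving average
  sm <- stats::filter(den, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  n_modes <- sum(diff(sign(diff(sm))) < 0 & sm[2:(length(sm) - 1)] >
                   0.1 * max(sm))
  list(mean_r = mean_r, peak_r = peak_r, low_r = low_r, high_r = high_r,
       fwhm_r = fwhm_r, bimodal = n_modes > 1, peak_tie = peak_tie)
}

#' Write an rDMD as a two-column CSV
#' @param dist a `density_distribution`.
#' @param path output path.
#' @export
write_rdmd_csv <- function(dist, path) {
  write.csv(data.frame(bin_center_au = dist$bin_centers,
                       density = dist$density), path, row.names = FALSE)
  invisible(path)
}
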