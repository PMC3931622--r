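#' Acquisition geometry for in-line phase-contrast imaging
#'
#' Defaults are the study settings: 16.874 keV, 282 mm propagation
#' (sample-detector) distance, 0.35 um detector pixels, 1201 projections
#' over 360 degrees, and delta/beta = 199 for cortical bone at this energy.
#' The wavelength is derived as lambda = hc/E (hc = 1.23984 keV nm), which
#' gives 0.0735 nm at the default energy.
#'
#' @param energy_kev photon energy in keV.
#' @param propagation_distance_mm sample-detector distance in mm (>= 0).
#' @param pixel_size_um detector pixel (= voxel) size in um.
#' @param n_projections number of projections.
#' @param angular_range_deg total rotation range in degrees (180 or 360).
#' @param delta_beta ratio of refractive index decrement to absorption
#'   index (> 0).
#' @return an `acq_geometry` list; element `wavelength_nm` is derived.
#' @export
acquisition_geometry <- function(energy_kev = 16.874,
                                 propagation_distance_mm = 282,
                                 pixel_size_um = 0.35,
                                 n_projections = 1201L,
                                 angular_range_deg = 360,
                                 delta_beta = 199) {
  if (energy_kev <= 0) stop("energy must be > 0")
  if (propagation_distance_mm < 0) stop("propagation distance must be >= 0")
  if (delta_beta <= 0) stop("delta_beta must be > 0")
  structure(list(energy_kev = energy_kev,
                 wavelength_nm = HC_KEV_NM / energy_kev,
                 propagation_distance_mm = propagation_distance_mm,
                 pixel_size_um = pixel_size_um,
                 n_projections = as.integer(n_projections),
                 angular_range_deg = angular_range_deg,
                 delta_beta = delta_beta),
            class = "acq_geometry")
}

#' Projection angles for a geometry
#' @param geometry an [acquisition_geometry()].
#' @return angles in degrees, evenly spaced over the angular range
#'   (endpoint excluded).
#' @export
projection_angles <- function(geometry) {
  n <- geometry$n_projections
  geometry$angular_range_deg * (seq_len(n) - 1) / n
}

# FFT sample frequencies (cycles per unit), numpy fftfreq convention.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}

# Free-space Fresnel propagation of a complex field (angular spectrum,
# paraxial transfer function), zero-padded to twice the field size with
# vacuum (value 1) fill to avoid wrap-around fringes.
fresnel_propagate <- function(field, wavelength_um, distance_um,
                              pixel_um) {
  if (distance_um == 0) return(field)
  d <- dim(field)
  np <- 2L * d
  pad <- matrix(complex(real = 1, imaginary = 0), np[1], np[2])
  i0 <- floor((np[1] - d[1]) / 2); j0 <- floor((np[2] - d[2]) / 2)
  pad[i0 + seq_len(d[1]), j0 + seq_len(d[2])] <- field
  fx <- fft_freq(np[1], pixel_um)
  fy <- fft_freq(np[2], pixel_um)
  H <- exp(-1i * pi * wavelength_um * distance_um *
             outer(fx^2, fy^2, `+`))
  out <- fft(fft(pad) * H, inverse = TRUE) / prod(np)
  out[i0 + seq_len(d[1]), j0 + seq_len(d[2])]
}

# Parallel-beam line integrals of a 3D array about the z axis.
# Returns, for one angle (radians), a (n_u x n_z) matrix of sums along rays
# in the x-y plane (bilinear interpolation, 1-voxel ray step, values in
# array units times voxels). Multiply by the voxel size for physical units.
project_slicewise <- function(arr, theta, z_chunk = 64L) {
  d <- dim(arr)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  nu <- nx
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  tmax <- ceiling(sqrt(nx^2 + ny^2) / 2)
  tt <- seq(-tmax, tmax)
  uu <- seq_len(nu) - (nu + 1) / 2
  ct <- cos(theta); st <- sin(theta)
  X <- outer(uu * ct, -tt * st, `+`) + cx       # nu x nt
  Y <- outer(uu * st, tt * ct, `+`) + cy
  i0 <- floor(X); j0 <- floor(Y)
  wx <- X - i0; wy <- Y - j0
  valid <- i0 >= 1 & i0 <= nx - 1 & j0 >= 1 & j0 <= ny - 1
  i0[!valid] <- 1L; j0[!valid] <- 1L
  l00 <- (j0 - 1) * nx + i0
  w00 <- (1 - wx) * (1 - wy) * valid
  w10 <- wx * (1 - wy) * valid
  w01 <- (1 - wx) * wy * valid
  w11 <- wx * wy * valid
  nt <- length(tt)
  dim(arr) <- c(nx * ny, nz)
  proj <- matrix(0, nu, nz)
  for (z1 in seq(1L, nz, by = z_chunk)) {
    zi <- z1:min(nz, z1 + z_chunk - 1L)
    V <- arr[, zi, drop = FALSE]
    P <- array(0, dim = c(nu, nt, length(zi)))
    for (k in seq_along(zi)) {
      v <- V[, k]
      S <- w00 * v[l00] + w10 * v[l00 + 1L] +
        w01 * v[l00 + nx] + w11 * v[l00 + nx + 1L]
      P[, , k] <- S
    }
    proj[, zi] <- colSums(aperm(P, c(2, 1, 3)))
  }
  proj
}

#' Simulate near-field phase-contrast radiographs
#'
#' Forward model of in-line propagation imaging with a parallel beam: per
#' projection angle, line integrals of the refractive index decrement
#' (delta) and absorption index (beta) are computed through the volume, the
#' complex transmittance exp(-2 pi/lambda (i integral(delta) +
#' integral(beta))) is formed, propagated over the sample-detector distance
#' by the angular-spectrum Fresnel propagator, and recorded as the squared
#' modulus (flat-corrected intensity I/I0).
#'
#' @param delta a [voxel_volume()] or 3D array of refractive index
#'   decrement values (dimensionless).
#' @param geometry an [acquisition_geometry()]; its pixel size must equal
#'   the volume voxel size when `delta` is a `voxel_volume`.
#' @param beta optional 3D array of absorption index values; default
#'   `delta / geometry$delta_beta` (homogeneous-object assumption).
#' @return a `projection_set`: list with `intensities` (nu x nz x n_angles
#'   array), `angles_deg`, `geometry`.
#' @export
forward_project <- function(delta, geometry, beta = NULL) {
  if (inherits(delta, "voxel_volume")) {
    if (abs(delta$voxel_size - geometry$pixel_size_um) > 1e-12)
      stop("voxel size and detector pixel size differ")
    delta <- delta$data
  }
  stopifnot(is.array(delta), length(dim(delta)) == 3L)
  if (is.null(beta)) beta <- delta / geometry$delta_beta
  h <- geometry$pixel_size_um
  lam_um <- geometry$wavelength_nm * 1e-3
  D_um <- geometry$propagation_distance_mm * 1e3
  angles <- projection_angles(geometry)
  d <- dim(delta)
  out <- array(0, dim = c(d[1], d[3], length(angles)))
  same_beta <- identical(beta, delta / geometry$delta_beta)
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    p_delta <- project_slicewise(delta, th) * h   # um
    p_beta <- if (same_beta) p_delta / geometry$delta_beta
      else project_slicewise(beta, th) * h
    phase <- -2 * pi / lam_um * p_delta
    amp <- exp(-2 * pi / lam_um * p_beta)
    field <- amp * exp(1i * phase)
    field <- fresnel_propagate(field, lam_um, D_um, h)
    out[, , a] <- Mod(field)^2
  }
  structure(list(intensities = out, angles_deg = angles,
                 geometry = geometry), class = "projection_set")
}

#' Paganin single-distance phase retrieval
#'
#' Applies, per projection, the low-pass Fourier filter
#' \deqn{H(k) = 1 / (1 + (\lambda D (\delta/\beta) / 4\pi) |k|^2)}
#' (with |k| the angular spatial frequency, 2 pi f) to the flat-corrected
#' intensity, then takes the negative logarithm. The result equals
#' mu * T, the attenuation coefficient times the projected thickness of a
#' homogeneous object; divide by mu = 4 pi beta / lambda (per um) for
#' thickness in um. The retrieval is only quantitative in the near-field
#' regime.
#'
#' @param projections a `projection_set` (intensities strictly positive) or
#'   a single intensity matrix.
#' @param geometry required when `projections` is a bare matrix.
#' @param output `"mu_thickness"` (default, -log of the filtered intensity)
#'   or `"thickness"` (um; requires `beta`).
#' @param beta absorption index used to scale to thickness.
#' @return array of retrieved maps with the same layout as the input
#'   intensities.
#' @export
paganin_retrieve <- function(projections, geometry = NULL,
                             output = c("mu_thickness", "thickness"),
                             beta = NULL) {
  output <- match.arg(output)
  if (inherits(projections, "projection_set")) {
    geometry <- projections$geometry
    ints <- projections$intensities
  } else {
    if (is.null(geometry)) stop("geometry required for bare intensities")
    ints <- projections
  }
  single <- length(dim(ints)) == 2L
  if (single) ints <- array(ints, dim = c(dim(ints), 1L))
  if (any(ints <= 0)) stop("intensities must be strictly positive")
  lam_um <- geometry$wavelength_nm * 1e-3
  D_um <- geometry$propagation_distance_mm * 1e3
  h <- geometry$pixel_size_um
  d <- dim(ints)
  # |k|^2 = (2 pi f)^2  =>  coefficient pi * lambda * D * (delta/beta) * f^2
  coef <- pi * lam_um * D_um * geometry$delta_beta
  np <- 2L * d[1:2]
  fx <- fft_freq(np[1], h); fy <- fft_freq(np[2], h)
  H <- 1 / (1 + coef * outer(fx^2, fy^2, `+`))
  out <- array(0, dim = d)
  i0 <- floor((np[1] - d[1]) / 2); j0 <- floor((np[2] - d[2]) / 2)
  for (a in seq_len(d[3])) {
    pad <- matrix(1, np[1], np[2])
    pad[i0 + seq_len(d[1]), j0 + seq_len(d[2])] <- ints[, , a]
    filt <- Re(fft(fft(pad) * H, inverse = TRUE) / prod(np))
    filt <- filt[i0 + seq_len(d[1]), j0 + seq_len(d[2])]
    if (any(filt <= 0))
      stop("non-positive intensity after Paganin filtering; input invalid ",
           "or propagation distance too large for the near field")
    out[, , a] <- -log(filt)
  }
  if (output == "thickness") {
    if (is.null(beta)) stop("`beta` needed for thickness output")
    mu <- 4 * pi * beta / lam_um        # per um
    out <- out / mu
  }
  if (single) out <- out[, , 1]
  out
}

#' The Paganin transfer function
#'
#' Exposed for inspection/testing: the filter value at spatial frequencies
#' `f` (cycles/um).
#' @param f spatial frequency, cycles/um (vector).
#' @param geometry an [acquisition_geometry()].
#' @return filter values in (0, 1]; 1 at f = 0.
#' @export
paganin_filter_value <- function(f, geometry) {
  lam_um <- geometry$wavelength_nm * 1e-3
  D_um <- geometry$propagation_distance_mm * 1e3
  1 / (1 + pi * lam_um * D_um * geometry$delta_beta * f^2)
}

#' Filtered back projection (parallel beam)
#'
#' Slice-by-slice ramp-filtered back projection of a projection stack.
#' Angles must be evenly spaced; a 360-degree set is handled by the uniform
#' weighting pi/n over all views (conjugate rays each contribute half).
#'
#' @param maps projection array (nu x nz x n_angles), e.g. retrieved
#'   mu-thickness maps; values are treated as line integrals in units of
#'   (reconstructed quantity) x um.
#' @param angles_deg projection angles in degrees (evenly spaced).
#' @param pixel_size_um detector pixel size in um.
#' @return a [voxel_volume()] of size nu x nu x nz; reconstructed values
#'   are per-um densities of the projected quantity.
#' @export
fbp_reconstruct <- function(maps, angles_deg, pixel_size_um = 0.35) {
  if (length(dim(maps)) == 2L) maps <- array(maps, dim = c(dim(maps), 1L))
  d <- dim(maps)
  nu <- d[1]; nz <- d[2]; na <- d[3]
  if (na != length(angles_deg)) stop("angle/image count mismatch")
  if (na < 2) stop("need at least 2 angles")
  h <- pixel_size_um

  # ramp filter with zero padding to the next power of two >= 2 nu
  np <- 2^ceiling(log2(2 * nu))
  nu_k <- abs(fft_freq(np, h))            # cycles/um
  filt <- array(0, dim = d)
  for (a in seq_len(na)) {
    P <- rbind(matrix(maps[, , a], nu, nz), matrix(0, np - nu, nz))
    Q <- Re(mvfft(mvfft(P) * nu_k, inverse = TRUE) / np)
    filt[, , a] <- Q[seq_len(nu), ]
  }

  xs <- seq_len(nu) - (nu + 1) / 2
  X <- matrix(xs, nu, nu)
  Y <- matrix(xs, nu, nu, byrow = TRUE)
  recon <- array(0, dim = c(nu, nu, nz))
  wsum <- pi / na
  for (a in seq_len(na)) {
    th <- angles_deg[a] * pi / 180
    U <- X * cos(th) + Y * sin(th) + (nu + 1) / 2
    iu <- floor(U)
    wu <- U - iu
    ok <- iu >= 1 & iu <= nu - 1
    iu[!ok] <- 1L
    w1 <- (1 - wu) * ok
    w2 <- wu * ok
    for (z in seq_len(nz)) {
      q <- filt[, z, a]
      recon[, , z] <- recon[, , z] + w1 * q[iu] + w2 * q[iu + 1L]
    }
  }
  # pi/na: Riemann weight of the angular integral over [0, pi); a
  # 360-degree set gives the same weight because conjugate views each
  # contribute half
  voxel_volume(recon * wsum, voxel_size = h)
}
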