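#' Lacunar volume distribution descriptor
#'
#' Describes the per-lacuna volume distribution used by the phantom
#' generator. Three families are supported:
#' \describe{
#'   \item{normal}{Gaussian with `mean` and `sd` (um^3); emulates the
#'     near-normal volume histograms of tibial and femoral cortical bone.}
#'   \item{lognormal}{log-normal with `meanlog`, `sdlog` of log(um^3).}
#'   \item{mixture_tail}{Gaussian main component plus a uniform
#'     right tail on `tail_range` carrying `tail_frac` of the mass; emulates
#'     the jaw-bone volume histograms, which are asymmetric with a small
#'     fraction of very large (400-1000 um^3) lacunae.}
#' }
#' Samples are confined to `[floor, ceiling]` um^3 by resampling, so the
#' downstream 50-1000 um^3 lacuna size gate is exercised from both sides.
#'
#' @param family one of `"normal"`, `"lognormal"`, `"mixture_tail"`.
#' @param mean,sd Gaussian location/scale in um^3 (normal and the main
#'   component of mixture_tail).
#' @param meanlog,sdlog log-normal parameters.
#' @param tail_frac fraction of mass in the uniform tail (mixture_tail).
#' @param tail_range numeric length-2, tail support in um^3.
#' @param floor,ceiling hard volume bounds in um^3.
#' @return a `lacuna_dist` descriptor list.
#' @export
lacuna_volume_dist <- function(family = c("normal", "lognormal",
                                          "mixture_tail"),
                               mean = 224, sd = 42,
                               meanlog = log(224), sdlog = 0.4,
                               tail_frac = 0.1, tail_range = c(400, 1000),
                               floor = 20, ceiling = 1500) {
  family <- match.arg(family)
  if (floor >= ceiling) stop("floor must be < ceiling")
  if (family == "mixture_tail") {
    if (tail_frac < 0 || tail_frac > 1)
      stop("tail_frac must be in [0, 1]")
    if (tail_range[1] >= tail_range[2]) stop("invalid tail_range")
  }
  structure(list(family = family, mean = mean, sd = sd, meanlog = meanlog,
                 sdlog = sdlog, tail_frac = tail_frac,
                 tail_range = tail_range, floor = floor, ceiling = ceiling),
            class = "lacuna_dist")
}

#' Sample lacunar volumes
#'
#' Draws `n` per-lacuna volumes (um^3) from a [lacuna_volume_dist()]
#' descriptor. Draws outside `[floor, ceiling]` are resampled.
#'
#' @param dist a `lacuna_dist` descriptor.
#' @param n number of volumes (>= 0).
#' @param seed optional integer; when given, sampling is done in a local,
#'   restored RNG state so surrounding code is unaffected.
#' @return numeric vector of `n` volumes in um^3.
#' @export
sample_lacuna_volumes <- function(dist, n, seed = NULL) {
  if (!inherits(dist, "lacuna_dist")) stop("`dist` must be a lacuna_dist")
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(numeric(0))
  draw <- function(m) {
    switch(dist$family,
      normal = rnorm(m, dist$mean, dist$sd),
      lognormal = rlnorm(m, dist$meanlog, dist$sdlog),
      mixture_tail = {
        tail <- runif(m) < dist$tail_frac
        v <- rnorm(m, dist$mean, dist$sd)
        v[tail] <- runif(sum(tail), dist$tail_range[1], dist$tail_range[2])
        v
      },
      stop("unknown distribution family: ", dist$family)
    )
  }
  run <- function() {
    v <- draw(n)
    bad <- which(v < dist$floor | v > dist$ceiling)
    guard <- 0L
    while (length(bad) > 0L && guard < 1000L) {
      v[bad] <- draw(length(bad))
      bad <- which(v < dist$floor | v > dist$ceiling)
      guard <- guard + 1L
    }
    if (length(bad) > 0L)
      stop("could not confine samples to [floor, ceiling]")
    v
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Phantom specification
#'
#' Parameters of a synthetic cortical-bone core: a cylinder of mineralized
#' matrix (axis = z, the sample-length axis) with a spatially structured
#' multi-modal density field, carved ellipsoidal osteocyte lacunae, carved
#' cylindrical vascular canals, air background, and an optional high-density
#' "glue" artifact blob outside the core.
#'
#' @param grid_shape integer length-3, voxels per axis (x, y, z).
#' @param voxel_size um per voxel (default 0.35, the acquisition value).
#' @param core_radius core radius in um; default fills 90% of the x extent.
#' @param lacuna_count number of lacunae to place (>= 0).
#' @param lacuna_volume_dist a [lacuna_volume_dist()].
#' @param lacuna_aspect_ratios semi-axis ratios (a : b : c), longest first;
#'   lacunae are triaxial ellipsoids with uniformly random orientation.
#' @param canal_spec list of canals, each `list(x, y, radius)` in um with
#'   (x, y) relative to the core axis; canals run the full z extent.
#' @param matrix_density_modes data.frame with columns `mean`, `sd`,
#'   `weight` (a.u.); the tissue field is a patchwork of regions (columnar,
#'   emulating osteonal vs interstitial tissue) drawn from these modes.
#' @param background_level air intensity (a.u.); pore interiors are set to
#'   this level plus matrix-like noise, as pores image at near-air density.
#' @param noise_sd additive Gaussian noise sd used for air and pores (a.u.);
#'   defaults to the mean of the mode sds.
#' @param artifact_region optional `list(x, y, z, radius, mean, sd)` (um and
#'   a.u.): a high-density blob in the background, emulating glue.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 128L),
                         voxel_size = 0.35,
                         core_radius = 0.45 * grid_shape[1] * voxel_size,
                         lacuna_count = 10L,
                         lacuna_volume_dist = lacunaCT::lacuna_volume_dist(),
                         lacuna_aspect_ratios = c(1, 0.7, 0.4),
                         canal_spec = list(),
                         matrix_density_modes = data.frame(
                           mean = c(1170, 1250), sd = c(40, 40),
                           weight = c(0.5, 0.5)),
                         background_level = -100,
                         noise_sd = NULL,
                         artifact_region = NULL,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  if (lacuna_count < 0) stop("lacuna_count must be >= 0")
  if (core_radius <= 0) stop("core_radius must be > 0")
  if (length(canal_spec) > 0 &&
      any(vapply(canal_spec, function(cn) cn$radius <= 0, logical(1))))
    stop("all canal radii must be > 0")
  w <- matrix_density_modes$weight
  if (abs(sum(w) - 1) > 1e-8) stop("matrix mode weights must sum to 1")
  if (any(lacuna_aspect_ratios <= 0)) stop("aspect ratios must be > 0")
  if (is.null(noise_sd)) noise_sd <- mean(matrix_density_modes$sd)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, core_radius = core_radius,
                 lacuna_count = as.integer(lacuna_count),
                 lacuna_volume_dist = lacuna_volume_dist,
                 lacuna_aspect_ratios = lacuna_aspect_ratios /
                   max(lacuna_aspect_ratios),
                 canal_spec = canal_spec,
                 matrix_density_modes = matrix_density_modes,
                 background_level = background_level, noise_sd = noise_sd,
                 artifact_region = artifact_region, seed = as.integer(seed)),
            class = "phantom_spec")
}

# uniform random rotation matrix (via quaternion)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Generate a synthetic bone phantom with ground truth
#'
#' Renders a [phantom_spec()] to a relative mass-density volume and returns
#' the exact ground truth used to build it: per-lacuna table with analytic
#' and voxelized volumes, canal mask, matrix (bone) mask, and the noiseless
#' density field. Matrix, lacuna and canal masks are pairwise disjoint and,
#' together with the background, partition the grid.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [voxel_volume()]) and `truth`
#'   (list: `lacuna_table`, `lacuna_mask`, `lacuna_labels` (integer array,
#'   value i = lacuna id i), `canal_mask`, `matrix_mask`, `density_field`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  h <- spec$voxel_size
  d <- spec$grid_shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r_vox <- spec$core_radius / h

  xs <- seq_len(nx) - cx
  ys <- seq_len(ny) - cy
  core2d <- outer(xs^2, ys^2, `+`) <= r_vox^2        # nx x ny
  core <- array(core2d, dim = d)

  # --- canal masks (vertical cylinders, full z extent) -------------------
  canal2d <- matrix(FALSE, nx, ny)
  for (cn in spec$canal_spec) {
    dx2 <- (xs - cn$x / h)^2
    dy2 <- (ys - cn$y / h)^2
    canal2d <- canal2d | (outer(dx2, dy2, `+`) <= (cn$radius / h)^2)
  }
  canal2d <- canal2d & core2d
  canal_mask <- array(canal2d, dim = d)

  # --- lacunae: sample volumes, place non-overlapping ellipsoids ---------
  n_lc <- spec$lacuna_count
  vols <- sample_lacuna_volumes(spec$lacuna_volume_dist, n_lc)
  ratios <- spec$lacuna_aspect_ratios
  # semi-axes in um: (4/3) pi a b c = V with (a, b, c) = a * ratios
  a_um <- (3 * vols / (4 * pi * ratios[2] * ratios[3]))^(1 / 3)
  semi <- cbind(a_um, a_um * ratios[2], a_um * ratios[3])

  lacuna_mask <- array(FALSE, dim = d)
  lacuna_lab <- array(0L, dim = d)       # ground-truth label per lacuna
  centers <- matrix(NA_real_, n_lc, 3)   # voxel coordinates
  voxel_vols <- numeric(n_lc)

  # voxelize an ellipsoid (semi-axes in voxels, rotation R) into a bounding
  # box; returns index ranges and the inside mask
  voxelize_ellipsoid <- function(c0, ax, R) {
    ri <- ceiling(max(ax)) + 1L
    ix <- max(1L, floor(c0[1]) - ri):min(nx, ceiling(c0[1]) + ri)
    iy <- max(1L, floor(c0[2]) - ri):min(ny, ceiling(c0[2]) + ri)
    iz <- max(1L, floor(c0[3]) - ri):min(nz, ceiling(c0[3]) + ri)
    G <- cbind(rep(ix - c0[1], times = length(iy) * length(iz)),
               rep(rep(iy - c0[2], each = length(ix)), times = length(iz)),
               rep(iz - c0[3], each = length(ix) * length(iy)))
    U <- G %*% R
    inside <- (U[, 1] / ax[1])^2 + (U[, 2] / ax[2])^2 +
      (U[, 3] / ax[3])^2 <= 1
    list(ix = ix, iy = iy, iz = iz,
         sub = array(inside, dim = c(length(ix), length(iy), length(iz))))
  }

  if (n_lc > 0) {
    placed <- 0L
    tries <- 0L
    cap <- 100L * n_lc
    while (placed < n_lc) {
      if (tries >= cap)
        stop("lacuna placement failed after ", cap,
             " retries: spec is overcrowded")
      tries <- tries + 1L
      i <- placed + 1L
      ax <- semi[i, ] / h                  # semi-axes in voxels
      margin <- ax[1] + 2
      if (r_vox - margin <= 0 || nz - 2 * margin <= 0)
        stop("lacuna placement failed: lacunae too large for the core")
      repeat {
        px <- runif(1, -(r_vox - margin), r_vox - margin)
        py <- runif(1, -(r_vox - margin), r_vox - margin)
        if (px^2 + py^2 <= (r_vox - margin)^2) break
      }
      pz <- runif(1, 1 + margin, nz - margin)
      cand <- c(cx + px, cy + py, pz)
      R <- random_rotation()
      # cheap reject: inscribed spheres already overlapping
      if (placed > 0) {
        dd <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                              cand)^2))
        if (any(dd <= semi[seq_len(placed), 3] / h + ax[3])) next
      }
      # exact non-overlap: the candidate inflated by one voxel must be
      # free of other pores, so neighbouring lacunae never touch
      vx_test <- voxelize_ellipsoid(cand, ax + 1, R)
      region_l <- lacuna_mask[vx_test$ix, vx_test$iy, vx_test$iz,
                              drop = FALSE]
      region_c <- canal_mask[vx_test$ix, vx_test$iy, vx_test$iz,
                             drop = FALSE]
      if (any((region_l | region_c) & vx_test$sub)) next
      vx <- voxelize_ellipsoid(cand, ax, R)
      region_l <- lacuna_mask[vx$ix, vx$iy, vx$iz, drop = FALSE]
      lacuna_mask[vx$ix, vx$iy, vx$iz] <- region_l | vx$sub
      region_lab <- lacuna_lab[vx$ix, vx$iy, vx$iz, drop = FALSE]
      region_lab[vx$sub] <- i
      lacuna_lab[vx$ix, vx$iy, vx$iz] <- region_lab
      centers[i, ] <- cand
      voxel_vols[i] <- sum(vx$sub) * h^3
      placed <- placed + 1L
    }
  }

  matrix_mask <- core & !lacuna_mask & !canal_mask

  # --- density field ------------------------------------------------------
  # columnar tissue patches (osteonal vs interstitial): nearest-seed regions
  # in the transverse plane, each patch drawn from one density mode
  modes <- spec$matrix_density_modes
  n_patch <- max(8L, 4L * nrow(modes))
  ang <- runif(n_patch, 0, 2 * pi)
  rad <- r_vox * sqrt(runif(n_patch))
  sx <- rad * cos(ang); sy <- rad * sin(ang)
  patch_mode <- sample.int(nrow(modes), n_patch, replace = TRUE,
                           prob = modes$weight)
  X2 <- matrix(xs, nx, ny)
  Y2 <- matrix(ys, nx, ny, byrow = TRUE)
  best <- matrix(Inf, nx, ny)
  assign2d <- matrix(1L, nx, ny)
  for (p in seq_len(n_patch)) {
    dp <- (X2 - sx[p])^2 + (Y2 - sy[p])^2
    upd <- dp < best
    best[upd] <- dp[upd]
    assign2d[upd] <- patch_mode[p]
  }

  field <- array(spec$background_level, dim = d)   # noiseless field
  mode_mean2d <- matrix(modes$mean[assign2d], nx, ny)
  mode_sd2d <- matrix(modes$sd[assign2d], nx, ny)
  for (z in seq_len(nz)) {
    slab <- field[, , z]
    slab[core2d] <- mode_mean2d[core2d]
    field[, , z] <- slab
  }
  field[lacuna_mask | canal_mask] <- spec$background_level

  art_mask <- array(FALSE, dim = d)
  if (!is.null(spec$artifact_region)) {
    ar <- spec$artifact_region
    if (identical(ar$type, "pool")) {
      # embedding glue pooled at the bottom of the field of view, outside
      # the bone core (cf. the air + glue + bone histogram of real scans)
      z_top <- max(1L, round(ar$z_frac * nz))
      art_mask[, , seq_len(z_top)] <- !core[, , seq_len(z_top)]
    } else {
      axv <- cx + ar$x / h; ayv <- cy + ar$y / h; azv <- ar$z / h
      rr <- ar$radius / h
      ix <- max(1L, floor(axv - rr)):min(nx, ceiling(axv + rr))
      iy <- max(1L, floor(ayv - rr)):min(ny, ceiling(ayv + rr))
      iz <- max(1L, floor(azv - rr)):min(nz, ceiling(azv + rr))
      sub <- outer(outer((ix - axv)^2, (iy - ayv)^2, `+`), (iz - azv)^2,
                   `+`)
      blob <- array(FALSE, dim = d)
      blob[ix, iy, iz] <- sub <= rr^2
      art_mask <- blob & !core
    }
    field[art_mask] <- ar$mean
  }

  # --- render: field + heteroscedastic noise -----------------------------
  vol <- field
  n_tot <- prod(d)
  noise <- rnorm(n_tot)
  sd_arr <- array(spec$noise_sd, dim = d)
  for (z in seq_len(nz)) {
    slab <- sd_arr[, , z]
    slab[core2d] <- mode_sd2d[core2d]
    sd_arr[, , z] <- slab
  }
  sd_arr[lacuna_mask | canal_mask] <- spec$noise_sd
  if (!is.null(spec$artifact_region)) sd_arr[art_mask] <-
    spec$artifact_region$sd
  vol <- vol + array(noise, dim = d) * sd_arr

  tbl <- data.frame(
    id = seq_len(n_lc),
    x_um = if (n_lc) (centers[, 1] - cx) * h else numeric(0),
    y_um = if (n_lc) (centers[, 2] - cy) * h else numeric(0),
    z_um = if (n_lc) centers[, 3] * h else numeric(0),
    a_um = if (n_lc) semi[, 1] else numeric(0),
    b_um = if (n_lc) semi[, 2] else numeric(0),
    c_um = if (n_lc) semi[, 3] else numeric(0),
    analytic_volume_um3 = if (n_lc) (4 / 3) * pi * semi[, 1] * semi[, 2] *
      semi[, 3] else numeric(0),
    voxel_volume_um3 = voxel_vols
  )

  list(volume = voxel_volume(vol, voxel_size = h),
       truth = list(lacuna_table = tbl,
                    lacuna_mask = lacuna_mask,
                    lacuna_labels = lacuna_lab,
                    canal_mask = canal_mask,
                    matrix_mask = matrix_mask,
                    density_field = voxel_volume(field, voxel_size = h)))
}

#' Site-profile phantom specifications
#'
#' Convenience constructor for phantoms emulating the four study groups.
#' Lacunar number density and median volume targets, volume-distribution
#' shape (near-normal for tibia/femur, right-tailed mixture for jaw), and
#' matrix density modes are set per site; the lacuna count is derived from
#' the target density and the expected bone volume of the core.
#'
#' @param site `"tibia"`, `"femur"`, `"jaw_control"` or `"jaw_bronj"`.
#' @param grid_shape voxels per axis.
#' @param voxel_size um (default 0.35).
#' @param seed integer seed.
#' @param n_canals number of vascular canals (default per site).
#' @param canal_radius canal radius in um; by default sized so the canal
#'   volume fraction of bone matches the site's typical vascular porosity.
#' @return a [phantom_spec()].
#' @export
site_phantom_spec <- function(site = c("tibia", "femur", "jaw_control",
                                       "jaw_bronj"),
                              grid_shape = c(192L, 192L, 192L),
                              voxel_size = 0.35, seed = 1L,
                              n_canals = NULL, canal_radius = NULL) {
  site <- match.arg(site)
  prof <- switch(site,
    tibia = list(density_mm3 = 38000, med = 194, sd = 80,
                 family = "normal", tail_frac = 0, ca_v_bv_pct = 5,
                 modes = data.frame(mean = c(1280, 1330), sd = c(35, 35),
                                    weight = c(0.5, 0.5)),
                 canals = 1L),
    femur = list(density_mm3 = 20000, med = 224, sd = 105,
                 family = "normal", tail_frac = 0, ca_v_bv_pct = 8,
                 modes = data.frame(mean = c(1185, 1255), sd = c(40, 40),
                                    weight = c(0.5, 0.5)),
                 canals = 1L),
    jaw_control = list(density_mm3 = 27000, med = 277, sd = 90,
                       family = "mixture_tail", tail_frac = 0.10,
                       ca_v_bv_pct = 7,
                       modes = data.frame(mean = c(1170, 1250),
                                          sd = c(40, 40),
                                          weight = c(0.5, 0.5)),
                       canals = 1L),
    jaw_bronj = list(density_mm3 = 23000, med = 269, sd = 100,
                     family = "mixture_tail", tail_frac = 0.10,
                     ca_v_bv_pct = 7,
                     modes = data.frame(mean = c(1190, 1265), sd = c(40, 40),
                                        weight = c(0.5, 0.5)),
                     canals = 1L))
  if (is.null(n_canals)) n_canals <- prof$canals

  h <- voxel_size
  core_radius <- 0.45 * grid_shape[1] * h       # um; core fills 90% of x
  height_um <- grid_shape[3] * h

  # canal radius from the target vascular porosity t (%):
  # n * r^2 / (R^2 - n r^2) = t/100  =>  r = R sqrt(t / (n (100 + t)))
  if (is.null(canal_radius) && n_canals > 0) {
    t <- prof$ca_v_bv_pct
    canal_radius <- core_radius * sqrt(t / (n_canals * (100 + t)))
  }

  # canal positions: ring at 50% core radius, deterministic given count
  canals <- list()
  if (n_canals > 0) {
    th <- 2 * pi * (seq_len(n_canals) - 1) / n_canals + 0.3
    for (k in seq_len(n_canals))
      canals[[k]] <- list(x = 0.5 * core_radius * cos(th[k]),
                          y = 0.5 * core_radius * sin(th[k]),
                          radius = canal_radius)
  }
  canal_vol <- n_canals * pi * canal_radius^2 * height_um
  bv_um3 <- pi * core_radius^2 * height_um - canal_vol
  count <- max(0L, as.integer(round(prof$density_mm3 * bv_um3 * 1e-9)))

  # main-component mean set so the distribution median hits the target
  if (prof$family == "mixture_tail") {
    mu <- prof$med - stats::qnorm(0.5 / (1 - prof$tail_frac)) * prof$sd
    dist <- lacuna_volume_dist("mixture_tail", mean = mu, sd = prof$sd,
                               tail_frac = prof$tail_frac,
                               tail_range = c(400, 1000))
  } else {
    dist <- lacuna_volume_dist("normal", mean = prof$med, sd = prof$sd)
  }

  phantom_spec(grid_shape = grid_shape, voxel_size = h,
               core_radius = core_radius, lacuna_count = count,
               lacuna_volume_dist = dist,
               canal_spec = canals,
               matrix_density_modes = prof$modes,
               background_level = -100,
               artifact_region = list(type = "pool", z_frac = 0.22,
                                      mean = 200, sd = 60),
               seed = seed)
}

#' Write a ground-truth lacuna table as CSV
#' @param truth the `truth` element returned by [generate_phantom()].
#' @param path output CSV path.
#' @export
write_ground_truth_csv <- function(truth, path) {
  write.csv(truth$lacuna_table, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a phantom spec to / from a YAML config file
#'
#' The file is a flat key/value document mirroring the [phantom_spec()]
#' fields; the volume distribution and the density modes are nested
#' mappings. A spec written and read back compares equal.
#'
#' @param spec a `phantom_spec`.
#' @param path YAML file path.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  lst <- unclass(spec)
  lst$lacuna_volume_dist <- unclass(lst$lacuna_volume_dist)
  lst$matrix_density_modes <- as.list(lst$matrix_density_modes)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$lacuna_volume_dist <- structure(lst$lacuna_volume_dist,
                                      class = "lacuna_dist")
  lst$matrix_density_modes <- as.data.frame(lst$matrix_density_modes)
  structure(lst, class = "phantom_spec")
}
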