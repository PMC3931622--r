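geom_near <- function(n_proj = 1L, D = 30)
  acquisition_geometry(propagation_distance_mm = D, n_projections = n_proj)

test_that("wavelength is derived from energy", {
  g <- acquisition_geometry()
  expect_equal(g$wavelength_nm, 1.23984 / 16.874)
  expect_equal(round(g$wavelength_nm, 4), 0.0735)
  expect_error(acquisition_geometry(energy_kev = -1), "energy")
  expect_error(acquisition_geometry(delta_beta = 0), "delta_beta")
})

test_that("vacuum projects to unit intensity at any distance", {
  vol <- voxel_volume(array(0, c(24, 24, 6)), 0.35)
  ps <- forward_project(vol, acquisition_geometry(n_projections = 3L))
  expect_equal(max(abs(ps$intensities - 1)), 0)
})

test_that("contact-plane images obey the Beer-Lambert law", {
  g0 <- acquisition_geometry(propagation_distance_mm = 0,
                             n_projections = 1L)
  beta <- 5e-9
  delta <- array(0, c(32, 32, 8))
  delta[, 10:21, ] <- beta * g0$delta_beta      # 12-voxel slab along y
  ps <- forward_project(voxel_volume(delta, 0.35), g0)
  T_um <- 12 * 0.35
  lam_um <- g0$wavelength_nm * 1e-3
  expect_equal(ps$intensities[16, 4, 1], exp(-4 * pi * beta * T_um / lam_um),
               tolerance = 1e-10)
})

test_that("propagation produces edge-enhancement fringes matching a direct Fresnel integral", {
  # 1D edge: half-plane of constant phase shift, propagated 30 mm
  n <- 256
  h <- 0.35
  lam_um <- acquisition_geometry()$wavelength_nm * 1e-3
  D_um <- 30e3
  phase <- rep(0, n)
  phase[(n / 2):n] <- -0.5
  # package propagator (2D routine on an edge profile replicated along y)
  F2 <- matrix(exp(1i * phase), n, 16)
  out <- lacunaCT:::fresnel_propagate(F2, lam_um, D_um, h)
  prof <- Mod(out[, 8])^2
  # independent closed-form edge diffraction (Fresnel integrals)
  edge <- n / 2           # edge sits between samples edge-1 and edge
  x <- (seq_len(n) - edge + 0.5) * h
  bprof <- Mod(fresnel_edge_analytic(exp(0i), exp(-0.5i), x,
                                     lam_um, D_um))^2
  # fringes: overshoot above 1 on the unshifted side, undershoot below
  expect_gt(max(prof[(edge - 20):(edge - 2)]), 1.02)
  expect_lt(min(prof[(edge + 2):(edge + 20)]), 0.98)
  # agreement with the closed form near the edge; the tolerance allows for
  # pixel sampling of the finest fringes and the finite field window
  idx <- (edge - 30):(edge + 30)
  expect_lt(max(abs(prof[idx] - bprof[idx])), 0.12)
  # fringe extrema sit at the analytic positions (+- 1 sample)
  expect_lt(abs(which.max(prof[idx]) - which.max(bprof[idx])), 2)
  expect_lt(abs(which.min(prof[idx]) - which.min(bprof[idx])), 2)
})

test_that("Paganin filter preserves DC and contracts all other frequencies", {
  g <- acquisition_geometry()   # delta/beta = 199, 282 mm
  expect_equal(paganin_filter_value(0, g), 1)
  f <- seq(0.01, 1 / (2 * 0.35), length.out = 50)
  v <- paganin_filter_value(f, g)
  expect_true(all(v < 1 & v > 0))
  expect_true(all(diff(v) < 0))
})

test_that("uniform unit intensity retrieves zero thickness", {
  u <- array(1, c(32, 32, 2))
  r <- paganin_retrieve(u, geom_near())
  expect_equal(max(abs(r)), 0)
})

test_that("Paganin retrieval round-trips a homogeneous ellipsoid in the near field", {
  n <- 96
  del <- 1e-6
  ax <- c(24, 18, 14)
  arr <- make_ellipsoid_delta(n, ax, del)
  g <- geom_near(n_proj = 1L, D = 30)
  ps <- forward_project(voxel_volume(arr, 0.35), g)
  th <- paganin_retrieve(ps, output = "thickness", beta = del / 199)
  # analytic projected thickness at angle 0 (rays along y)
  c0 <- (n + 1) / 2
  xs <- (seq_len(n) - c0) / ax[1]
  zs <- (seq_len(n) - c0) / ax[3]
  q <- pmax(1 - outer(xs^2, zs^2, `+`), 0)
  true_T <- 2 * ax[2] * 0.35 * sqrt(q)
  rms <- sqrt(mean((th[, , 1] - true_T)^2)) / max(true_T)
  expect_lt(rms, 0.03)
})

test_that("retrieval rejects invalid intensities", {
  u <- array(1, c(16, 16, 1))
  u[4, 4, 1] <- -0.2
  expect_error(paganin_retrieve(u, geom_near()), "strictly positive")
})

test_that("FBP reconstructs position, value and is linear", {
  n <- 64
  h <- 0.35
  arr <- array(0, c(n, n, 2))
  c0 <- (n + 1) / 2
  r2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`)
  arr[, , 1] <- (r2 <= 20^2) * 2.5
  arr[, , 2] <- (r2 <= 20^2) * 2.5
  angs <- seq(0, 360, length.out = 145)[1:144]
  sino <- array(0, c(n, 2, 144))
  for (a in seq_along(angs))
    sino[, , a] <- lacunaCT:::project_slicewise(arr, angs[a] * pi / 180) * h
  rec <- fbp_reconstruct(sino, angs, h)

  # interior mean within 5% of the true value
  interior <- r2 <= 14^2
  expect_lt(abs(mean(rec$data[, , 1][interior]) / 2.5 - 1), 0.05)

  # 180-degree range agrees within 1% RMS
  angs180 <- seq(0, 180, length.out = 73)[1:72]
  sino180 <- array(0, c(n, 2, 72))
  for (a in seq_along(angs180))
    sino180[, , a] <- lacunaCT:::project_slicewise(arr,
                                                   angs180[a] * pi / 180) * h
  rec180 <- fbp_reconstruct(sino180, angs180, h)
  supp <- r2 <= 24^2
  rel <- sqrt(mean((rec$data[, , 1][supp] - rec180$data[, , 1][supp])^2)) /
    max(abs(rec$data))
  expect_lt(rel, 0.01)

  # linearity and the zero sinogram
  rec3 <- fbp_reconstruct(3 * sino, angs, h)
  expect_equal(rec3$data, 3 * rec$data, tolerance = 1e-12)
  zero <- fbp_reconstruct(0 * sino, angs, h)
  expect_equal(max(abs(zero$data)), 0)

  # an off-centre ball peaks at its true position (+- 1 voxel)
  arr2 <- array(0, c(n, n, 1))
  arr2[40:44, 20:24, 1] <- 1
  sino2 <- array(0, c(n, 1, 144))
  for (a in seq_along(angs))
    sino2[, , a] <- lacunaCT:::project_slicewise(arr2, angs[a] * pi / 180) * h
  recb <- fbp_reconstruct(sino2, angs, h)
  w <- which(recb$data[, , 1] == max(recb$data[, , 1]), arr.ind = TRUE)
  expect_lte(abs(w[1, 1] - 42), 1)
  expect_lte(abs(w[1, 2] - 22), 1)

  expect_error(fbp_reconstruct(sino, angs[-1], h), "mismatch")
})

test_that("axial slices of a symmetric phantom have low azimuthal variation", {
  n <- 64
  h <- 0.35
  arr <- array(0, c(n, n, 1))
  c0 <- (n + 1) / 2
  r2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`)
  arr[, , 1] <- (r2 <= 22^2) * 1
  angs <- seq(0, 360, length.out = 181)[1:180]
  sino <- array(0, c(n, 1, 180))
  for (a in seq_along(angs))
    sino[, , a] <- lacunaCT:::project_slicewise(arr, angs[a] * pi / 180) * h
  rec <- fbp_reconstruct(sino, angs, h)$data[, , 1]
  # ring at radius 12-14: relative azimuthal variation
  ring <- r2 >= 12^2 & r2 <= 14^2
  vals <- rec[ring]
  expect_lt(sd(vals) / mean(vals), 0.02)
})
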