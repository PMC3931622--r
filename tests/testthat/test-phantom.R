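test_that("empty phantom spec yields an empty lacuna table", {
  sp <- phantom_spec(grid_shape = c(48L, 48L, 48L), lacuna_count = 0L,
                     seed = 1)
  ph <- generate_phantom(sp)
  expect_equal(nrow(ph$truth$lacuna_table), 0)
  expect_false(any(ph$truth$lacuna_mask))
})

test_that("voxelized ellipsoid volumes match the analytic volume", {
  # semi-axes (5, 4, 2) um: (4/3) pi * 40 = 167.55 um^3
  v <- (4 / 3) * pi * 5 * 4 * 2
  sp <- phantom_spec(grid_shape = c(128L, 128L, 128L), lacuna_count = 10L,
                     lacuna_volume_dist = lacuna_volume_dist(
                       "normal", mean = v, sd = 1e-9, floor = 100,
                       ceiling = 200),
                     lacuna_aspect_ratios = c(5, 4, 2), seed = 42)
  ph <- generate_phantom(sp)
  tbl <- ph$truth$lacuna_table
  expect_equal(nrow(tbl), 10)
  expect_equal(tbl$analytic_volume_um3, rep(v, 10), tolerance = 1e-6)
  expect_true(all(abs(tbl$voxel_volume_um3 / tbl$analytic_volume_um3 - 1)
                  < 0.15))
})

test_that("identical spec and seed give bit-identical phantoms", {
  sp <- phantom_spec(grid_shape = c(48L, 48L, 48L), lacuna_count = 3L,
                     lacuna_volume_dist = lacuna_volume_dist(
                       "normal", mean = 60, sd = 10),
                     seed = 7)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$lacuna_mask, b$truth$lacuna_mask)
  expect_identical(a$truth$lacuna_table, b$truth$lacuna_table)
})

test_that("masks are pairwise disjoint and partition the grid", {
  sp <- site_phantom_spec("jaw_control", grid_shape = c(96L, 96L, 96L),
                          seed = 3)
  ph <- generate_phantom(sp)
  tr <- ph$truth
  expect_false(any(tr$matrix_mask & tr$lacuna_mask))
  expect_false(any(tr$matrix_mask & tr$canal_mask))
  expect_false(any(tr$lacuna_mask & tr$canal_mask))
  n_bg <- prod(dim(ph$volume$data)) - sum(tr$matrix_mask) -
    sum(tr$lacuna_mask) - sum(tr$canal_mask)
  expect_gte(n_bg, 0)
  # ground-truth labels agree with the mask
  expect_identical(tr$lacuna_labels > 0, tr$lacuna_mask)
})

test_that("lacuna volume sampler hits its distributional targets", {
  # empty draw
  expect_length(sample_lacuna_volumes(lacuna_volume_dist(), 0), 0)

  # location: normal centred on the femoral median volume
  d1 <- lacuna_volume_dist("normal", mean = 224, sd = 42)
  v1 <- sample_lacuna_volumes(d1, 1e4, seed = 11)
  expect_lt(abs(median(v1) / 224 - 1), 0.03)
  expect_true(all(v1 >= d1$floor & v1 <= d1$ceiling))

  # tail mass of the jaw-like mixture (binomial: 0.10 +- 0.01 at n = 1e4)
  d2 <- lacuna_volume_dist("mixture_tail", mean = 250, sd = 60,
                           tail_frac = 0.10, tail_range = c(400, 1000))
  v2 <- sample_lacuna_volumes(d2, 1e4, seed = 12)
  frac <- mean(v2 > 400)
  expect_lt(abs(frac - 0.10), 0.012)

  expect_error(sample_lacuna_volumes(
    structure(list(family = "cauchy"), class = "lacuna_dist"), 5),
    "family")
})

test_that("matrix density histogram is bimodal for a two-mode spec", {
  sp <- phantom_spec(grid_shape = c(96L, 96L, 96L), lacuna_count = 0L,
                     matrix_density_modes = data.frame(
                       mean = c(1170, 1250), sd = c(25, 25),
                       weight = c(0.5, 0.5)),
                     seed = 5)
  ph <- generate_phantom(sp)
  x <- ph$volume$data[ph$truth$matrix_mask]
  h <- hist(x, breaks = seq(min(x), max(x), length.out = 65), plot = FALSE)
  sm <- stats::filter(h$counts, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  n_modes <- sum(diff(sign(diff(sm))) < 0 & sm[2:(length(sm) - 1)] >
                   0.1 * max(sm))
  expect_equal(n_modes, 2)
})

test_that("overcrowded specs fail with a clear error", {
  sp <- phantom_spec(grid_shape = c(48L, 48L, 48L), lacuna_count = 40L,
                     lacuna_volume_dist = lacuna_volume_dist(
                       "normal", mean = 224, sd = 10),
                     seed = 1)
  expect_error(generate_phantom(sp), "overcrowded|too large")
})

test_that("spec validation rejects inconsistent inputs", {
  expect_error(phantom_spec(lacuna_count = -1), "lacuna_count")
  expect_error(phantom_spec(matrix_density_modes = data.frame(
    mean = c(1, 2), sd = c(1, 1), weight = c(0.5, 0.6))), "sum to 1")
  expect_error(phantom_spec(canal_spec = list(list(x = 0, y = 0,
                                                   radius = -2))),
               "radii")
  expect_error(lacuna_volume_dist(floor = 100, ceiling = 50), "floor")
})
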