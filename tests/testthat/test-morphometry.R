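test_that("lacunar metrics follow their definitions", {
  tbl <- data.frame(volume_um3 = c(100, 200, 300))
  # bone volume passed as a voxel count: 5e-4 mm^3 at 1 um voxels
  bv_vox <- 5e-4 * 1e9
  lm <- lacunar_metrics(tbl, bv_vox, voxel_size = 1)
  expect_equal(lm$lc_v_med_um3, 200)
  expect_equal(lm$lc_v_var_1000um6, var(c(100, 200, 300)) / 1000)
  # 3 lacunae in 5e-4 mm^3 -> 6000 mm^-3; and with 10 lacunae -> 20000
  expect_equal(lm$n_lc_bv_1000mm3, 6)
  lm10 <- lacunar_metrics(data.frame(volume_um3 = rep(100, 10)), bv_vox, 1)
  expect_equal(lm10$n_lc_bv_1000mm3, 20)
  expect_equal(lm10$lc_tv_bv_pct, 100 * 1000 / 5e5)
  expect_error(lacunar_metrics(tbl, 0, 1), "empty bone")
})

test_that("sample variance uses the n-1 denominator", {
  set.seed(3)
  v <- rnorm(25, 200, 40)
  lm <- lacunar_metrics(data.frame(volume_um3 = v), 1e6, 0.35)
  two_pass <- sum((v - mean(v))^2) / (length(v) - 1)
  expect_equal(lm$lc_v_var_1000um6 * 1000, two_pass, tolerance = 1e-12)
})

test_that("lacunar spacing is exact on a one-voxel shell", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE                     # the lacuna
  shell <- array(FALSE, c(5, 5, 5))
  shell[2:4, 2:4, 2:4] <- TRUE
  shell[3, 3, 3] <- FALSE
  # bone restricted to the 6 face-neighbours: all at distance 1
  bone <- array(FALSE, c(5, 5, 5))
  bone[c(2, 4), 3, 3] <- TRUE
  bone[3, c(2, 4), 3] <- TRUE
  bone[3, 3, c(2, 4)] <- TRUE
  expect_equal(lacunar_spacing(bone, m, 0.35), 0.35)
  expect_error(lacunar_spacing(bone, array(FALSE, c(5, 5, 5)), 0.35),
               "empty lacuna")
})

test_that("median EDT distance matches brute force on random masks", {
  set.seed(17)
  for (rep in 1:3) {
    lac <- random_mask(c(20, 20, 20), fill = 0.01)
    if (!any(lac)) next
    bone <- random_mask(c(20, 20, 20), fill = 0.4) & !lac
    d <- distance_transform(lac)
    fast <- median(d[bone])
    brute <- median(brute_nearest_distances(bone, lac))
    expect_equal(fast, brute, tolerance = 1e-12)
  }
})

test_that("spacing falls when lacunae are added and scales with voxel size", {
  set.seed(5)
  bone <- array(TRUE, c(30, 30, 30))
  lac1 <- array(FALSE, c(30, 30, 30)); lac1[8, 8, 8] <- TRUE
  lac2 <- lac1; lac2[22, 22, 22] <- TRUE
  bone1 <- bone & !lac1
  bone2 <- bone & !lac2
  s1 <- lacunar_spacing(bone1, lac1, 0.35)
  s2 <- lacunar_spacing(bone2, lac2, 0.35)
  expect_lt(s2, s1)
  expect_equal(lacunar_spacing(bone1, lac1, 0.70), 2 * s1)
})

test_that("coarsening applies the majority rule blockwise", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:10, 1:10, 1:10] <- TRUE
  cc <- coarsen_mask(m, 5)
  expect_equal(dim(cc), c(2L, 2L, 2L))
  expect_true(all(cc))
  # a block filled to 40% is non-pore under the majority rule, pore at 52%
  m2 <- array(FALSE, c(5, 5, 5))
  m2[seq_len(50)] <- TRUE                # 50 / 125 = 40%
  expect_false(coarsen_mask(m2, 5)[1, 1, 1])
  m3 <- array(FALSE, c(5, 5, 5))
  m3[seq_len(65)] <- TRUE                # 52%
  expect_true(coarsen_mask(m3, 5)[1, 1, 1])
  expect_true(coarsen_mask(m2, 5, rule = "any")[1, 1, 1])
  # factor 1 is the identity
  expect_identical(coarsen_mask(m, 1), m)
})

test_that("small-object cleaning keeps the boundary size inclusive", {
  m <- array(FALSE, c(40, 40, 40))
  m[1:20, 1:20, 1:4] <- TRUE             # 1600 voxels: retained
  m[1:19, 1:20, 21:24] <- TRUE
  m[20, 1, 21] <- TRUE                   # 1520 + 1 = 1521 < 1600
  m[30:39, 30:39, 30:39] <- TRUE         # 1000 voxels: removed
  cleaned <- clean_small_objects(m, min_voxels = 1600)
  expect_equal(sum(cleaned), 1600)
  expect_true(all(cleaned[1:20, 1:20, 1:4]))
  # exact boundary: a 1599-voxel object is removed
  m2 <- array(FALSE, c(40, 40, 40))
  m2[1:20, 1:20, 1:4] <- TRUE
  m2[1, 1, 1] <- FALSE                   # 1599
  expect_false(any(clean_small_objects(m2, 1600)))
  # degenerate settings
  expect_identical(clean_small_objects(m, 1), m)
  empty <- array(FALSE, c(5, 5, 5))
  expect_identical(clean_small_objects(empty, 1600), empty)
})

test_that("canal surface-to-volume matches the analytic cylinder value", {
  # long discrete cylinder of radius r coarse voxels: S/V = 2 / (r * a)
  n <- 40; L <- 60
  r <- 6
  c0 <- (n + 1) / 2
  disc <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`) <= r^2
  cyl <- array(disc, dim = c(n, n, L))
  a <- 1.75                               # coarse voxel size (5 x 0.35)
  cm <- canal_metrics(cyl, bone_mask = 1e6, voxel_size = 0.35, factor = 5)
  analytic <- 2 / (r * a)
  expect_lt(abs(cm$ca_s_cav_per_um / analytic - 1), 0.20)
  # zero canal volume reports missing S/V and zero ratios
  cm0 <- canal_metrics(array(FALSE, c(4, 4, 4)), 1e6, 0.35, 5)
  expect_equal(cm0$ca_v_bv_pct, 0)
  expect_true(is.na(cm0$ca_s_cav_per_um))
})

test_that("canal volume fraction recovers the phantom ground truth", {
  sp <- site_phantom_spec("jaw_control", grid_shape = c(192L, 192L, 192L),
                          seed = 31)
  ph <- generate_phantom(sp)
  seg <- segment_volume(ph$volume)
  coarse <- coarsen_mask(seg$pore_mask, 5)
  coarse <- clean_small_objects(coarse, 1600)
  measured <- 100 * sum(coarse) * (5 * 0.35)^3 /
    (sum(seg$bone_mask) * 0.35^3)
  true_pct <- 100 * sum(ph$truth$canal_mask) / sum(ph$truth$matrix_mask)
  expect_lt(abs(measured - true_pct), 0.5)
})

test_that("ratios are invariant and sizes equivariant under voxel rescaling", {
  tbl <- data.frame(volume_um3 = c(120, 260, 400))
  lm1 <- lacunar_metrics(tbl, 2e6, voxel_size = 0.35)
  # doubling the voxel size with the same voxel counts: volumes x8
  tbl2 <- data.frame(volume_um3 = tbl$volume_um3 * 8)
  lm2 <- lacunar_metrics(tbl2, 2e6, voxel_size = 0.70)
  expect_equal(lm2$lc_tv_bv_pct, lm1$lc_tv_bv_pct, tolerance = 1e-12)
  expect_equal(lm2$lc_v_med_um3, 8 * lm1$lc_v_med_um3)
  expect_equal(lm2$n_lc_bv_1000mm3, lm1$n_lc_bv_1000mm3 / 8)
})
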