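test_that("two delta peaks give a single threshold strictly between them", {
  counts <- rep(0, 100)
  counts[10] <- 60
  counts[90] <- 40
  t1 <- multi_otsu(counts, 2)
  expect_length(t1, 1)
  expect_gt(t1, 10)
  expect_lt(t1, 90)
})

test_that("three-class Otsu equals exhaustive search on random histograms", {
  set.seed(21)
  for (rep in 1:100) {
    counts <- rpois(64, lambda = sample(1:20, 1)) +
      round(50 * dnorm(1:64, mean = runif(1, 10, 55), sd = runif(1, 2, 8)))
    if (sum(counts > 0) < 3) next
    fast <- multi_otsu(counts, 3)
    slow <- brute_otsu3(counts)
    expect_equal(fast, slow)
  }
})

test_that("Otsu separates air, glue and bone modes of a trimodal histogram", {
  # mimics the scan histogram: air peak near -100 a.u., broad glue peak
  # near 200 a.u., mineralized tissue near 1200 a.u.
  centers <- seq(-300, 1500, length.out = 256)
  counts <- round(4e4 * dnorm(centers, -100, 40) +
                    1.5e4 * dnorm(centers, 200, 80) +
                    6e4 * dnorm(centers, 1200, 60))
  thr <- multi_otsu(counts, 3, values = centers)
  expect_length(thr, 2)
  expect_gt(thr[1], -100); expect_lt(thr[1], 200)
  expect_gt(thr[2], 200); expect_lt(thr[2], 1200)
  expect_error(multi_otsu(c(0, 5, 0), 3), "degenerate")
})

test_that("pore segmentation recovers carved phantom pores", {
  sp <- site_phantom_spec("jaw_control", grid_shape = c(96L, 96L, 96L),
                          seed = 19)
  ph <- generate_phantom(sp)
  thr <- otsu_thresholds(ph$volume, 3)
  seg <- segment_pores(ph$volume, thr)
  true_pore <- ph$truth$lacuna_mask | ph$truth$canal_mask
  n_true <- sum(true_pore)
  n_seg <- sum(seg$pore_mask)
  expect_lt(abs(n_seg / n_true - 1), 0.05)
  # all-above-threshold volume has an empty pore mask
  flat <- voxel_volume(array(1000, c(16, 16, 16)), 0.35)
  seg2 <- segment_pores(flat, thresholds = c(0, 500))
  expect_false(any(seg2$pore_mask))
  expect_error(segment_pores(voxel_volume(array(-1, c(8, 8, 8)), 0.35),
                             c(0, 500)), "empty bone")
})

test_that("sign inversion swaps bone and pore roles within the support", {
  sp <- phantom_spec(grid_shape = c(48L, 48L, 48L), lacuna_count = 3L,
                     lacuna_volume_dist = lacuna_volume_dist(
                       "normal", mean = 60, sd = 10),
                     seed = 4)
  ph <- generate_phantom(sp)
  thr <- otsu_thresholds(ph$volume, 2)
  seg <- segment_pores(ph$volume, thr)
  inv <- voxel_volume(-ph$volume$data, 0.35)
  bone_inv <- inv$data > max(-thr)
  # inverted "bone" equals the original non-bone voxels
  expect_identical(bone_inv, !(ph$volume$data > max(thr)))
})

test_that("volume gate boundaries are inclusive", {
  # with 1 um voxels, voxel count == volume in um^3: rods of 50 / 49 voxels
  m <- array(FALSE, c(120, 20, 10))
  m[1:50 + 0, 3, 3] <- TRUE            # 50 voxels = 50 um^3 (kept)
  m[1:49 + 60, 8, 3] <- TRUE           # 49 voxels (excluded)
  lab <- label_components(m, 26)
  cls <- classify_by_volume(lab, voxel_size = 1)
  expect_equal(nrow(cls$table), 1)
  expect_equal(cls$table$volume_um3, 50)
  expect_equal(sum(cls$other_pore_mask), 49)
})

test_that("gate keeps in-range objects and routes the rest to other pores", {
  # ground-truth volumes ~ {40, 60, 500, 1100} um^3 -> exactly 2 lacunae
  m <- array(FALSE, c(60, 60, 60))
  put_ball <- function(m, c0, vol_um3, h = 1) {
    r <- (3 * vol_um3 / (4 * pi))^(1 / 3) / h
    rng <- function(c) max(1, floor(c - r - 1)):min(60, ceiling(c + r + 1))
    ix <- rng(c0[1]); iy <- rng(c0[2]); iz <- rng(c0[3])
    sub <- outer(outer((ix - c0[1])^2, (iy - c0[2])^2, `+`),
                 (iz - c0[3])^2, `+`) <= r^2
    m[ix, iy, iz] <- m[ix, iy, iz] | sub
    m
  }
  m <- put_ball(m, c(10, 10, 10), 40)
  m <- put_ball(m, c(30, 10, 10), 60)
  m <- put_ball(m, c(15, 35, 30), 500)
  m <- put_ball(m, c(42, 42, 45), 1100)
  lab <- label_components(m, 26)
  expect_equal(attr(lab, "n_components"), 4L)
  cls <- classify_by_volume(lab, voxel_size = 1)
  expect_equal(nrow(cls$table), 2)
  # idempotence: re-gating the gated output changes nothing
  lab2 <- cls$lacuna_labels
  cls2 <- classify_by_volume(lab2, voxel_size = 1)
  expect_equal(sort(cls2$table$volume_um3), sort(cls$table$volume_um3))
  # monotonicity: widening the gate never loses objects
  cls_wide <- classify_by_volume(lab, voxel_size = 1, vmin = 20,
                                 vmax = 2000)
  expect_gte(nrow(cls_wide$table), nrow(cls$table))
})

test_that("VOI splitting partitions the axis with the stated tie-break", {
  expect_equal(as.integer(table(split_vois(c(10, 10, 999)))),
               c(333L, 333L, 333L))
  v <- split_vois(c(10, 10, 1000))
  expect_equal(as.integer(table(v)), c(334L, 333L, 333L))
  expect_equal(length(v), 1000L)
  expect_true(all(diff(v) >= 0))           # contiguous slabs
  expect_error(split_vois(c(5, 5, 2), n_vois = 3), "shorter")
})

test_that("border-touching lacunae are removed from analysis", {
  m <- array(0L, c(30, 30, 30))
  m[14:16, 14:16, 5:7] <- 1L      # interior of VOI 1 (slices 1:10)
  m[14:16, 14:16, 9:12] <- 2L     # spans the VOI-1/VOI-2 interface
  m[1:2, 20:22, 24:26] <- 3L      # touches the x = 1 face
  voi <- split_vois(c(30, 30, 30))
  out <- remove_border_lacunae(m, voi)
  expect_true(all(out[m == 1L] == 1L))
  expect_true(all(out[m == 2L] == 0L))
  expect_true(all(out[m == 3L] == 0L))
  expect_equal(attr(out, "removed"), c(2L, 3L))
  # when every lacuna touches a face the result is empty
  m2 <- array(0L, c(12, 12, 12))
  m2[1, 5, 5] <- 1L
  out2 <- remove_border_lacunae(m2, split_vois(c(12, 12, 12)))
  expect_false(any(out2 > 0))
})

test_that("retained lacunae equal ground-truth interior in-gate lacunae", {
  sp <- site_phantom_spec("jaw_control", grid_shape = c(128L, 128L, 128L),
                          seed = 23)
  ph <- generate_phantom(sp)
  seg <- segment_volume(ph$volume)

  tl <- ph$truth$lacuna_labels
  d <- dim(tl)
  voi <- seg$voi_slices
  bz <- unlist(lapply(split(seq_len(d[3]), voi),
                      function(s) c(s[1], s[length(s)])), use.names = FALSE)
  touch <- unique(c(tl[1, , ], tl[d[1], , ], tl[, 1, ], tl[, d[2], ],
                    tl[, , unique(bz)]))
  tt <- ph$truth$lacuna_table
  interior <- !(tt$id %in% touch) & tt$voxel_volume_um3 >= 50 &
    tt$voxel_volume_um3 <= 1000
  expect_lte(abs(nrow(seg$lacuna_table) - sum(interior)), 1)
  if (nrow(seg$lacuna_table) == sum(interior) && sum(interior) > 0) {
    expect_equal(sort(seg$lacuna_table$volume_um3),
                 sort(tt$voxel_volume_um3[interior]), tolerance = 0.02)
  }
})
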