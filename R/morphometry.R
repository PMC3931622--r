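#' Per-VOI lacunar morphometry
#'
#' Computes, from a table of retained (interior, in-gate) lacunae and the
#' bone mask of one VOI:
#' \describe{
#'   \item{n_lc}{lacuna count.}
#'   \item{lc_v_med_um3}{median lacunar volume (um^3).}
#'   \item{lc_v_var_1000um6}{sample variance (n-1 denominator) of lacunar
#'     volumes, reported in 1000 um^6.}
#'   \item{lc_tv_bv_pct}{total lacunar volume / bone volume, percent.}
#'   \item{n_lc_bv_1000mm3}{lacunar number density, in 1000 per mm^3.}
#' }
#' Bone volume (BV) is the mineralized tissue excluding lacunae and all
#' other pores: `sum(bone_mask) * voxel_size^3`.
#'
#' @param table lacuna table restricted to one VOI (needs column
#'   `volume_um3`), border lacunae already removed.
#' @param bone_mask logical array (or precomputed voxel count) of the VOI's
#'   mineralized tissue.
#' @param voxel_size um per voxel.
#' @return named list of the five metrics.
#' @export
lacunar_metrics <- function(table, bone_mask, voxel_size) {
  bv_vox <- if (is.array(bone_mask) || is.logical(bone_mask))
    sum(bone_mask) else as.numeric(bone_mask)
  if (bv_vox <= 0) stop("invalid VOI: empty bone mask")
  bv_um3 <- bv_vox * voxel_size^3
  v <- table$volume_um3
  n <- length(v)
  list(n_lc = n,
       lc_v_med_um3 = if (n > 0) median(v) else NA_real_,
       lc_v_var_1000um6 = if (n > 1) var(v) / 1000 else NA_real_,
       lc_tv_bv_pct = 100 * sum(v) / bv_um3,
       n_lc_bv_1000mm3 = n / (bv_um3 * 1e-9) / 1000)
}

#' Median distance of bone tissue to the nearest lacuna
#'
#' For every bone voxel, the Euclidean distance to the nearest lacunar
#' voxel; the returned value is the median over bone voxels, in um -- the
#' distance within which half of the mineralized tissue lies with respect
#' to the closest lacunar surface.
#'
#' @param bone_mask logical array.
#' @param lacuna_mask logical array (non-empty).
#' @param voxel_size um per voxel.
#' @return median distance in um.
#' @export
lacunar_spacing <- function(bone_mask, lacuna_mask, voxel_size) {
  if (!any(lacuna_mask))
    stop("lacunar spacing undefined: empty lacuna mask")
  d <- distance_transform(lacuna_mask)
  median(d[bone_mask]) * voxel_size
}

#' Coarsen a binary mask by block majority
#'
#' Each `factor^3` block maps to one coarse voxel, which is pore when more
#' than half of the block's fine voxels are pore. Trailing fine voxels not
#' filling a whole block are dropped. The coarse voxel size is
#' `factor * voxel_size`.
#'
#' @param mask logical 3D array.
#' @param factor integer >= 1 (default 5).
#' @param rule `"majority"` (> 50% of the block) or `"any"`.
#' @return logical coarse array.
#' @export
coarsen_mask <- function(mask, factor = 5L, rule = c("majority", "any")) {
  rule <- match.arg(rule)
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1L) return(mask)
  d <- dim(mask)
  dc <- d %/% factor
  if (any(dc == 0)) stop("mask smaller than one block")
  m <- mask[seq_len(dc[1] * factor), seq_len(dc[2] * factor),
            seq_len(dc[3] * factor), drop = FALSE]
  dim(m) <- c(factor, dc[1], factor, dc[2], factor, dc[3])
  s <- colSums(aperm(m, c(1, 3, 5, 2, 4, 6)), dims = 3)
  if (rule == "majority") s > factor^3 / 2 else s > 0
}

#' Remove small objects from a (coarse) mask
#'
#' Connected components with fewer than `min_voxels` voxels are removed;
#' components with exactly `min_voxels` are retained.
#'
#' @param mask logical 3D array.
#' @param min_voxels minimum component size (default 1600, which at 5x
#'   coarsening of 0.35 um voxels corresponds to 8575 um^3).
#' @param connectivity component adjacency (default 26).
#' @return cleaned logical array.
#' @export
clean_small_objects <- function(mask, min_voxels = 1600L,
                                connectivity = 26L) {
  if (min_voxels <= 1) return(mask)
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity = connectivity)
  n_lab <- attr(lab, "n_components")
  counts <- .label_counts_cpp(lab, as.integer(n_lab))
  small <- which(counts < min_voxels)
  out <- mask
  if (length(small) > 0) out[lab %in% small] <- FALSE
  out
}

#' Vascular canal metrics
#'
#' On the coarsened, cleaned pore mask: canal volume Ca.V by voxel
#' counting; canal surface Ca.S as the number of pore voxels within one
#' voxel Euclidean distance of the pore boundary (pore-side convention)
#' times the coarse voxel face area. Ratios are reported against the
#' fine-resolution bone volume.
#'
#' @param coarse_mask cleaned coarse pore mask (logical array).
#' @param bone_mask fine-resolution bone mask (logical array) or its voxel
#'   count.
#' @param voxel_size fine voxel size, um.
#' @param factor coarsening factor used to build `coarse_mask`.
#' @param side `"pore"` (default) or `"bone"`: which side of the boundary
#'   the surface voxels are counted on.
#' @return list: `ca_v_bv_pct`, `ca_s_bv_per_um`, `ca_s_cav_per_um`
#'   (`NA` when the canal volume is zero), plus `ca_v_um3`, `ca_s_um2`.
#' @export
canal_metrics <- function(coarse_mask, bone_mask, voxel_size, factor = 5L,
                          side = c("pore", "bone")) {
  side <- match.arg(side)
  hc <- voxel_size * factor
  bv_vox <- if (is.array(bone_mask) || is.logical(bone_mask))
    sum(bone_mask) else as.numeric(bone_mask)
  bv_um3 <- bv_vox * voxel_size^3
  n_pore <- sum(coarse_mask)
  ca_v <- n_pore * hc^3
  if (n_pore == 0) {
    return(list(ca_v_bv_pct = 0, ca_s_bv_per_um = 0,
                ca_s_cav_per_um = NA_real_, ca_v_um3 = 0, ca_s_um2 = 0))
  }
  if (side == "pore") {
    dist_to_out <- distance_transform(!coarse_mask)
    n_surf <- sum(coarse_mask & dist_to_out <= 1)
  } else {
    dist_to_pore <- distance_transform(coarse_mask)
    n_surf <- sum(!coarse_mask & dist_to_pore <= 1)
  }
  ca_s <- n_surf * hc^2
  list(ca_v_bv_pct = 100 * ca_v / bv_um3,
       ca_s_bv_per_um = ca_s / bv_um3,
       ca_s_cav_per_um = ca_s / ca_v,
       ca_v_um3 = ca_v, ca_s_um2 = ca_s)
}

#' Per-VOI morphometry of a segmented volume
#'
#' Applies [lacunar_metrics()] and [lacunar_spacing()] per VOI. The canal
#' chain ([coarsen_mask()] then [clean_small_objects()]) runs on the full
#' sample pore mask -- so canals spanning several VOIs are not fragmented
#' below the cleaning threshold -- and the cleaned coarse mask is then
#' split into VOI slabs for [canal_metrics()].
#'
#' @param seg result of [segment_volume()].
#' @param voxel_size um per voxel.
#' @param coarsen_factor canal-analysis coarsening factor (default 5).
#' @param clean_min_voxels minimum coarse object size (default 1600).
#' @return data.frame, one row per VOI, with the lacunar and canal metric
#'   columns of the per-VOI result schema.
#' @export
voi_morphometry <- function(seg, voxel_size, coarsen_factor = 5L,
                            clean_min_voxels = 1600L) {
  voi_slices <- seg$voi_slices
  n_vois <- max(voi_slices)

  # sample-level canal mask; surface voxels from the full-mask EDT so that
  # VOI interfaces do not create artificial canal surface
  coarse <- coarsen_mask(seg$pore_mask, factor = coarsen_factor)
  coarse <- clean_small_objects(coarse, min_voxels = clean_min_voxels)
  surf <- if (any(coarse))
    coarse & distance_transform(!coarse) <= 1 else coarse
  nzc <- dim(coarse)[3]
  nz <- length(voi_slices)
  voi_coarse <- voi_slices[pmin(pmax(round((seq_len(nzc) - 0.5) *
                                             coarsen_factor + 0.5), 1L), nz)]
  hc <- voxel_size * coarsen_factor

  rows <- vector("list", n_vois)
  for (v in seq_len(n_vois)) {
    zi <- which(voi_slices == v)
    bone_v <- seg$bone_mask[, , zi, drop = FALSE]
    lac_lab_v <- seg$lacuna_labels[, , zi, drop = FALSE]
    lac_mask_v <- lac_lab_v > 0
    tbl_v <- seg$lacuna_table[seg$lacuna_table$voi == v, , drop = FALSE]
    lm <- lacunar_metrics(tbl_v, bone_v, voxel_size)
    dist50 <- if (any(lac_mask_v))
      lacunar_spacing(bone_v, lac_mask_v, voxel_size) else NA_real_

    zc <- which(voi_coarse == v)
    bv_um3 <- sum(bone_v) * voxel_size^3
    ca_v <- sum(coarse[, , zc]) * hc^3
    ca_s <- sum(surf[, , zc]) * hc^2
    rows[[v]] <- data.frame(
      voi = v, N.Lc = lm$n_lc, Lc.V_med_um3 = lm$lc_v_med_um3,
      Lc.V_var_1000um6 = lm$lc_v_var_1000um6, Lc.Dist50_um = dist50,
      Lc.TV_BV_pct = lm$lc_tv_bv_pct,
      N.Lc_BV_1000mm3 = lm$n_lc_bv_1000mm3,
      Ca.V_BV_pct = 100 * ca_v / bv_um3,
      Ca.S_CaV_um_1 = if (ca_v > 0) ca_s / ca_v else NA_real_,
      Ca.S_BV_um_1 = ca_s / bv_um3)
  }
  do.call(rbind, rows)
}
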