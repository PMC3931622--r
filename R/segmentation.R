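#' Multi-class Otsu thresholds of a histogram
#'
#' Exhaustively maximizes the between-class variance
#' sum_k w_k (mu_k - mu)^2 over all placements of `n_classes - 1`
#' thresholds on the histogram bins. This is the multi-level extension of
#' Otsu's method used to separate air / intermediate (glue-like) material /
#' mineralized tissue in reconstructed bone volumes.
#'
#' @param counts histogram counts per bin.
#' @param n_classes number of classes (>= 2).
#' @param values bin centres (ascending); default bin indices.
#' @return numeric thresholds (length `n_classes - 1`), ascending; each is
#'   the midpoint between the last bin of one class and the first bin of
#'   the next.
#' @export
multi_otsu <- function(counts, n_classes = 2L, values = seq_along(counts)) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (length(counts) == 0 || sum(counts) == 0) stop("empty histogram")
  if (length(values) != length(counts)) stop("values/counts mismatch")
  if (is.unsorted(values, strictly = TRUE)) stop("values must be ascending")
  populated <- which(counts > 0)
  if (length(populated) < n_classes)
    stop("degenerate histogram: fewer populated bins than classes")
  n <- length(counts)
  p <- counts / sum(counts)
  cw <- cumsum(p)                      # class weight up to bin i
  cm <- cumsum(p * values)             # first moment up to bin i

  k <- n_classes - 1L
  # candidate cut points: after bin t (t in 1..n-1); combinations with an
  # empty class are invalidated below. Class j spans bins (t_{j-1}, t_j].
  combos <- utils::combn(n - 1L, k)
  ncombo <- ncol(combos)
  sigma <- rep(0, ncombo)
  prev_w <- rep(0, ncombo); prev_m <- rep(0, ncombo)
  valid <- rep(TRUE, ncombo)
  for (j in seq_len(k + 1L)) {
    tj <- if (j <= k) combos[j, ] else rep(n, ncombo)
    wj <- cw[tj] - prev_w
    mj <- cm[tj] - prev_m
    valid <- valid & wj > 0
    muj <- ifelse(wj > 0, mj / wj, 0)
    sigma <- sigma + wj * muj^2
    prev_w <- cw[tj]
    prev_m <- cm[tj]
  }
  sigma[!valid] <- -Inf
  best_i <- which.max(sigma)
  cuts <- combos[, best_i]
  (values[cuts] + values[cuts + 1L]) / 2
}

#' Otsu thresholds of a volume's intensity histogram
#'
#' @param volume a [voxel_volume()] or 3D array.
#' @param n_classes number of intensity classes (default 3: air/soft,
#'   intermediate, mineralized).
#' @param n_bins histogram bins (default 256).
#' @return thresholds in intensity units (a.u.), ascending.
#' @export
otsu_thresholds <- function(volume, n_classes = 3L, n_bins = 256L) {
  x <- as_volume_data(volume)
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- tabulate(pmin(pmax(findInterval(x, edges,
                                            rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  multi_otsu(counts, n_classes = n_classes, values = centers)
}

fill_holes_2d <- function(m) {
  # m: logical matrix (TRUE = solid); returns m with enclosed holes filled
  d <- dim(m)
  lab <- .cc_label_cpp(as.logical(!m), as.integer(c(d, 1L)), 6L)
  dim(lab) <- d
  border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
  border <- border[border > 0]
  m | !(lab %in% border)
}

#' Sample support mask
#'
#' The region occupied by the physical sample (bone plus its internal
#' pores), used to keep exterior air out of the pore masks. Computed as a
#' morphological closing of the bone mask with a ball structuring element,
#' followed by slice-wise hole filling transverse to the sample-length
#' axis, so internal cavities of any size (lacunae, canal lumina) belong to
#' the support while exterior air does not.
#'
#' @param bone_mask logical 3D array.
#' @param closing_radius ball radius in voxels (default 10).
#' @param axis sample-length axis (default 3 = z).
#' @return logical array, the support.
#' @export
support_mask <- function(bone_mask, closing_radius = 10, axis = 3L) {
  if (axis != 3L) stop("only axis = 3 (z) is supported")
  closed <- close_ball(bone_mask, closing_radius)
  d <- dim(closed)
  out <- closed
  for (z in seq_len(d[3])) out[, , z] <- fill_holes_2d(closed[, , z])
  out
}

#' Segment mineralized tissue and pores
#'
#' Voxels above the highest threshold are bone; voxels below it but inside
#' the sample support are pores; everything else is background (excluded
#' from all analysis).
#'
#' @param volume a [voxel_volume()] or 3D array.
#' @param thresholds thresholds from [multi_otsu()] / [otsu_thresholds()].
#' @param support optional precomputed support mask; computed from the bone
#'   mask by [support_mask()] when `NULL`.
#' @param closing_radius passed to [support_mask()].
#' @return list with logical arrays `bone_mask`, `pore_mask`, `support`.
#' @export
segment_pores <- function(volume, thresholds, support = NULL,
                          closing_radius = 10) {
  x <- as_volume_data(volume)
  bone <- x > max(thresholds)
  if (!any(bone)) stop("segmentation failure: empty bone mask")
  if (is.null(support)) support <- support_mask(bone, closing_radius)
  pore <- support & !bone
  list(bone_mask = bone & support, pore_mask = pore, support = support)
}

#' Classify labelled pores by the lacunar volume gate
#'
#' Objects with volume inside `[vmin, vmax]` um^3 (boundaries inclusive;
#' strictly smaller or strictly larger objects are excluded) are lacunae;
#' all other objects go to the other-pore mask that feeds the vascular
#' canal analysis.
#'
#' @param labels integer label volume from [label_components()].
#' @param voxel_size um per voxel.
#' @param vmin,vmax gate bounds in um^3 (defaults 50 and 1000).
#' @return list: `lacuna_labels` (gated label volume), `other_pore_mask`
#'   (logical), `table` (data.frame: id, voxels, volume_um3, cx, cy, cz in
#'   voxel coordinates).
#' @export
classify_by_volume <- function(labels, voxel_size, vmin = 50, vmax = 1000) {
  n_lab <- attr(labels, "n_components")
  if (is.null(n_lab)) n_lab <- max(0L, max(labels))
  d <- dim(labels)
  if (n_lab == 0) {
    return(list(lacuna_labels = labels,
                other_pore_mask = array(FALSE, dim = d),
                table = data.frame(id = integer(0), voxels = numeric(0),
                                   volume_um3 = numeric(0), cx = numeric(0),
                                   cy = numeric(0), cz = numeric(0))))
  }
  counts <- .label_counts_cpp(labels, as.integer(n_lab))
  vols <- counts * voxel_size^3
  keep <- vols >= vmin & vols <= vmax

  idx <- which(labels > 0)
  lab <- labels[idx]
  ix <- ((idx - 1) %% d[1]) + 1
  iy <- (((idx - 1) %/% d[1]) %% d[2]) + 1
  iz <- ((idx - 1) %/% (d[1] * d[2])) + 1
  cx <- rowsum(ix, lab)[, 1] / counts
  cy <- rowsum(iy, lab)[, 1] / counts
  cz <- rowsum(iz, lab)[, 1] / counts

  lac <- labels
  drop <- which(!keep)
  if (length(drop) > 0) lac[lac %in% drop] <- 0L
  other <- labels > 0 & !(labels %in% which(keep))
  dim(other) <- d
  attr(lac, "n_components") <- n_lab   # ids keep their original numbering
  tbl <- data.frame(id = which(keep), voxels = counts[keep],
                    volume_um3 = vols[keep], cx = cx[keep], cy = cy[keep],
                    cz = cz[keep])
  list(lacuna_labels = lac, other_pore_mask = other, table = tbl)
}

#' Split a volume into equal VOIs along the sample length
#'
#' `n_vois` contiguous slabs whose sizes differ by at most one slice; any
#' remainder slices go to the first slab(s).
#'
#' @param volume_shape integer length-3 (or the length of the chosen axis).
#' @param n_vois number of VOIs (default 3).
#' @param axis sample-length axis (default 3).
#' @return integer vector of VOI ids, one per slice along the axis.
#' @export
split_vois <- function(volume_shape, n_vois = 3L, axis = 3L) {
  len <- if (length(volume_shape) > 1) volume_shape[axis] else volume_shape
  if (len < n_vois) stop("axis shorter than the number of VOIs")
  base <- len %/% n_vois
  extra <- len %% n_vois
  sizes <- rep(base, n_vois) + c(rep(1L, extra), rep(0L, n_vois - extra))
  rep(seq_len(n_vois), times = sizes)
}

#' Remove border-truncated lacunae
#'
#' Any lacuna with at least one voxel on a VOI face -- the outer volume
#' faces or the slices adjacent to an interface between VOIs -- may be
#' truncated and is removed entirely (a lacuna spanning a VOI interface is
#' removed from both VOIs).
#'
#' @param lacuna_labels gated label volume.
#' @param voi_slices per-slice VOI ids from [split_vois()].
#' @return label volume with border lacunae zeroed; removed ids in
#'   attribute `removed`.
#' @export
remove_border_lacunae <- function(lacuna_labels, voi_slices) {
  d <- dim(lacuna_labels)
  if (length(voi_slices) != d[3]) stop("voi_slices length != z extent")
  # boundary slices: first and last slice of every VOI slab
  bz <- unlist(lapply(split(seq_len(d[3]), voi_slices),
                      function(s) c(s[1], s[length(s)])), use.names = FALSE)
  touching <- unique(c(
    lacuna_labels[1, , ], lacuna_labels[d[1], , ],
    lacuna_labels[, 1, ], lacuna_labels[, d[2], ],
    lacuna_labels[, , unique(bz)]))
  touching <- touching[touching > 0]
  out <- lacuna_labels
  if (length(touching) > 0) out[out %in% touching] <- 0L
  attr(out, "removed") <- sort(touching)
  attr(out, "n_components") <- attr(lacuna_labels, "n_components")
  out
}

#' Full segmentation of a reconstructed volume
#'
#' Convenience wrapper: Otsu thresholds, bone/pore masks, 3D labelling,
#' lacunar volume gate, VOI split, border-lacuna removal.
#'
#' @param volume a [voxel_volume()].
#' @param n_classes Otsu classes (default 3).
#' @param connectivity pore connectivity (default 26).
#' @param vmin,vmax lacunar volume gate, um^3.
#' @param n_vois number of VOIs.
#' @param closing_radius support closing radius, voxels.
#' @return list: `thresholds`, `bone_mask`, `pore_mask`, `support`,
#'   `lacuna_labels` (border-removed), `other_pore_mask`, `lacuna_table`
#'   (with `voi` assigned by centroid), `voi_slices`.
#' @export
segment_volume <- function(volume, n_classes = 3L, connectivity = 26L,
                           vmin = 50, vmax = 1000, n_vois = 3L,
                           closing_radius = 10) {
  stopifnot(inherits(volume, "voxel_volume"))
  thr <- otsu_thresholds(volume, n_classes = n_classes)
  seg <- segment_pores(volume, thr)
  labels <- label_components(seg$pore_mask, connectivity = connectivity)
  cls <- classify_by_volume(labels, voxel_size = volume$voxel_size,
                            vmin = vmin, vmax = vmax)
  voi_slices <- split_vois(dim(volume$data), n_vois = n_vois)
  lac <- remove_border_lacunae(cls$lacuna_labels, voi_slices)
  tbl <- cls$table[!(cls$table$id %in% attr(lac, "removed")), , drop = FALSE]
  tbl$voi <- voi_slices[pmin(pmax(round(tbl$cz), 1L), dim(volume$data)[3])]
  list(thresholds = thr, bone_mask = seg$bone_mask,
       pore_mask = seg$pore_mask, support = seg$support,
       lacuna_labels = lac, other_pore_mask = cls$other_pore_mask,
       lacuna_table = tbl, voi_slices = voi_slices)
}
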