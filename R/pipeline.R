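#' Pipeline configuration
#'
#' Nested list of every stage parameter. Defaults are the acquisition and
#' analysis settings of the study: 0.35 um voxels, 16.874 keV, 282 mm
#' propagation distance, delta/beta = 199, 1201 projections over 360
#' degrees, lacunar volume gate [50, 1000] um^3, 3 VOIs, 5x canal
#' coarsening, 1600-voxel cleaning, P = 0.005 density percentiles and
#' alpha = 0.05. The config round-trips through YAML unchanged.
#'
#' @param seed master seed; per-sample seeds are derived from it.
#' @param out_dir output directory for CSVs (`NULL` = return only).
#' @param sites character vector of group profiles to simulate (see
#'   [site_phantom_spec()]).
#' @param n_samples phantoms per site.
#' @param grid_shape phantom grid (voxels per axis).
#' @param voxel_size_um voxel size in um.
#' @param recon_enabled simulate radiographs, retrieve phase and
#'   reconstruct before segmentation (slow); otherwise the rendered phantom
#'   volume is analysed directly.
#' @param energy_kev,distance_mm,delta_beta,n_projections,angular_range_deg
#'   acquisition settings used when `recon_enabled`.
#' @param delta_scale refractive index decrement per intensity a.u.
#' @param n_classes,connectivity,vmin_um3,vmax_um3,n_vois,closing_radius
#'   segmentation settings.
#' @param coarsen_factor,clean_min_voxels canal-analysis settings.
#' @param density_bins,density_p rDMD settings.
#' @param alpha significance level for group statistics.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            sites = c("tibia", "femur", "jaw_control",
                                      "jaw_bronj"),
                            n_samples = 3L,
                            grid_shape = c(160L, 160L, 160L),
                            voxel_size_um = 0.35,
                            recon_enabled = FALSE,
                            energy_kev = 16.874, distance_mm = 282,
                            delta_beta = 199, n_projections = 1201L,
                            angular_range_deg = 360,
                            delta_scale = 1.2e-9,
                            n_classes = 3L, connectivity = 26L,
                            vmin_um3 = 50, vmax_um3 = 1000, n_vois = 3L,
                            closing_radius = 10,
                            coarsen_factor = 5L, clean_min_voxels = 1600L,
                            density_bins = 256L, density_p = 0.005,
                            alpha = 0.05) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 phantom = list(sites = sites,
                                n_samples = as.integer(n_samples),
                                grid_shape = as.integer(grid_shape),
                                voxel_size_um = voxel_size_um),
                 recon = list(enabled = recon_enabled,
                              energy_kev = energy_kev,
                              distance_mm = distance_mm,
                              delta_beta = delta_beta,
                              n_projections = as.integer(n_projections),
                              angular_range_deg = angular_range_deg,
                              delta_scale = delta_scale),
                 segmentation = list(n_classes = as.integer(n_classes),
                                     connectivity = as.integer(connectivity),
                                     vmin_um3 = vmin_um3,
                                     vmax_um3 = vmax_um3,
                                     n_vois = as.integer(n_vois),
                                     closing_radius = closing_radius),
                 morphometry = list(coarsen_factor = as.integer(coarsen_factor),
                                    clean_min_voxels =
                                      as.integer(clean_min_voxels)),
                 density = list(n_bins = as.integer(density_bins),
                                p = density_p),
                 stats = list(alpha = alpha)),
            class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

# reconstruct one phantom volume through the simulated imaging chain
reconstruct_volume <- function(vol, rc) {
  geom <- acquisition_geometry(energy_kev = rc$energy_kev,
                               propagation_distance_mm = rc$distance_mm,
                               pixel_size_um = vol$voxel_size,
                               n_projections = rc$n_projections,
                               angular_range_deg = rc$angular_range_deg,
                               delta_beta = rc$delta_beta)
  # map a.u. density to refractive index decrement; clamp air noise at 0
  delta <- pmax(vol$data, 0) * rc$delta_scale
  dim(delta) <- dim(vol$data)
  ps <- forward_project(voxel_volume(delta, vol$voxel_size), geom)
  maps <- paganin_retrieve(ps)
  rec <- fbp_reconstruct(maps, ps$angles_deg, pixel_size_um = vol$voxel_size)
  lam_um <- geom$wavelength_nm * 1e-3
  # FBP of mu-thickness maps gives mu (per um); convert back to a.u.
  au <- rec$data * lam_um / (4 * pi) * geom$delta_beta / rc$delta_scale
  voxel_volume(au, vol$voxel_size)
}

analyse_volume <- function(vol, config, group, sample_id) {
  sg <- config$segmentation
  seg <- segment_volume(vol, n_classes = sg$n_classes,
                        connectivity = sg$connectivity, vmin = sg$vmin_um3,
                        vmax = sg$vmax_um3, n_vois = sg$n_vois,
                        closing_radius = sg$closing_radius)
  mm <- voi_morphometry(seg, vol$voxel_size,
                        coarsen_factor = config$morphometry$coarsen_factor,
                        clean_min_voxels =
                          config$morphometry$clean_min_voxels)
  dens <- lapply(seq_len(max(seg$voi_slices)), function(v) {
    zi <- which(seg$voi_slices == v)
    bm <- seg$bone_mask[, , zi, drop = FALSE]
    dd <- compute_rdmd(vol$data[, , zi, drop = FALSE], bm,
                       n_bins = config$density$n_bins)
    ds <- rdmd_descriptors(dd, p = config$density$p)
    data.frame(Mean_r = ds$mean_r, Peak_r = ds$peak_r,
               FWHM_r = ds$fwhm_r, Low_r = ds$low_r, High_r = ds$high_r,
               bimodal = ds$bimodal)
  })
  cbind(data.frame(site = group, sample = sample_id, group = group),
        mm, do.call(rbind, dens))
}

#' Run the full analysis pipeline
#'
#' Phantom generation for every configured site/sample, optional simulated
#' acquisition + phase retrieval + reconstruction, segmentation, per-VOI
#' lacunar/canal morphometry and density descriptors, and group statistics.
#' Fully deterministic for a fixed config (per-sample seeds are derived
#' from the master seed).
#'
#' @param config a [pipeline_config()].
#' @param progress print per-sample progress lines.
#' @return list: `results` (per-VOI data.frame), `comparisons` (named list
#'   of `comparison_result`), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  ph <- config$phantom
  rows <- list()
  k <- 0L
  for (site in ph$sites) {
    for (s in seq_len(ph$n_samples)) {
      k <- k + 1L
      seed_k <- config$seed + 1000L * k
      spec <- site_phantom_spec(site, grid_shape = ph$grid_shape,
                                voxel_size = ph$voxel_size_um,
                                seed = seed_k)
      phm <- generate_phantom(spec)
      vol <- phm$volume
      if (isTRUE(config$recon$enabled))
        vol <- reconstruct_volume(vol, config$recon)
      if (progress)
        message(sprintf("[%s #%d] seed %d: %d lacunae placed", site, s,
                        seed_k, nrow(phm$truth$lacuna_table)))
      rows[[k]] <- analyse_volume(vol, config, group = site,
                                  sample_id = sprintf("%s_%02d", site, s))
    }
  }
  results <- do.call(rbind, rows)
  metrics <- c("Lc.V_med_um3", "Lc.V_var_1000um6", "Lc.Dist50_um",
               "Lc.TV_BV_pct", "N.Lc_BV_1000mm3", "Ca.V_BV_pct",
               "Ca.S_CaV_um_1", "Ca.S_BV_um_1", "Mean_r", "Peak_r",
               "FWHM_r", "Low_r", "High_r")
  comparisons <- if (length(unique(results$group)) >= 2)
    compare_groups(results, metrics = metrics,
                   alpha = config$stats$alpha) else list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(config$out_dir, "per_voi_results.csv"),
              row.names = FALSE)
    if (length(comparisons) > 0) {
      comp_rows <- do.call(rbind, lapply(names(comparisons), function(m) {
        cr <- comparisons[[m]]
        data.frame(metric = m, f_stat = cr$f_stat, p_value = cr$p_value,
                   n_significant_pairs = sum(cr$pairwise$significant))
      }))
      write.csv(comp_rows, file.path(config$out_dir,
                                     "group_comparisons.csv"),
                row.names = FALSE)
    }
    write_config(config, file.path(config$out_dir, "config.yaml"))
  }
  list(results = results, comparisons = comparisons, config = config)
}
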