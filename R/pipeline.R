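# End-to-end orchestration: per-cell trajectory + density analysis into a
# study dataset and radius fit, and the NERD grid scan on top of it.

#' Analysis configuration
#'
#' Bundles the per-cell inputs and the constants of the assay. Each entry of
#' `cells` is a list with elements `id`, `trajectories` (CSV path), `mask`
#' (TIFF path written by [write_pattern_mask()]), and either `on_mean` /
#' `off_mean` (counts/um^2, flat-field corrected) or `pattern_image` (TIFF
#' path, evaluated under the same mask).
#'
#' @param cells list of per-cell input descriptions.
#' @param calib a [single_molecule_brightness()] calibration.
#' @param bulk_illumination illumination time of the pattern images (s).
#' @param frame_spacing,t_ill trajectory timing constants (s).
#' @param cp,r_lipid,dark_fraction,oligomer_n model constants.
#' @param n_boot bootstrap resamples per cell.
#' @param n_sim simulated datasets for the fit error.
#' @param seed integer seed for all stochastic stages.
#' @param max_lag MSD lags computed per cell.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(cells, calib, bulk_illumination = 0.003,
                            frame_spacing = 0.01, t_ill = 0.003,
                            cp = 0.676, r_lipid = 0.49, dark_fraction = 0.2,
                            oligomer_n = 1, n_boot = 100, n_sim = 1000,
                            seed = 1, max_lag = 5) {
  stopifnot(length(cells) >= 1, inherits(calib, "brightness_calibration"),
            bulk_illumination > 0, frame_spacing > 0, t_ill >= 0,
            cp > 0, cp < 1, r_lipid > 0,
            dark_fraction >= 0, dark_fraction < 1, oligomer_n >= 1)
  for (cell in cells) {
    for (p in c(cell$trajectories, cell$mask, cell$pattern_image))
      if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
    if (is.null(cell$pattern_image) &&
        (is.null(cell$on_mean) || is.null(cell$off_mean)))
      stop("cell '", cell$id, "': need on_mean/off_mean or a pattern_image")
  }
  structure(list(cells = cells, calib = calib,
                 bulk_illumination = bulk_illumination,
                 frame_spacing = frame_spacing, t_ill = t_ill, cp = cp,
                 r_lipid = r_lipid, dark_fraction = dark_fraction,
                 oligomer_n = as.integer(oligomer_n), n_boot = n_boot,
                 n_sim = n_sim, seed = seed, max_lag = max_lag),
            class = "analysis_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the per-cell analysis workflow
#'
#' For each cell: reads the trajectories, splits them into ON/OFF groups
#' under the cell's pattern mask, computes pooled MSDs, fits the two-point
#' diffusion model with bootstrap errors, forms `D_ON/D_OFF`, and converts
#' the pattern brightness into an obstacle density. The per-cell rows are
#' assembled into a [study_dataset()] and fitted with
#' [fit_apparent_radius()] plus [estimate_fit_error()]. Cells failing any
#' stage are skipped and counted.
#'
#' @param config an [analysis_config()].
#' @return list with `dataset` (study_dataset), `fit` (fit_result), and
#'   `report` (provenance: config hash, seed, package version, per-cell
#'   log).
#' @export
run_cell_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  rows <- list(); log <- list(); failed <- 0L
  for (i in seq_along(config$cells)) {
    cell <- config$cells[[i]]
    res <- try({
      trajs <- read_trajectories(cell$trajectories, config$frame_spacing)
      mask <- read_pattern_mask(cell$mask)
      grp <- classify_trajectories(trajs, mask)
      msd_on <- compute_msd(grp$on, config$max_lag)
      msd_off <- compute_msd(grp$off, config$max_lag)
      est_on <- fit_diffusion(msd_on, config$t_ill)
      est_off <- fit_diffusion(msd_off, config$t_ill)
      est_on$D_error <- as.numeric(bootstrap_diffusion(
        grp$on, config$t_ill, config$n_boot,
        seed = config$seed * 100 + i))
      est_off$D_error <- as.numeric(bootstrap_diffusion(
        grp$off, config$t_ill, config$n_boot,
        seed = config$seed * 100 + i + 50000))
      rat <- mobility_ratio(est_on, est_off)
      means <- if (!is.null(cell$pattern_image)) {
        img <- tiff::readTIFF(cell$pattern_image, as.is = TRUE)
        pattern_region_means(img, mask)
      } else list(on_mean = cell$on_mean, off_mean = cell$off_mean)
      rho_mgfp <- mgfp_density(means$on_mean, means$off_mean, config$calib,
                               config$bulk_illumination)
      rho_obs <- obstacle_density(rho_mgfp, config$dark_fraction,
                                  config$oligomer_n)
      list(row = data.frame(cell_id = cell$id %||% paste0("cell", i),
                            rho_mgfp = rho_mgfp, rho_obstacle = rho_obs,
                            ratio = rat$ratio, ratio_error = rat$ratio_error),
           log = list(n_tracks_on = length(unique(grp$on$track_id)),
                      n_tracks_off = length(unique(grp$off$track_id)),
                      discarded = grp$discarded_count))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failed <- failed + 1L
      log[[i]] <- list(cell = cell$id %||% i, error = as.character(res))
    } else {
      rows[[length(rows) + 1L]] <- res$row
      log[[i]] <- res$log
    }
  }
  if (!length(rows)) stop("all cells failed; nothing to fit")
  dataset <- study_dataset(do.call(rbind, rows),
                           oligomer_n = config$oligomer_n,
                           dark_fraction = config$dark_fraction)
  fit <- fit_apparent_radius(dataset, cp = config$cp,
                             r_lipid = config$r_lipid)
  fit <- estimate_fit_error(fit, dataset, n_sim = config$n_sim,
                            seed = config$seed)
  report <- list(package = "nerdmap",
                 version = as.character(utils::packageVersion("nerdmap")),
                 config_hash = .config_hash(config), seed = config$seed,
                 n_cells = nrow(dataset$cells), n_cells_failed = failed,
                 r_app = fit$r_app, r_app_error = fit$r_app_error,
                 r_poi_app = fit$r_poi_app, cells = log)
  list(dataset = dataset, fit = fit, report = report)
}

#' Run the NERD grid scan workflow
#'
#' Builds a [dataset_profile()] from an analyzed study dataset and scans the
#' (d_NERD, f_NERD) grid against the fitted apparent radius.
#'
#' @param config an [analysis_config()].
#' @param fit the [fit_result][fit_apparent_radius()] from
#'   [run_cell_analysis()] (with its error estimated).
#' @param dataset the corresponding [study_dataset()].
#' @param r_poi structural protein radius (nm) for the modeled core;
#'   defaults to the fitted `r_poi_app`.
#' @param ... passed to [scan_nerd_grid()].
#' @return a [scan_nerd_grid()] classification matrix.
#' @export
run_nerd_map <- function(config, fit, dataset, r_poi = NULL, ...) {
  stopifnot(inherits(config, "analysis_config"),
            inherits(fit, "fit_result"), inherits(dataset, "study_dataset"))
  if (is.na(fit$r_app_error))
    stop("fit error missing; run estimate_fit_error() first")
  profile <- profile_from_dataset(dataset, r_poi = r_poi %||% fit$r_poi_app,
                                  r_lipid = config$r_lipid, cp = config$cp)
  scan_nerd_grid(profile, c(fit$r_poi_app, fit$r_poi_app_error),
                 seed = config$seed, ...)
}

#' Write a machine-readable JSON report
#'
#' @param report the `report` element of [run_cell_analysis()].
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Summary table in the style of the published radius comparison
#'
#' One row per analyzed dataset: oligomeric state, structural radius, and
#' fitted apparent radius with its error.
#'
#' @param fits named list of [fit_result][fit_apparent_radius()] objects.
#' @param r_poi named numeric vector of structural radii (nm), matched by
#'   name; `NA` where unavailable.
#' @return data.frame with columns `dataset`, `oligomer_n`, `r_poi`,
#'   `r_poi_app`, `r_poi_app_error`.
#' @export
radius_table <- function(fits, r_poi = NULL) {
  stopifnot(length(fits) >= 1)
  data.frame(
    dataset = names(fits) %||% seq_along(fits),
    r_poi = if (is.null(r_poi)) NA_real_
            else unname(r_poi[names(fits)]),
    r_poi_app = vapply(fits, `[[`, numeric(1), "r_poi_app"),
    r_poi_app_error = vapply(fits, function(f)
      f$r_poi_app_error %||% NA_real_, numeric(1)),
    row.names = NULL)
}
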