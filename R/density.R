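# Molecular counting: single-fluorophore brightness calibration and
# conversion of bulk pattern brightness into obstacle densities.

#' Single-molecule brightness calibration
#'
#' Median integrated brightness of single fluorophores, computed from
#' localizations at or after `start_frame` (late frames avoid multimeric
#' species that have not yet partially bleached).
#'
#' @param localizations a [trajectory_set()] of single-molecule
#'   localizations with a `mass` column.
#' @param start_frame first frame included (typically 30-50).
#' @param calib_illumination illumination time of the calibration movie (s);
#'   default 20 ms.
#' @param min_n minimum number of localizations required.
#' @return an object of class `brightness_calibration`: list with
#'   `single_mgfp_brightness` (counts/frame), `calib_illumination`,
#'   `start_frame`, `n_molecules`.
#' @export
single_molecule_brightness <- function(localizations, start_frame = 30,
                                       calib_illumination = 0.02,
                                       min_n = 20) {
  stopifnot(inherits(localizations, "trajectory_set"), start_frame >= 0,
            calib_illumination > 0)
  m <- localizations$mass[localizations$frame >= start_frame]
  if (length(m) < min_n)
    stop("only ", length(m), " localizations at/after frame ", start_frame,
         "; lower start_frame")
  structure(list(single_mgfp_brightness = median(m),
                 calib_illumination = calib_illumination,
                 start_frame = start_frame,
                 n_molecules = length(m)),
            class = "brightness_calibration")
}

#' @export
print.brightness_calibration <- function(x, ...) {
  cat(sprintf(
    "Single-molecule brightness: %.4g counts/frame at %g s illumination (n = %d, frames >= %d)\n",
    x$single_mgfp_brightness, x$calib_illumination, x$n_molecules,
    x$start_frame))
  invisible(x)
}

#' Fluorophore surface density from pattern brightness
#'
#' The mean OFF-region pixel intensity (background) is subtracted from the
#' mean ON-region intensity and the result divided by the single-molecule
#' brightness, linearly adjusted to the bulk illumination time:
#' `rho_mGFP = (on_mean - off_mean) / (B_single * t_bulk / t_calib)`.
#'
#' @param on_mean,off_mean mean intensity of ON/OFF regions (counts per
#'   um^2); the images are assumed flat-field corrected
#'   (see [flatfield_correct()]).
#' @param calib a [single_molecule_brightness()] calibration.
#' @param bulk_illumination illumination time of the pattern image (s).
#' @return fluorophore density (per um^2).
#' @export
mgfp_density <- function(on_mean, off_mean, calib, bulk_illumination) {
  stopifnot(inherits(calib, "brightness_calibration"), bulk_illumination > 0)
  if (on_mean < off_mean)
    stop("ON mean below OFF mean: inverted pattern or flat-field failure")
  b <- calib$single_mgfp_brightness *
    bulk_illumination / calib$calib_illumination
  (on_mean - off_mean) / b
}

#' Obstacle density from fluorophore density
#'
#' Corrects the fluorophore density for non-fluorescent (immature) tags and
#' for the oligomeric state:
#' `rho_POI = rho_mGFP * (1 + dark_fraction) / n`. With the default 20%
#' dark mGFP the correction factor is exactly the published 1.2 (the dark
#' fraction is counted relative to the fluorescent population).
#'
#' @param rho_mgfp fluorophore density (per um^2).
#' @param dark_fraction dark-per-fluorescent tag ratio, in `[0, 1)`.
#' @param n_oligomer number of tags per immobilized obstacle (>= 1).
#' @return obstacle density (per um^2).
#' @export
obstacle_density <- function(rho_mgfp, dark_fraction = 0.2, n_oligomer = 1) {
  stopifnot(rho_mgfp >= 0, dark_fraction >= 0, dark_fraction < 1)
  if (n_oligomer < 1) stop("n_oligomer must be >= 1")
  rho_mgfp * (1 + dark_fraction) / n_oligomer
}

#' Reinterpret obstacle densities for a different oligomeric state
#'
#' Pure reinterpretation of already-corrected densities for a reanalysis
#' assuming `n_new` tags per obstacle: a monomer analysis at
#' 1000 obstacles/um^2 becomes a dimer analysis at 500/um^2.
#'
#' @param rho_obstacle_monomeric density under the monomer assumption
#'   (per um^2).
#' @param n_new assumed oligomer size (>= 1).
#' @return density per um^2 under the new assumption.
#' @export
reinterpret_oligomer <- function(rho_obstacle_monomeric, n_new) {
  stopifnot(all(rho_obstacle_monomeric >= 0))
  if (n_new < 1) stop("n_new must be >= 1")
  rho_obstacle_monomeric / n_new
}

#' Flat-field correction by reference division
#'
#' Divides an image by a normalized reference illumination image.
#'
#' @param img numeric matrix (counts).
#' @param reference numeric matrix of the same size; normalized internally
#'   to unit mean.
#' @return corrected matrix.
#' @export
flatfield_correct <- function(img, reference) {
  stopifnot(is.matrix(img), all(dim(img) == dim(reference)),
            all(reference > 0))
  img / (reference / mean(reference))
}

#' ON/OFF region mean intensities under a pattern mask
#'
#' @param img numeric matrix of pixel intensities (counts/pixel), same
#'   geometry as the mask raster.
#' @param mask a [render_pattern_mask()] object.
#' @param per_area return counts per um^2 (divide by the pixel area) rather
#'   than counts per pixel.
#' @return list with `on_mean` and `off_mean`.
#' @export
pattern_region_means <- function(img, mask, per_area = TRUE) {
  stopifnot(inherits(mask, "pattern_mask"), is.matrix(img),
            all(dim(img) == dim(mask$mask)))
  f <- if (per_area) mask$pixel_size^2 else 1
  list(on_mean = mean(img[mask$mask]) / f,
       off_mean = mean(img[!mask$mask]) / f)
}
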