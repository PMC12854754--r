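# Synthetic-data generators: obstacle fields, Brownian tracer trajectories,
# micropattern masks, percolation estimation, and noisy per-cell datasets.
# These emulate the study conditions of the micropatterning assay: 3 um dots
# on a 6 um pitch, 10 ms frames (3 ms illumination + 7 ms delay), ~40 nm
# localization precision, tracer D ~ 1 um^2/s, obstacle densities in the
# 10^2-10^3 um^-2 range.

#' Poisson field of disc obstacles
#'
#' Places immobile circular obstacles uniformly at random (overlapping-disc
#' model): the obstacle count is Poisson with mean `density * box_size^2` and
#' positions are i.i.d. uniform in the box. Each obstacle has an impenetrable
#' core and, optionally, a surrounding annulus of width `nerd_width` within
#' which tracer mobility is scaled by `nerd_factor`.
#'
#' @param density obstacle density (per um^2), >= 0.
#' @param core_radius impenetrable core radius (nm), > 0.
#' @param nerd_width annulus width (nm), >= 0.
#' @param nerd_factor mobility factor inside the annulus, in `[0, 1]`.
#' @param box_size box edge length (um); must exceed 50 core radii.
#' @param seed integer seed; identical seeds give identical fields.
#' @return an object of class `obstacle_field` with elements `x`, `y` (um),
#'   `core_radius`, `nerd_width` (nm), `nerd_factor`, `box_size` (um).
#' @export
place_obstacles <- function(density, core_radius, nerd_width = 0,
                            nerd_factor = 1, box_size, seed = NULL) {
  if (!is.numeric(density) || density < 0) stop("density must be >= 0")
  if (!is.numeric(core_radius) || core_radius <= 0)
    stop("core_radius must be > 0")
  stopifnot(nerd_width >= 0, nerd_factor >= 0, nerd_factor <= 1, box_size > 0)
  if (box_size * 1000 < 50 * core_radius)
    stop("box_size must cover at least 50 core radii")
  with_seed(seed, {
    n <- rpois(1, density * box_size^2)
    x <- runif(n, 0, box_size)
    y <- runif(n, 0, box_size)
  })
  structure(list(x = x, y = y, core_radius = core_radius,
                 nerd_width = nerd_width, nerd_factor = nerd_factor,
                 box_size = box_size, density = density, seed = seed),
            class = "obstacle_field")
}

#' @export
print.obstacle_field <- function(x, ...) {
  cat(sprintf(
    "Obstacle field: %d discs (core %.3g nm, annulus %.3g nm, f = %.3g) in %.3g x %.3g um\n",
    length(x$x), x$core_radius, x$nerd_width, x$nerd_factor,
    x$box_size, x$box_size))
  cat(sprintf("  coverage (cores) = %.4f\n",
              1 - exp(-x$density * pi * (x$core_radius / 1000)^2)))
  invisible(x)
}

#' Simulation configuration for tracer dynamics
#'
#' Time stepping and imaging parameters for [simulate_tracers()]. Frame
#' positions are the average of the sub-step positions during the
#' illumination window `t_ill` (motion blur), plus Gaussian localization
#' noise of SD `localization_sigma` per coordinate. Defaults reproduce the
#' imaging protocol of the assay: 10 ms frame spacing (3 ms illumination +
#' 7 ms delay) and 40 nm localization precision.
#'
#' `step_time` is chosen automatically unless given: small enough that the
#' r.m.s. sub-step is at most one fifth of the obstacle core radius
#' (resolution condition) and that at least 10 sub-positions fall within the
#' illumination window.
#'
#' @param free_diffusion free diffusion coefficient D (um^2/s).
#' @param frame_spacing time between frames (s).
#' @param t_ill illumination time per frame (s); 0 disables motion blur.
#' @param localization_sigma localization error SD (um); 0 disables noise.
#' @param step_time sub-step duration (s), or `NULL` for automatic choice.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(free_diffusion = 1, frame_spacing = 0.01,
                       t_ill = 0.003, localization_sigma = 0.04,
                       step_time = NULL) {
  stopifnot(free_diffusion > 0, frame_spacing > 0,
            t_ill >= 0, t_ill <= frame_spacing, localization_sigma >= 0)
  structure(list(free_diffusion = free_diffusion,
                 frame_spacing = frame_spacing, t_ill = t_ill,
                 localization_sigma = localization_sigma,
                 step_time = step_time, boundary = "periodic"),
            class = "sim_config")
}

# Resolve integer step counts from a sim_config and a core radius (nm).
.resolve_steps <- function(cfg, core_radius_nm) {
  # rms step sqrt(4 D dt) <= core/5; blur window sampled >= 10 times
  dt_core <- (core_radius_nm / 5000)^2 / (4 * cfg$free_diffusion)
  dt_blur <- if (cfg$t_ill > 0) cfg$t_ill / 10 else cfg$frame_spacing / 10
  dt <- cfg$step_time %||% min(dt_core, dt_blur, cfg$frame_spacing / 10)
  steps_per_frame <- max(10L, as.integer(ceiling(cfg$frame_spacing / dt)))
  dt <- cfg$frame_spacing / steps_per_frame
  if (is.finite(core_radius_nm) &&
      sqrt(4 * cfg$free_diffusion * dt) > core_radius_nm / 5000)
    warning("resolution condition violated: rms sub-step exceeds core_radius/5")
  blur_steps <- if (cfg$t_ill > 0)
    max(1L, as.integer(round(cfg$t_ill / dt))) else 1L
  list(dt = dt, steps_per_frame = steps_per_frame, blur_steps = blur_steps)
}

#' Simulate Brownian tracers in an obstacle field
#'
#' Monte-Carlo Brownian dynamics of point tracers among the reflecting disc
#' cores of an [place_obstacles()] field, with periodic boundaries. Each
#' sub-step is a Gaussian displacement; moves ending inside a core are
#' rejected (the tracer stays put), which realizes reflection with the
#' correct equilibrium for small steps. Displacements of steps originating
#' inside an annulus are scaled by `sqrt(nerd_factor)`, giving a local
#' diffusivity of `nerd_factor * free_diffusion` inside the ring. Reported
#' frame positions are motion-blurred averages over the illumination window
#' plus localization noise; coordinates are unwrapped (not folded back into
#' the box), so displacement statistics can be taken directly.
#'
#' @param field an [place_obstacles()] obstacle field.
#' @param cfg a [sim_config()].
#' @param n_tracers number of tracers (trajectories).
#' @param n_frames frames per trajectory.
#' @param seed integer seed.
#' @param mass constant integrated brightness value stored per localization.
#' @param keep_raw also keep pre-noise positions as columns
#'   `x_raw`/`y_raw`.
#' @return a [trajectory_set()]; empty when `n_tracers` or `n_frames` is 0.
#' @export
simulate_tracers <- function(field, cfg, n_tracers, n_frames, seed = NULL,
                             mass = 500, keep_raw = FALSE) {
  stopifnot(inherits(field, "obstacle_field"), inherits(cfg, "sim_config"),
            n_tracers >= 0, n_frames >= 0)
  if (n_tracers == 0 || n_frames == 0) {
    empty <- data.frame(track_id = integer(), frame = integer(),
                        x_um = numeric(), y_um = numeric(), mass = numeric())
    return(trajectory_set(empty, cfg$frame_spacing))
  }
  st <- .resolve_steps(cfg,
    if (length(field$x)) field$core_radius else Inf)
  sim <- with_seed(seed, cpp_simulate_tracers(
    field$x, field$y,
    field$core_radius / 1000, field$nerd_width / 1000, field$nerd_factor,
    field$box_size, cfg$free_diffusion, st$dt,
    st$steps_per_frame, st$blur_steps,
    as.integer(n_frames), as.integer(n_tracers), cfg$localization_sigma))
  rec <- data.frame(
    track_id = rep(seq_len(n_tracers), each = n_frames),
    frame = rep(seq_len(n_frames), n_tracers),
    x_um = as.vector(sim$x), y_um = as.vector(sim$y),
    mass = mass)
  if (keep_raw) {
    rec$x_raw <- as.vector(sim$x_raw)
    rec$y_raw <- as.vector(sim$y_raw)
  }
  out <- trajectory_set(rec, cfg$frame_spacing)
  attr(out, "sim_steps") <- st
  out
}

#' Micropattern mask of circular dots
#'
#' Boolean raster of circular ON dots on a square lattice, mirroring the
#' stamped streptavidin patterns (default: 3 um dots, 6 um center-to-center
#' pitch). Dot centers sit at `(pitch/2 + k*pitch)` so that
#' `extent == pitch` yields a single centered dot.
#'
#' @param dot_diameter dot diameter (um); must be smaller than `pitch`.
#' @param pitch lattice constant (um).
#' @param pixel_size raster pixel edge (um); must not exceed
#'   `dot_diameter/4` (else the dots are undersampled).
#' @param extent raster edge length (um).
#' @return an object of class `pattern_mask`: list with logical matrix
#'   `mask` (rows = y, columns = x), `pixel_size`, `dot_diameter`, `pitch`,
#'   `extent`.
#' @export
render_pattern_mask <- function(dot_diameter = 3, pitch = 6,
                                pixel_size = 0.1, extent = 12) {
  stopifnot(dot_diameter >= 0, pitch > 0, pixel_size > 0, extent > 0)
  if (dot_diameter >= pitch && dot_diameter > 0)
    stop("dot_diameter must be smaller than pitch")
  if (dot_diameter > 0 && pixel_size > dot_diameter / 4)
    stop("pixel_size > dot_diameter/4: pattern undersampled")
  n <- as.integer(round(extent / pixel_size))
  centers <- (seq_len(n) - 0.5) * pixel_size
  # distance of each pixel centre to the nearest lattice point, per axis
  ax <- abs((centers - pitch / 2) %% pitch)
  ax <- pmin(ax, pitch - ax)
  m <- outer(ax^2, ax^2, "+") <= (dot_diameter / 2)^2
  if (dot_diameter == 0) m[] <- FALSE
  structure(list(mask = m, pixel_size = pixel_size,
                 dot_diameter = dot_diameter, pitch = pitch, extent = extent),
            class = "pattern_mask")
}

#' @export
print.pattern_mask <- function(x, ...) {
  cat(sprintf(
    "Pattern mask: %d x %d px (%.3g um/px), %.3g um dots on %.3g um pitch, ON fraction %.4f\n",
    nrow(x$mask), ncol(x$mask), x$pixel_size, x$dot_diameter, x$pitch,
    mean(x$mask)))
  invisible(x)
}

#' Write/read a pattern mask as TIFF plus JSON sidecar
#'
#' @param mask a [render_pattern_mask()] object.
#' @param path TIFF file path; the sidecar is written to `<path>.json`.
#' @return `read_pattern_mask` returns a `pattern_mask`;
#'   `write_pattern_mask` returns `path` invisibly.
#' @export
write_pattern_mask <- function(mask, path) {
  stopifnot(inherits(mask, "pattern_mask"))
  tiff::writeTIFF(mask$mask * 1, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(pixel_size = mask$pixel_size, dot_diameter = mask$dot_diameter,
         pitch = mask$pitch, extent = mask$extent),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pattern_mask
#' @export
read_pattern_mask <- function(path) {
  m <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(mask = m > 0.5, pixel_size = meta$pixel_size,
                 dot_diameter = meta$dot_diameter, pitch = meta$pitch,
                 extent = meta$extent),
            class = "pattern_mask")
}

#' Critical coverage at the continuum percolation threshold
#'
#' Estimates the critical area coverage of randomly placed overlapping discs
#' by spanning-cluster simulation. At a trial coverage, discs are placed
#' Poisson-uniformly in a square box with free boundaries and clustered by
#' union-find over the overlap graph; a replicate percolates if one cluster
#' touches both the left and right box edge, or both the bottom and top edge.
#' The density is bisected to the 50% spanning probability and the returned
#' coverage `1 - exp(-rho * pi * R^2)` is refined by a probit fit over all
#' evaluated densities, which also supplies the standard error.
#'
#' The threshold is a size-independent constant (~0.676 for overlapping
#' discs); `core_radius` only sets the scale of the simulated geometry.
#'
#' @param core_radius disc radius (nm).
#' @param box_size box edge (um); must be at least 100 disc radii (default
#'   150, which keeps the finite-size bias below the Monte-Carlo error).
#' @param n_reps spanning replicates per evaluated density (>= 200 for the
#'   defaults to be meaningful).
#' @param n_iter bisection iterations after bracketing.
#' @param bracket initial coverage bracket.
#' @param seed integer seed.
#' @return an object of class `percolation_estimate`: list with `coverage`,
#'   `se`, and the evaluation table `evals` (coverage, spanning count, reps).
#' @export
estimate_percolation_coverage <- function(core_radius = 5, box_size = NULL,
                                          n_reps = 200, n_iter = 8,
                                          bracket = c(0.60, 0.75),
                                          seed = NULL) {
  stopifnot(core_radius > 0, n_reps >= 10)
  r_um <- core_radius / 1000
  box_size <- box_size %||% (150 * r_um)
  if (box_size < 100 * r_um)
    stop("box_size below 100 disc radii: finite-size bias too large")
  span_count <- function(cov) {
    rho <- -log(1 - cov) / (pi * r_um^2)
    hits <- 0L
    for (i in seq_len(n_reps)) {
      n <- rpois(1, rho * box_size^2)
      hits <- hits + cpp_discs_span(runif(n, 0, box_size),
                                    runif(n, 0, box_size), r_um, box_size)
    }
    hits
  }
  with_seed(seed, {
    evals <- data.frame(coverage = numeric(), k = integer(), n = integer())
    note <- function(cov) {
      k <- span_count(cov)
      evals <<- rbind(evals, data.frame(coverage = cov, k = k, n = n_reps))
      k / n_reps
    }
    lo <- bracket[1]; hi <- bracket[2]
    p_lo <- note(lo); p_hi <- note(hi)
    if (p_lo >= 0.5 || p_hi <= 0.5)
      stop("bracket does not straddle the 50% spanning probability")
    for (i in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      p <- note(mid)
      if (p < 0.5) lo <- mid else hi <- mid
    }
  })
  # probit interpolation over all bisection evaluations
  fit <- try(glm(cbind(k, n - k) ~ coverage, family = binomial("probit"),
                 data = evals), silent = TRUE)
  if (!inherits(fit, "try-error") && coef(fit)[2] > 0) {
    b <- coef(fit)
    c50 <- unname(-b[1] / b[2])
    V <- vcov(fit)
    g <- c(-1 / b[2], b[1] / b[2]^2)     # gradient of -a/b
    se <- sqrt(drop(t(g) %*% V %*% g))
  } else {
    c50 <- (lo + hi) / 2
    se <- (hi - lo) / 2
  }
  structure(list(coverage = c50, se = se, evals = evals,
                 box_over_radius = box_size / r_um, n_reps = n_reps),
            class = "percolation_estimate")
}

#' @export
print.percolation_estimate <- function(x, ...) {
  cat(sprintf(
    "Percolation threshold coverage: %.4f +/- %.4f (box = %.0f R, %d reps/density)\n",
    x$coverage, x$se, x$box_over_radius, x$n_reps))
  invisible(x)
}

#' Generate a noisy per-cell study dataset
#'
#' Emulates a measured dataset for one protein: for each cell an obstacle
#' density is drawn from `density_sampler`, the true mobility ratio is
#' computed from the NERD model ([mobility_nerd()]), and the observed
#' density/ratio pair is drawn from Gaussians centered on the true values
#' with the stated relative SDs. Observed ratios are clipped to
#' `(0, 1.05]`; the number of clipped values is recorded in attribute
#' `n_clipped`.
#'
#' @param params a [nerd_params()] object (use `d_nerd = 0` or `f_nerd = 1`
#'   for inert obstacles).
#' @param density_sampler either a function `n -> densities` or a numeric
#'   sample of densities to resample from.
#' @param rel_err_density relative SD of the observed density.
#' @param rel_err_ratio relative SD of the observed mobility ratio.
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @param label dataset label.
#' @return a [study_dataset()] with attributes `rel_err_density`,
#'   `rel_err_ratio`, `true_params` and `n_clipped`. `rho_obstacle` holds the
#'   observed (noisy) density; `rho_mgfp` the corresponding uncorrected
#'   fluorophore density.
#' @export
generate_cell_dataset <- function(params, density_sampler,
                                  rel_err_density = 0.05,
                                  rel_err_ratio = 0.05,
                                  n_cells, seed = NULL, label = "synthetic") {
  stopifnot(inherits(params, "nerd_params"), n_cells >= 1,
            rel_err_density >= 0, rel_err_ratio >= 0)
  draw <- if (is.function(density_sampler)) density_sampler
  else function(n) sample(density_sampler, n, replace = TRUE)
  with_seed(seed, {
    rho <- draw(n_cells)
    for (try in 1:100) {
      bad <- !is.finite(rho) | rho < 0
      if (!any(bad)) break
      rho[bad] <- draw(sum(bad))
    }
    if (any(!is.finite(rho) | rho < 0))
      stop("density_sampler keeps yielding negative densities")
    ratio_true <- mobility_nerd(rho, params)
    rho_obs <- rho * (1 + rel_err_density * rnorm(n_cells))
    rho_obs[rho_obs < 0] <- 0
    ratio_obs <- ratio_true * (1 + rel_err_ratio * rnorm(n_cells))
  })
  n_clipped <- sum(ratio_obs <= 0 | ratio_obs > 1.05)
  ratio_obs <- pmin(pmax(ratio_obs, 1e-6), 1.05)
  cells <- data.frame(cell_id = sprintf("cell%03d", seq_len(n_cells)),
                      rho_mgfp = rho_obs / 1.2,
                      rho_obstacle = rho_obs,
                      ratio = ratio_obs,
                      ratio_error = rel_err_ratio * ratio_true)
  out <- study_dataset(cells, oligomer_n = 1L, label = label)
  attr(out, "rel_err_density") <- rel_err_density
  attr(out, "rel_err_ratio") <- rel_err_ratio
  attr(out, "true_params") <- params
  attr(out, "n_clipped") <- n_clipped
  out
}
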