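# Continuum-percolation models of obstructed tracer diffusion.
#
# Radii are in nm throughout, obstacle densities in um^-2. The nm^2 -> um^2
# conversion (x 1e-6) lives in .nm2_to_um2 only, so the model formulas read
# exactly as published.

.nm2_to_um2 <- function(area_nm2) area_nm2 * 1e-6

#' Tracer mobility ratio for inert disc obstacles
#'
#' Relative tracer diffusion `D_ON/D_OFF` in the presence of randomly
#' immobilized, mutually overlapping circular obstacles of combined
#' (obstacle + tracer) radius `r_combined`:
#' \deqn{D_{ON}/D_{OFF} = 1 - \sqrt{1 - e^{-\rho \pi R^2 / C_P}}}
#' where \eqn{C_P \approx 0.676} is the critical area coverage at the
#' continuum percolation threshold of overlapping discs.
#'
#' @param rho obstacle density (per um^2); vectorized.
#' @param r_combined combined in-plane radius of obstacle plus tracer (nm).
#' @param cp percolation threshold coverage (area fraction).
#' @return mobility ratio in (0, 1]; 1 at `rho = 0`.
#' @seealso [mobility_nerd()] for obstacles with a reduced-diffusivity ring,
#'   [fit_apparent_radius()] for inverting this relation.
#' @examples
#' mobility_inert(500, 2.6)   # ~0.875
#' @export
mobility_inert <- function(rho, r_combined, cp = 0.676) {
  stopifnot(all(rho >= 0), r_combined > 0, cp > 0, cp < 1)
  z <- rho * pi * .nm2_to_um2(r_combined^2) / cp
  1 - sqrt(pmax(0, 1 - exp(-z)))
}

#' Tracer mobility ratio for obstacles carrying a NERD ring
#'
#' Extends [mobility_inert()] to protein obstacles surrounded by a ring-shaped
#' nanoenvironment with reduced diffusivity (NERD) of width `d_nerd` in which
#' tracer mobility is scaled by `f_nerd` relative to the bulk membrane. The
#' impenetrable core has radius `r_poi + r_lipid` (protein plus tracer); the
#' ring contributes through
#' \deqn{x = (R_{POI} + R_{lipid} + d_{NERD})^2 - (R_{POI} + R_{lipid})^2.}
#' The core term carries the percolation divisor \eqn{C_P}; the ring factor's
#' exponentials intentionally do not (the model is implemented exactly as
#' published).
#'
#' With `f_nerd = 1` or `d_nerd = 0` the ring factor is identically 1 and the
#' result equals `mobility_inert(rho, r_poi + r_lipid, cp)`.
#'
#' @param rho obstacle density (per um^2); vectorized.
#' @param params a [nerd_params()] object; alternatively supply the individual
#'   values via `...`.
#' @param ... passed to [nerd_params()] when `params` is not given.
#' @return mobility ratio in (0, 1].
#' @examples
#' p <- nerd_params(r_poi = 1.94, r_lipid = 0.49, d_nerd = 0.7, f_nerd = 0.1)
#' mobility_nerd(1000, p)
#' @export
mobility_nerd <- function(rho, params = NULL, ...) {
  p <- if (is.null(params)) nerd_params(...) else params
  stopifnot(inherits(p, "nerd_params"), all(rho >= 0))
  r_core <- p$r_poi + p$r_lipid
  x <- (r_core + p$d_nerd)^2 - r_core^2           # nm^2, >= 0
  q <- rho * pi * .nm2_to_um2(x)
  core <- mobility_inert(rho, r_core, p$cp)
  omf <- 1 - p$f_nerd
  ring <- 1 - (1 - exp(-q)) * omf + (exp(-2 * q) - exp(-q)) * omf^2
  core * ring
}

#' NERD model parameters
#'
#' Bundles the geometry of an obstacle with a reduced-diffusivity ring:
#' protein in-plane radius, lipid tracer radius, ring width `d_nerd` (nm) and
#' ring mobility factor `f_nerd` (1 = bulk mobility, 0 = immobile).
#'
#' @param r_poi protein in-plane radius (nm), > 0.
#' @param r_lipid lipid tracer radius (nm), > 0. Default 0.49 nm
#'   (sphingomyelin tracer, see [lipid_tracer_radius()]).
#' @param d_nerd ring width (nm), >= 0.
#' @param f_nerd ring mobility factor in `[0, 1]`.
#' @param cp percolation threshold coverage.
#' @return an object of class `nerd_params`.
#' @export
nerd_params <- function(r_poi, r_lipid = 0.49, d_nerd = 0, f_nerd = 1,
                        cp = 0.676) {
  stopifnot(
    is.numeric(r_poi), r_poi > 0,
    is.numeric(r_lipid), r_lipid > 0,
    is.numeric(d_nerd), d_nerd >= 0,
    is.numeric(f_nerd), f_nerd >= 0, f_nerd <= 1,
    cp > 0, cp < 1
  )
  structure(list(r_poi = r_poi, r_lipid = r_lipid, d_nerd = d_nerd,
                 f_nerd = f_nerd, cp = cp),
            class = "nerd_params")
}

#' @export
print.nerd_params <- function(x, ...) {
  cat(sprintf(
    "NERD parameters: R_POI = %.3g nm, R_lipid = %.3g nm, d_NERD = %.3g nm, f_NERD = %.3g, C_P = %.3g\n",
    x$r_poi, x$r_lipid, x$d_nerd, x$f_nerd, x$cp))
  invisible(x)
}

#' Per-cell study dataset
#'
#' The unit on which the apparent radius is fitted: one row per cell with the
#' obstacle density within patterned (ON) areas and the measured mobility
#' ratio `D_ON/D_OFF`.
#'
#' @param cells data.frame with columns `cell_id`, `rho_mgfp`, `rho_obstacle`
#'   (per um^2), `ratio`, `ratio_error`.
#' @param oligomer_n assumed number of mGFP tags per immobilized obstacle.
#' @param dark_fraction fraction of non-fluorescent mGFP used for the density
#'   correction.
#' @param label free-text dataset label.
#' @return an object of class `study_dataset`.
#' @export
study_dataset <- function(cells, oligomer_n = 1L, dark_fraction = 0.2,
                          label = "") {
  cells <- as.data.frame(cells)
  need <- c("cell_id", "rho_mgfp", "rho_obstacle", "ratio", "ratio_error")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols))
    stop("study_dataset: missing columns: ", paste(missing_cols, collapse = ", "))
  stopifnot(all(cells$rho_mgfp >= 0), all(cells$rho_obstacle >= 0),
            all(cells$ratio > 0), oligomer_n >= 1)
  structure(list(cells = cells, oligomer_n = as.integer(oligomer_n),
                 dark_fraction = dark_fraction, label = label),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Study dataset '%s': %d cells, oligomer n = %d\n",
              x$label, nrow(x$cells), x$oligomer_n))
  cat(sprintf("  density range %.0f - %.0f / um^2, ratio range %.3f - %.3f\n",
              min(x$cells$rho_obstacle), max(x$cells$rho_obstacle),
              min(x$cells$ratio), max(x$cells$ratio)))
  invisible(x)
}

#' Read/write a study dataset as CSV
#'
#' @param data a [study_dataset()].
#' @param path CSV file path.
#' @param ... passed to [study_dataset()] on read.
#' @return `read_study_dataset` returns a `study_dataset`;
#'   `write_study_dataset` returns `path` invisibly.
#' @export
write_study_dataset <- function(data, path) {
  stopifnot(inherits(data, "study_dataset"))
  utils::write.csv(data$cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_dataset
#' @export
read_study_dataset <- function(path, ...) {
  study_dataset(utils::read.csv(path), ...)
}

#' Fit the apparent combined radius to per-cell data
#'
#' Nonlinear least squares of the inert-obstacle model ([mobility_inert()])
#' over the per-cell `(rho_obstacle, ratio)` pairs, with the combined radius
#' `R_app` as the sole free parameter. The apparent protein radius is
#' `R_POI,app = R_app - r_lipid`; any lipid nanoenvironment contributes to it.
#'
#' The minimization is an exact one-dimensional search (coarse log-grid
#' bracket plus golden-section refinement) and is deterministic. By default
#' all cells enter with equal weight; `weighted = TRUE` weights by
#' `1/ratio_error^2`.
#'
#' @param data a [study_dataset()].
#' @param cp percolation threshold coverage.
#' @param r_lipid lipid tracer radius (nm), subtracted to give `R_POI,app`.
#'   Its own uncertainty is deliberately not folded into the fit error.
#' @param weighted weight cells by their inverse squared ratio error.
#' @param bounds search interval for `R_app` (nm).
#' @return an object of class `fit_result` with elements `r_app`,
#'   `r_poi_app`, `r_app_error` (`NA` until [estimate_fit_error()] is run),
#'   `residual_norm`, `n_cells`, `cp`, `r_lipid`.
#' @export
fit_apparent_radius <- function(data, cp = 0.676, r_lipid = 0.49,
                                weighted = FALSE, bounds = c(0.05, 30)) {
  stopifnot(inherits(data, "study_dataset"))
  cells <- data$cells
  if (nrow(cells) < 3) stop("need at least 3 cells to fit the radius")
  rho <- cells$rho_obstacle
  ratio <- cells$ratio
  pos <- rho[rho > 0]
  if (length(pos) >= 2 && max(pos) / min(pos) <= 2)
    warning("obstacle densities span less than a 2-fold range; ",
            "the radius may be poorly constrained")
  if (all(abs(ratio - 1) < 0.02))
    warning("all mobility ratios are ~1; the radius is unidentifiable")
  if (weighted) {
    w <- 1 / pmax(cells$ratio_error, 1e-12)^2
    w <- w / mean(w)
    # fold weights in by scaling residuals: fit on sqrt(w)-scaled copies
    obj <- function(R) sum(w * (ratio - mobility_inert(rho, R, cp))^2)
    opt <- stats::optimize(obj, interval = bounds, tol = 1e-9)
    r_app <- opt$minimum
    ssr <- opt$objective
  } else {
    f <- cpp_fit_radius(rho, ratio, cp, bounds[1], bounds[2])
    r_app <- f$R
    ssr <- f$ssr
  }
  if (r_app <= bounds[1] * 1.01 || r_app >= bounds[2] * 0.99)
    warning("fitted radius at the search boundary; fit not converged")
  structure(list(r_app = r_app, r_app_error = NA_real_,
                 r_poi_app = r_app - r_lipid, r_poi_app_error = NA_real_,
                 residual_norm = sqrt(ssr), n_cells = nrow(cells),
                 cp = cp, r_lipid = r_lipid, weighted = weighted),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  err <- if (is.na(x$r_app_error)) "" else sprintf(" +/- %.3f", x$r_app_error)
  cat(sprintf("Apparent combined radius R_app  = %.3f%s nm (n = %d cells)\n",
              x$r_app, err, x$n_cells))
  cat(sprintf("Apparent protein radius R_POI,app = %.3f%s nm (R_lipid = %.2f nm)\n",
              x$r_poi_app, err, x$r_lipid))
  invisible(x)
}

#' Fit error by refitting simulated datasets
#'
#' Estimates the variability of the fitted `R_app` by simulating `n_sim`
#' synthetic datasets at the fitted radius and refitting each one. Every
#' synthetic dataset mirrors the characteristics of the measured one: cell
#' densities are resampled (with replacement) from the observed densities or
#' drawn from a fitted log-normal, multiplicative Gaussian noise with the
#' stated relative errors is applied to density and mobility ratio, and the
#' number of cells is kept. The standard deviation of the refitted radii is
#' returned and stamped onto the fit result.
#'
#' @param fit a [fit_result][fit_apparent_radius()].
#' @param data the [study_dataset()] the fit was obtained from.
#' @param n_sim number of simulated datasets.
#' @param seed integer seed (RNG state is restored afterwards).
#' @param rel_err_density relative SD of per-cell density noise; default
#'   taken from `attr(data, "rel_err_density")`, else 0.05.
#' @param rel_err_ratio relative SD of per-cell ratio noise; default the
#'   median observed `ratio_error/ratio`, or `attr(data, "rel_err_ratio")`.
#' @param density_model `"bootstrap"` resamples observed densities;
#'   `"lognormal"` draws from a log-normal matched to them.
#' @return the updated `fit_result` with `r_app_error`/`r_poi_app_error` set
#'   and attribute `refit_radii` holding the simulated radii.
#' @export
estimate_fit_error <- function(fit, data, n_sim = 1000, seed = NULL,
                               rel_err_density = NULL, rel_err_ratio = NULL,
                               density_model = c("bootstrap", "lognormal")) {
  stopifnot(inherits(fit, "fit_result"), inherits(data, "study_dataset"))
  density_model <- match.arg(density_model)
  cells <- data$cells
  n <- nrow(cells)
  rel_err_density <- rel_err_density %||%
    attr(data, "rel_err_density") %||% 0.05
  rel_err_ratio <- rel_err_ratio %||% attr(data, "rel_err_ratio") %||%
    stats::median(cells$ratio_error / cells$ratio)
  with_seed(seed, {
    rho_true <- if (density_model == "bootstrap") {
      matrix(sample(cells$rho_obstacle, n * n_sim, replace = TRUE), n, n_sim)
    } else {
      lr <- log(cells$rho_obstacle[cells$rho_obstacle > 0])
      matrix(exp(rnorm(n * n_sim, mean(lr), sd(lr))), n, n_sim)
    }
    ratio_true <- 1 - sqrt(pmax(0, 1 - exp(-rho_true * pi *
      .nm2_to_um2(fit$r_app^2) / fit$cp)))
    rho_obs <- rho_true * (1 + rel_err_density * matrix(rnorm(n * n_sim), n))
    rho_obs[rho_obs < 0] <- 0
    ratio_obs <- ratio_true * (1 + rel_err_ratio * matrix(rnorm(n * n_sim), n))
    ratio_obs <- pmin(pmax(ratio_obs, 1e-6), 1.05)
    radii <- cpp_fit_radius_many(rho_obs, ratio_obs, fit$cp, 0.05, 30)
  })
  at_bound <- radii <= 0.0505 | radii >= 29.7
  if (mean(at_bound) > 0.05)
    stop(sprintf("%.0f%% of simulated refits failed to converge",
                 100 * mean(at_bound)))
  err <- sd(radii[!at_bound])
  fit$r_app_error <- err
  fit$r_poi_app_error <- err
  attr(fit, "refit_radii") <- radii
  fit
}
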