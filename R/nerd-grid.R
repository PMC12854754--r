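# Mapping the (d_NERD, f_NERD) parameter space: modeled apparent-radius
# distributions per ring geometry, classified against the experimental value.

#' Dataset profile for NERD modeling
#'
#' The characteristics of a measured dataset that the grid scan reproduces:
#' the density distribution, the per-cell relative errors, the number of
#' cells, and the structural radii.
#'
#' @param densities numeric sample of obstacle densities (resampled from
#'   during modeling) or a function `n -> densities`.
#' @param rel_err_density,rel_err_ratio per-cell relative measurement errors.
#' @param n_cells number of cells per modeled dataset (>= 3).
#' @param r_poi protein in-plane radius (nm).
#' @param r_lipid lipid tracer radius (nm).
#' @param cp percolation threshold coverage.
#' @return an object of class `dataset_profile`.
#' @export
dataset_profile <- function(densities, rel_err_density, rel_err_ratio,
                            n_cells, r_poi, r_lipid = 0.49, cp = 0.676) {
  stopifnot(n_cells >= 3, rel_err_density >= 0, rel_err_ratio >= 0,
            r_poi > 0, r_lipid > 0)
  structure(list(densities = densities, rel_err_density = rel_err_density,
                 rel_err_ratio = rel_err_ratio, n_cells = as.integer(n_cells),
                 r_poi = r_poi, r_lipid = r_lipid, cp = cp),
            class = "dataset_profile")
}

#' Profile extracted from a measured study dataset
#'
#' @param data a [study_dataset()].
#' @param r_poi protein radius (nm) used for the modeled obstacle core.
#' @param r_lipid lipid tracer radius (nm).
#' @param rel_err_density relative density error; default from the dataset
#'   attribute, else 0.05.
#' @param cp percolation threshold coverage.
#' @return a [dataset_profile()] using the dataset's empirical densities.
#' @export
profile_from_dataset <- function(data, r_poi, r_lipid = 0.49,
                                 rel_err_density = NULL, cp = 0.676) {
  stopifnot(inherits(data, "study_dataset"))
  rel_err_density <- rel_err_density %||%
    attr(data, "rel_err_density") %||% 0.05
  rel_err_ratio <- attr(data, "rel_err_ratio") %||%
    median(data$cells$ratio_error / data$cells$ratio)
  dataset_profile(data$cells$rho_obstacle, rel_err_density, rel_err_ratio,
                  nrow(data$cells), r_poi, r_lipid, cp)
}

#' Modeled apparent protein radius for one NERD geometry
#'
#' Implements the modeling procedure used to interpret the assay: a large
#' pool of `(rho, D_ON/D_OFF)` value pairs is generated from the NERD model
#' with the profile's density distribution and measurement noise; then, for
#' `n_iter` iterations, `n_cells` pairs are drawn from the pool and fitted
#' with the inert-obstacle model exactly as the experimental data are. The
#' lipid radius is subtracted from each fitted combined radius. Returned are
#' the mean and SD of the fitted `R_POI,app` over iterations — the result
#' one would extract when measuring a protein carrying this particular NERD.
#'
#' @param profile a [dataset_profile()].
#' @param d_nerd ring width (nm).
#' @param f_nerd ring mobility factor.
#' @param n_iter number of draw-and-fit iterations.
#' @param pool_size size of the generated value-pair pool ("several
#'   thousand").
#' @param seed integer seed.
#' @return list with `mean`, `sd` (nm) and `n_fail` (non-converged fits).
#' @export
model_expected_radius <- function(profile, d_nerd, f_nerd, n_iter = 1000,
                                  pool_size = 5000, seed = NULL) {
  stopifnot(inherits(profile, "dataset_profile"))
  params <- nerd_params(profile$r_poi, profile$r_lipid, d_nerd, f_nerd,
                        profile$cp)
  with_seed(seed, {
    pool <- generate_cell_dataset(params, profile$densities,
                                  profile$rel_err_density,
                                  profile$rel_err_ratio,
                                  n_cells = pool_size)
    idx <- matrix(sample.int(pool_size, profile$n_cells * n_iter,
                             replace = TRUE), profile$n_cells, n_iter)
  })
  rho <- matrix(pool$cells$rho_obstacle[idx], nrow(idx))
  ratio <- matrix(pool$cells$ratio[idx], nrow(idx))
  radii <- cpp_fit_radius_many(rho, ratio, profile$cp, 0.05, 30)
  bad <- radii <= 0.0505 | radii >= 29.7
  if (mean(bad) > 0.05)
    stop(sprintf("%.0f%% of modeled fits failed to converge", 100 * mean(bad)))
  r <- radii[!bad] - profile$r_lipid
  list(mean = mean(r), sd = sd(r), n_fail = sum(bad))
}

#' Classify one NERD geometry against the experimental radius
#'
#' Default rule (`"interval"`): *consistent* when the experimental mean lies
#' within the error of the modeled value; else *borderline* when the two
#' error intervals overlap; else *not_consistent*. The alternative
#' `"d0_interval"` rule instead grades *borderline* when the modeled mean
#' falls inside the interval of the `d_nerd = 0` scenario (supplied via
#' `d0`); the two published variants of the rule disagree, so both are
#' available.
#'
#' @param experimental,modeled numeric `c(mean, err)` pairs (nm).
#' @param rule `"interval"` (default) or `"d0_interval"`.
#' @param d0 `c(mean, err)` of the `d_nerd = 0` scenario; required for the
#'   `"d0_interval"` rule.
#' @return one of `"consistent"`, `"borderline"`, `"not_consistent"`.
#' @export
classify_nerd <- function(experimental, modeled,
                          rule = c("interval", "d0_interval"), d0 = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(experimental) >= 2, length(modeled) >= 2,
            experimental[2] >= 0, modeled[2] >= 0)
  em <- experimental[1]; ee <- experimental[2]
  mm <- modeled[1]; me <- modeled[2]
  overlap <- (em - ee) <= (mm + me) && (mm - me) <= (em + ee)
  if (rule == "interval") {
    if (abs(em - mm) <= me) "consistent"
    else if (overlap) "borderline"
    else "not_consistent"
  } else {
    if (is.null(d0)) stop("the d0_interval rule needs the d_nerd = 0 interval")
    if (!overlap) "not_consistent"
    else if (abs(mm - d0[1]) <= d0[2]) "borderline"
    else "consistent"
  }
}

#' Scan the (d_NERD, f_NERD) grid
#'
#' Runs [model_expected_radius()] for every combination of ring width and
#' mobility factor and classifies each against the experimental apparent
#' radius with [classify_nerd()]. The default grid — ring widths from 0 to
#' 2.1 nm in steps of 0.35 nm (half a lipid layer; 0.7 nm corresponds to a
#' single layer of lipids) by mobility factors 0.05 to 0.95 in steps of
#' 0.05 — has the canonical 7 x 19 = 133 combinations.
#'
#' @param profile a [dataset_profile()].
#' @param experimental `c(mean, err)` of the measured `R_POI,app` (nm).
#' @param d_values,f_values grid values (nm / unitless).
#' @param n_iter,pool_size passed to [model_expected_radius()].
#' @param seed integer seed; each grid cell uses an independent substream.
#' @param rule classification rule, see [classify_nerd()].
#' @return an object of class `nerd_matrix`: data.frame with columns `d`,
#'   `f`, `mod_mean`, `mod_sd`, `label`, plus attributes `experimental`,
#'   `d_values`, `f_values`.
#' @export
scan_nerd_grid <- function(profile, experimental,
                           d_values = seq(0, 2.1, by = 0.35),
                           f_values = seq(0.05, 0.95, by = 0.05),
                           n_iter = 1000, pool_size = 5000, seed = NULL,
                           rule = c("interval", "d0_interval")) {
  stopifnot(inherits(profile, "dataset_profile"),
            length(d_values) >= 1, length(f_values) >= 1)
  rule <- match.arg(rule)
  grid <- expand.grid(d = d_values, f = f_values)
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(grid))
           else as.list((abs(seed) %% 1048576) * 1024 + seq_len(nrow(grid)))
  mods <- Map(function(d, f, s)
    model_expected_radius(profile, d, f, n_iter, pool_size, seed = s),
    grid$d, grid$f, seeds)
  grid$mod_mean <- vapply(mods, `[[`, numeric(1), "mean")
  grid$mod_sd <- vapply(mods, `[[`, numeric(1), "sd")
  d0 <- if (rule == "d0_interval") {
    i0 <- which(grid$d == min(grid$d))[1]
    c(grid$mod_mean[i0], grid$mod_sd[i0])
  } else NULL
  grid$label <- mapply(function(mm, ms)
    classify_nerd(experimental, c(mm, ms), rule = rule, d0 = d0),
    grid$mod_mean, grid$mod_sd)
  structure(grid, class = c("nerd_matrix", "data.frame"),
            experimental = experimental, d_values = d_values,
            f_values = f_values, rule = rule)
}

#' @export
print.nerd_matrix <- function(x, ...) {
  e <- attr(x, "experimental")
  cat(sprintf(
    "NERD classification matrix: %d combinations vs R_POI,app = %.2f +/- %.2f nm\n",
    nrow(x), e[1], e[2]))
  tab <- table(factor(x$label,
                      c("consistent", "borderline", "not_consistent")))
  print(tab)
  invisible(x)
}

#' Write a NERD matrix as CSV
#'
#' @param x a [scan_nerd_grid()] matrix.
#' @param path CSV path.
#' @export
write_nerd_matrix <- function(x, path) {
  stopifnot(inherits(x, "nerd_matrix"))
  utils::write.csv(as.data.frame(x)[, c("d", "f", "label",
                                        "mod_mean", "mod_sd")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Heatmap of a NERD classification matrix
#'
#' Uses ggplot2 when available, else a base-graphics image. Green =
#' consistent, yellow = borderline, red = not consistent.
#'
#' @param x a [scan_nerd_grid()] matrix.
#' @param file optional output file (png); plotted to the active device
#'   otherwise.
#' @return the ggplot object, or `NULL` for base graphics, invisibly.
#' @export
plot_nerd_matrix <- function(x, file = NULL) {
  stopifnot(inherits(x, "nerd_matrix"))
  cols <- c(consistent = "#4daf4a", borderline = "#ffd92f",
            not_consistent = "#e41a1c")
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    df <- as.data.frame(x)
    p <- ggplot2::ggplot(df, ggplot2::aes(
      factor(.data$d), factor(.data$f), fill = .data$label)) +
      ggplot2::geom_tile(color = "grey30") +
      ggplot2::scale_fill_manual(values = cols) +
      ggplot2::labs(x = "d_NERD (nm)", y = "f_NERD") +
      ggplot2::theme_minimal()
    print(p)
    return(invisible(p))
  }
  z <- matrix(match(x$label, names(cols)),
              length(attr(x, "d_values")), length(attr(x, "f_values")))
  graphics::image(attr(x, "d_values"), attr(x, "f_values"), z,
                  col = cols, xlab = "d_NERD (nm)", ylab = "f_NERD")
  invisible(NULL)
}
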