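# Pooled MSD analysis and the two-point diffusion fit with motion-blur
# correction: MSD(t_lag) = 4 D (t_lag - t_ill/3) + 4 sigma^2.

#' Pooled mean square displacement
#'
#' Time-and-ensemble averaged MSD: for each lag the mean squared displacement
#' over all overlapping frame pairs of all tracks is pooled. Frame gaps
#' within a track contribute only to the lags they actually span.
#'
#' @param trajs a [trajectory_set()].
#' @param max_lag largest lag in frames; truncated (with a message) when it
#'   exceeds the longest track.
#' @return an object of class `msd_curve`: list with `lag_times` (s), `msd`
#'   (um^2), `n_pairs`, `frame_spacing`, `n_trajectories`.
#' @export
compute_msd <- function(trajs, max_lag = 10) {
  stopifnot(inherits(trajs, "trajectory_set"), max_lag >= 1)
  fs <- attr(trajs, "frame_spacing")
  dt <- data.table::as.data.table(as.data.frame(trajs))
  if (!nrow(dt)) stop("empty trajectory set")
  longest <- dt[, diff(range(frame)), by = track_id][, max(V1)]
  if (longest < 1) stop("no displacement pairs at lag 1")
  if (max_lag > longest) {
    message("max_lag truncated to longest track span (", longest, " frames)")
    max_lag <- longest
  }
  data.table::setkey(dt, track_id, frame)
  res <- lapply(seq_len(max_lag), function(L) {
    shifted <- dt[, .(track_id, frame = frame - L, x2 = x_um, y2 = y_um)]
    j <- dt[shifted, on = c("track_id", "frame"), nomatch = NULL]
    if (!nrow(j)) return(c(NA_real_, 0))
    c(mean((j$x2 - j$x_um)^2 + (j$y2 - j$y_um)^2), nrow(j))
  })
  msd <- vapply(res, `[`, numeric(1), 1)
  np <- vapply(res, `[`, numeric(1), 2)
  structure(list(lag_times = seq_len(max_lag) * fs, msd = msd,
                 n_pairs = as.integer(np), frame_spacing = fs,
                 n_trajectories = length(unique(dt$track_id))),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags, %d trajectories\n",
              length(x$lag_times), x$n_trajectories))
  print(data.frame(lag_s = x$lag_times, msd_um2 = x$msd, n_pairs = x$n_pairs))
  invisible(x)
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares line through the first `n_points` of MSD versus
#' `(t_lag - t_ill/3)`; the slope is `4 D` and the intercept `4 sigma^2`
#' (localization precision). With the default `n_points = 2` this is the
#' exact two-point solution used throughout the assay, which is robust to
#' the mask-induced deviation from linearity at long lags. A negative
#' intercept is truncated to `sigma = 0` and flagged.
#'
#' @param curve an [compute_msd()] curve.
#' @param t_ill illumination time (s) for the motion-blur correction.
#' @param n_points number of leading lags used (>= 2).
#' @param use_points optional explicit lag indices (overrides `n_points`),
#'   e.g. `3:6` to fit a late-lag window.
#' @return an object of class `diffusion_estimate`: list with `D` (um^2/s),
#'   `sigma_loc` (um), `D_error` (`NA` until bootstrapped),
#'   `n_trajectories`, and `negative_intercept` flag.
#' @export
fit_diffusion <- function(curve, t_ill = 0.003, n_points = 2,
                          use_points = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  idx <- use_points %||% seq_len(n_points)
  if (length(idx) < 2) stop("need at least 2 MSD points to fit")
  if (max(idx) > length(curve$lag_times))
    stop("curve has fewer lags than requested")
  t <- curve$lag_times[idx] - t_ill / 3
  y <- curve$msd[idx]
  if (anyNA(y)) stop("MSD undefined at requested lags")
  fit <- lm(y ~ t)
  slope <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
  neg <- icpt < 0
  structure(list(D = slope / 4,
                 sigma_loc = if (neg) 0 else sqrt(icpt / 4),
                 D_error = NA_real_,
                 n_trajectories = curve$n_trajectories,
                 negative_intercept = neg,
                 lags_used = idx, t_ill = t_ill),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  err <- if (is.na(x$D_error)) "" else sprintf(" +/- %.4g", x$D_error)
  cat(sprintf("D = %.4g%s um^2/s, sigma_loc = %.4g um (n = %d tracks)\n",
              x$D, err, x$sigma_loc, x$n_trajectories))
  invisible(x)
}

# Per-track displacement sums for the first `max_lag` lags; the bootstrap
# resampling unit is the trajectory.
.track_lag_table <- function(trajs, max_lag) {
  dt <- data.table::as.data.table(as.data.frame(trajs))
  data.table::setkey(dt, track_id, frame)
  ids <- unique(dt$track_id)
  out <- lapply(seq_len(max_lag), function(L) {
    shifted <- dt[, .(track_id, frame = frame - L, x2 = x_um, y2 = y_um)]
    j <- dt[shifted, on = c("track_id", "frame"), nomatch = NULL]
    j[, sq := (x2 - x_um)^2 + (y2 - y_um)^2]
    agg <- j[, .(s = sum(sq), n = .N), by = track_id]
    s <- setNames(numeric(length(ids)), ids)
    n <- setNames(numeric(length(ids)), ids)
    s[as.character(agg$track_id)] <- agg$s
    n[as.character(agg$track_id)] <- agg$n
    list(s = s, n = n)
  })
  list(ids = ids, lags = out)
}

#' Bootstrap error of the fitted diffusion coefficient
#'
#' Resamples whole trajectories with replacement, recomputes the pooled MSD
#' over the first `n_points` lags and refits the two-point diffusion model;
#' the returned `D_error` is the standard deviation of the refitted `D`.
#' Resamples without displacement pairs at every used lag are skipped and
#' counted.
#'
#' @param trajs a [trajectory_set()] with at least 5 trajectories.
#' @param t_ill illumination time (s).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param n_points number of leading lags in the refit.
#' @return numeric `D_error` with attributes `n_skipped` and `D_boot`.
#' @export
bootstrap_diffusion <- function(trajs, t_ill = 0.003, n_boot = 200,
                                seed = NULL, n_points = 2) {
  stopifnot(inherits(trajs, "trajectory_set"))
  tab <- .track_lag_table(trajs, n_points)
  K <- length(tab$ids)
  if (K < 5) stop("need at least 5 trajectories to bootstrap")
  fs <- attr(trajs, "frame_spacing")
  t <- seq_len(n_points) * fs - t_ill / 3
  S <- vapply(tab$lags, `[[`, numeric(K), "s")   # K x n_points
  N <- vapply(tab$lags, `[[`, numeric(K), "n")
  with_seed(seed, {
    Ds <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      pick <- sample.int(K, K, replace = TRUE)
      ns <- colSums(N[pick, , drop = FALSE])
      if (any(ns == 0)) next
      m <- colSums(S[pick, , drop = FALSE]) / ns
      # closed-form simple linear regression slope
      slope <- sum((t - mean(t)) * (m - mean(m))) / sum((t - mean(t))^2)
      Ds[b] <- slope / 4
    }
  })
  skipped <- sum(is.na(Ds))
  if (skipped) message(skipped, " degenerate bootstrap resample(s) skipped")
  structure(sd(Ds, na.rm = TRUE), n_skipped = skipped, D_boot = Ds)
}

#' Per-cell mobility ratio
#'
#' `D_ON/D_OFF` with first-order (delta-method) propagation of the two
#' bootstrap errors:
#' `err = ratio * sqrt((e_on/D_on)^2 + (e_off/D_off)^2)`.
#'
#' @param on,off [diffusion_estimate][fit_diffusion()] objects for the ON and
#'   OFF areas; missing `D_error`s are treated as 0.
#' @return list with `ratio` and `ratio_error`.
#' @export
mobility_ratio <- function(on, off) {
  stopifnot(inherits(on, "diffusion_estimate"),
            inherits(off, "diffusion_estimate"))
  if (!is.finite(off$D) || off$D <= 0) stop("D_OFF must be positive")
  e_on <- if (is.na(on$D_error)) 0 else on$D_error
  e_off <- if (is.na(off$D_error)) 0 else off$D_error
  r <- on$D / off$D
  list(ratio = r,
       ratio_error = r * sqrt((e_on / on$D)^2 + (e_off / off$D)^2))
}
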