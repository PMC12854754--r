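# Trajectory containers and ON/OFF classification against pattern masks.

#' Single-molecule trajectory set
#'
#' Time-ordered localizations grouped by track, with integrated brightness.
#' The canonical record columns are `track_id`, `frame`, `x_um`, `y_um`,
#' `mass`; frames must be strictly increasing within a track (gaps are
#' allowed and contribute only to the lags they span).
#'
#' @param records data.frame with the canonical columns.
#' @param frame_spacing time between consecutive frames (s).
#' @return an object of class `trajectory_set` (a data.frame with
#'   attribute `frame_spacing`).
#' @export
trajectory_set <- function(records, frame_spacing) {
  stopifnot(is.numeric(frame_spacing), frame_spacing > 0)
  records <- as.data.frame(records)
  need <- c("track_id", "frame", "x_um", "y_um", "mass")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("trajectory_set: missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(records)) {
    if (!all(is.finite(records$x_um)) || !all(is.finite(records$y_um)))
      stop("trajectory_set: non-finite coordinates")
    records <- records[order(records$track_id, records$frame), , drop = FALSE]
    rownames(records) <- NULL
    dup <- duplicated(records[, c("track_id", "frame")])
    if (any(dup))
      stop("duplicate (track, frame) records in track(s): ",
           paste(unique(records$track_id[dup]), collapse = ", "))
  }
  structure(records, class = c("trajectory_set", "data.frame"),
            frame_spacing = frame_spacing)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d localizations in %d tracks (frame spacing %g s)\n",
              nrow(x), length(unique(x$track_id)), attr(x, "frame_spacing")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Read and write trajectory tables
#'
#' CSV (or tab-separated) tables with columns `track_id`, `frame`, `x_um`,
#' `y_um`, `mass`. Rows with missing or non-finite values in the required
#' columns are dropped and counted in attribute `n_malformed`.
#'
#' @param path file path.
#' @param frame_spacing time between frames (s).
#' @return `read_trajectories` returns a [trajectory_set()];
#'   `write_trajectories` returns `path` invisibly.
#' @export
read_trajectories <- function(path, frame_spacing) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path)
  need <- c("track_id", "frame", "x_um", "y_um", "mass")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("trajectory file lacks columns: ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(dt)[, need]
  ok <- stats::complete.cases(df) & is.finite(df$x_um) & is.finite(df$y_um)
  n_bad <- sum(!ok)
  if (n_bad) message(n_bad, " malformed row(s) dropped")
  df <- df[ok, , drop = FALSE]
  if (!nrow(df)) stop("empty trajectory file: ", path)
  out <- trajectory_set(df, frame_spacing)
  attr(out, "n_malformed") <- n_bad
  out
}

#' @rdname read_trajectories
#' @param trajs a [trajectory_set()].
#' @export
write_trajectories <- function(trajs, path) {
  stopifnot(inherits(trajs, "trajectory_set"))
  cols <- c("track_id", "frame", "x_um", "y_um", "mass")
  data.table::fwrite(as.data.frame(trajs)[, cols], path)
  invisible(path)
}

#' Fold unwrapped simulated coordinates back into a box
#'
#' @param trajs a [trajectory_set()].
#' @param box_size box edge (um).
#' @return a `trajectory_set` with coordinates modulo `box_size`.
#' @export
wrap_trajectories <- function(trajs, box_size) {
  stopifnot(inherits(trajs, "trajectory_set"), box_size > 0)
  trajs$x_um <- trajs$x_um %% box_size
  trajs$y_um <- trajs$y_um %% box_size
  trajs
}

#' Split trajectories into ON and OFF groups using a pattern mask
#'
#' A trajectory is ON if all its localizations fall on ON pixels and OFF if
#' all fall on OFF pixels; mixed trajectories (straddling a dot edge) are
#' discarded and counted. Localizations outside the mask extent cause their
#' trajectory to be discarded, with a warning. The alternative
#' `rule = "per_point"` splits each track into maximal single-label runs
#' instead of discarding mixed tracks.
#'
#' @param trajs a [trajectory_set()].
#' @param mask a [render_pattern_mask()] / [read_pattern_mask()] object.
#' @param rule `"whole"` (default) or `"per_point"`.
#' @return list with elements `on`, `off` (trajectory sets) and
#'   `discarded_count` (number of discarded trajectories).
#' @export
classify_trajectories <- function(trajs, mask, rule = c("whole", "per_point")) {
  stopifnot(inherits(trajs, "trajectory_set"), inherits(mask, "pattern_mask"))
  rule <- match.arg(rule)
  fs <- attr(trajs, "frame_spacing")
  df <- as.data.frame(trajs)
  nx <- ncol(mask$mask); ny <- nrow(mask$mask)
  ix <- floor(df$x_um / mask$pixel_size) + 1
  iy <- floor(df$y_um / mask$pixel_size) + 1
  inside <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  lab <- rep(NA, nrow(df))                     # TRUE = ON pixel
  lab[inside] <- mask$mask[cbind(iy[inside], ix[inside])]
  if (any(!inside))
    warning(sum(!inside), " localization(s) outside the mask extent; ",
            "affected trajectories discarded")
  take <- function(sel) trajectory_set(df[sel, , drop = FALSE], fs)
  if (rule == "whole") {
    by_track <- split(seq_len(nrow(df)), df$track_id)
    status <- vapply(by_track, function(i) {
      l <- lab[i]
      if (anyNA(l)) "drop" else if (all(l)) "on" else if (all(!l)) "off"
      else "drop"
    }, character(1))
    on_idx <- unlist(by_track[status == "on"], use.names = FALSE)
    off_idx <- unlist(by_track[status == "off"], use.names = FALSE)
    list(on = take(sort(on_idx)), off = take(sort(off_idx)),
         discarded_count = sum(status == "drop"))
  } else {
    keep <- !is.na(lab)
    d2 <- df[keep, , drop = FALSE]; l2 <- lab[keep]
    # new track ids: break at track change or label change
    brk <- c(TRUE, d2$track_id[-1] != d2$track_id[-nrow(d2)] |
                   l2[-1] != l2[-length(l2)])
    run <- cumsum(brk)
    d2$track_id <- run
    lens <- tabulate(run)
    ok <- lens[run] >= 2                      # minimum length for pooling
    list(on = take_run(d2, l2, ok, TRUE, fs),
         off = take_run(d2, l2, ok, FALSE, fs),
         discarded_count = sum(!keep) + sum(!ok))
  }
}

take_run <- function(d2, l2, ok, want, fs) {
  trajectory_set(d2[ok & (l2 == want), , drop = FALSE], fs)
}
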