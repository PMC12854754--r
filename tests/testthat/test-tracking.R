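test_that("trajectory sets enforce their invariants", {
  df <- data.frame(track_id = c(1, 1, 1), frame = 1:3,
                   x_um = c(0, 1, 2), y_um = 0, mass = 500)
  ts <- trajectory_set(df, 0.01)
  expect_s3_class(ts, "trajectory_set")
  dup <- rbind(df, df[2, ])
  expect_error(trajectory_set(dup, 0.01), "track\\(s\\): 1")
  bad <- df; bad$x_um[2] <- NaN
  expect_error(trajectory_set(bad, 0.01), "non-finite")
  expect_error(trajectory_set(df[, -3], 0.01), "missing columns")
})

test_that("trajectory files round-trip and malformed rows are counted", {
  ts <- rw_tracks(5, 10, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_trajectories(ts, f)
  back <- read_trajectories(f, 0.01)
  expect_equal(as.data.frame(back), as.data.frame(ts), tolerance = 1e-12,
               ignore_attr = TRUE)
  # inject a malformed row
  lines <- readLines(f)
  writeLines(c(lines, "99,1,NA,0.5,500"), f)
  expect_message(back2 <- read_trajectories(f, 0.01), "malformed")
  expect_equal(attr(back2, "n_malformed"), 1)
  expect_error(read_trajectories(tempfile(), 0.01), "no such file")
})

test_that("whole-trajectory ON/OFF classification follows the mask rule", {
  mask <- render_pattern_mask(3, 6, 0.1, 12)    # dots centred at 3 and 9
  mk <- function(id, xs, ys) data.frame(track_id = id,
                                        frame = seq_along(xs),
                                        x_um = xs, y_um = ys, mass = 500)
  trajs <- trajectory_set(rbind(
    mk(1, c(3.0, 3.2, 2.9), c(3.0, 3.1, 3.0)),    # inside a dot -> ON
    mk(2, c(5.9, 6.0, 6.1), c(5.9, 6.0, 6.1)),    # between dots -> OFF
    mk(3, c(3.0, 4.6, 6.0), c(3.0, 3.0, 3.0))),   # straddles the edge
    0.01)
  cls <- classify_trajectories(trajs, mask)
  expect_equal(unique(cls$on$track_id), 1)
  expect_equal(unique(cls$off$track_id), 2)
  expect_equal(cls$discarded_count, 1)
  # all-OFF mask: every track OFF, nothing discarded
  off_mask <- render_pattern_mask(0, 6, 0.1, 12)
  cls2 <- classify_trajectories(trajs, off_mask)
  expect_equal(sort(unique(cls2$off$track_id)), c(1, 2, 3))
  expect_equal(cls2$discarded_count, 0)
  # points beyond the mask extent discard their trajectory with a warning
  out <- trajectory_set(mk(9, c(3, 30), c(3, 3)), 0.01)
  expect_warning(cls3 <- classify_trajectories(out, mask), "outside")
  expect_equal(cls3$discarded_count, 1)
})

test_that("ON/OFF split on uniform data yields statistically equal D", {
  ts <- rw_tracks(150, 10, D = 0.8, seed = 5, box = 12)
  wrapped <- wrap_trajectories(ts, 12)
  on_all <- classify_trajectories(wrapped, render_pattern_mask(3, 6, 0.1, 12))
  # compare tracks that happen to be fully ON vs fully OFF
  d_on <- fit_diffusion(compute_msd(on_all$on, 2), t_ill = 0)$D
  d_off <- fit_diffusion(compute_msd(on_all$off, 2), t_ill = 0)$D
  e_on <- as.numeric(bootstrap_diffusion(on_all$on, 0, 100, seed = 6))
  e_off <- as.numeric(bootstrap_diffusion(on_all$off, 0, 100, seed = 7))
  expect_lt(abs(d_on - d_off), 3 * sqrt(e_on^2 + e_off^2))
})

test_that("pooled MSD reproduces closed forms", {
  still <- trajectory_set(data.frame(track_id = 1, frame = 1:6,
                                     x_um = 2, y_um = 3, mass = 1), 0.01)
  expect_equal(compute_msd(still, 3)$msd, rep(0, 3))
  v <- 2                                         # ballistic x = v t
  ball <- trajectory_set(data.frame(track_id = 1, frame = 1:10,
                                    x_um = v * (1:10) * 0.01, y_um = 0,
                                    mass = 1), 0.01)
  curve <- compute_msd(ball, 4)
  expect_equal(curve$msd, (v * (1:4) * 0.01)^2, tolerance = 1e-12)
  expect_true(all(diff(curve$n_pairs) <= 0))
  # pooled Brownian MSD: 4 D t within 3 SE; overlapping pairs at lag L are
  # correlated, leaving ~n_pairs/L independent pairs of relative SD 1
  ts <- rw_tracks(300, 12, D = 1, seed = 8)
  c2 <- compute_msd(ts, 4)
  se <- c2$msd * sqrt((1:4) / c2$n_pairs)
  expect_true(all(abs(c2$msd - 4 * (1:4) * 0.01) < 3 * se))
})

test_that("pooled MSD is invariant to track order and global translation", {
  ts <- rw_tracks(20, 8, seed = 9)
  base <- compute_msd(ts, 3)
  df <- as.data.frame(ts)
  shuf <- trajectory_set(df[sample(nrow(df)), ], 0.01)
  expect_equal(compute_msd(shuf, 3)$msd, base$msd, tolerance = 1e-12)
  moved <- df; moved$x_um <- moved$x_um + 100; moved$y_um <- moved$y_um - 50
  expect_equal(compute_msd(trajectory_set(moved, 0.01), 3)$msd, base$msd,
               tolerance = 1e-10)
})

test_that("frame gaps contribute only to the lags they span", {
  gap <- trajectory_set(data.frame(track_id = 1, frame = c(1, 2, 4),
                                   x_um = c(0, 1, 3), y_um = 0, mass = 1),
                        0.01)
  curve <- compute_msd(gap, 3)
  expect_equal(curve$n_pairs, c(1L, 1L, 1L))     # lags 1 (1->2), 2 (2->4), 3
  expect_equal(curve$msd, c(1, 4, 9))
  expect_message(compute_msd(gap, 10), "truncated")
})

test_that("two-point diffusion fit solves the blur-corrected model exactly", {
  curve <- exact_msd_curve(D = 1, sigma = 0.04, t_ill = 0.003)
  est <- fit_diffusion(curve, t_ill = 0.003)
  expect_equal(est$D, 1, tolerance = 1e-12)
  expect_equal(est$sigma_loc, 0.04, tolerance = 1e-12)
  # the stated worked example: MSD points 0.0424 and 0.0824 um^2
  expect_equal(curve$msd, c(0.0424, 0.0824), tolerance = 1e-12)
  # linearity: doubling the MSD doubles D and 4 sigma^2
  twice <- curve; twice$msd <- 2 * curve$msd
  est2 <- fit_diffusion(twice, t_ill = 0.003)
  expect_equal(est2$D, 2, tolerance = 1e-12)
  expect_equal(est2$sigma_loc^2, 2 * 0.04^2, tolerance = 1e-12)
  # negative intercepts are truncated and flagged
  neg <- exact_msd_curve(D = 1, sigma = 0, t_ill = 0.003)
  neg$msd <- neg$msd - 0.001
  estn <- fit_diffusion(neg, t_ill = 0.003)
  expect_true(estn$negative_intercept)
  expect_equal(estn$sigma_loc, 0)
  expect_error(fit_diffusion(curve, 0.003, n_points = 1), "at least 2")
})

test_that("bootstrap diffusion errors behave as advertised", {
  one <- rw_tracks(1, 12, seed = 10)
  df <- as.data.frame(one)
  dup <- do.call(rbind, lapply(1:8, function(i) {
    d <- df; d$track_id <- i; d
  }))
  dup_ts <- trajectory_set(dup, 0.01)
  expect_equal(as.numeric(bootstrap_diffusion(dup_ts, 0, 50, seed = 11)), 0,
               tolerance = 1e-12)
  ts <- rw_tracks(100, 10, seed = 12)
  e1 <- bootstrap_diffusion(ts, 0, 100, seed = 13)
  e2 <- bootstrap_diffusion(ts, 0, 100, seed = 13)
  expect_identical(as.numeric(e1), as.numeric(e2))
  expect_error(bootstrap_diffusion(rw_tracks(3, 5), 0, 10), "at least 5")
  # ~1/sqrt(n) scaling of the error with the number of tracks
  big <- rw_tracks(400, 10, seed = 14)
  small <- trajectory_set(as.data.frame(big)[big$track_id <= 100, ], 0.01)
  r <- as.numeric(bootstrap_diffusion(small, 0, 300, seed = 15)) /
    as.numeric(bootstrap_diffusion(big, 0, 300, seed = 16))
  expect_equal(r, 2, tolerance = 0.3)
})

test_that("mobility ratios propagate bootstrap errors to first order", {
  mk <- function(D, err) structure(list(D = D, sigma_loc = 0, D_error = err,
                                        n_trajectories = 10L,
                                        negative_intercept = FALSE),
                                   class = "diffusion_estimate")
  expect_equal(mobility_ratio(mk(1, 0), mk(1, 0))$ratio, 1)
  r <- mobility_ratio(mk(0.5, 0), mk(1, 0))
  expect_equal(r$ratio, 0.5)
  expect_equal(r$ratio_error, 0)
  r2 <- mobility_ratio(mk(0.5, 0.05), mk(1, 0.1))
  expect_equal(r2$ratio_error, 0.5 * sqrt(0.01 + 0.01), tolerance = 1e-12)
  expect_error(mobility_ratio(mk(0.5, 0), mk(0, 0)), "positive")
})
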