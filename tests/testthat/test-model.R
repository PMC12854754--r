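test_that("inert-obstacle mobility matches independent evaluation and limits", {
  expect_equal(mobility_inert(0, 2.6), 1)
  expect_equal(mobility_inert(500, 2.6), oracle_inert(500, 2.6),
               tolerance = 1e-12)
  expect_equal(mobility_inert(500, 2.6), 0.8752, tolerance = 1e-4)
  # algebraic identity: filling/cp = ln(4/3) gives exactly 1/2
  rho <- log(4 / 3) * 0.676 / (pi * 2.6^2 * 1e-6)
  expect_equal(mobility_inert(rho, 2.6), 0.5, tolerance = 1e-12)
  # strictly decreasing in density and radius, limits 0 and 1
  rhos <- seq(0, 5000, by = 100)
  expect_true(all(diff(mobility_inert(rhos, 2.6)) < 0))
  rr <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(vapply(rr, function(R)
    mobility_inert(800, R), numeric(1))) < 0))
  expect_lt(mobility_inert(1e9, 2.6), 1e-6)
  expect_equal(mobility_inert(800, 1e-8), 1, tolerance = 1e-6)
})

test_that("NERD model collapses to the inert model when the ring vanishes", {
  rhos <- c(0, 100, 500, 2000)
  p_f1 <- nerd_params(2, 0.5, d_nerd = 1.4, f_nerd = 1)
  p_d0 <- nerd_params(2, 0.5, d_nerd = 0, f_nerd = 0.3)
  expect_equal(mobility_nerd(rhos, p_f1), mobility_inert(rhos, 2.5),
               tolerance = 1e-14)
  expect_equal(mobility_nerd(rhos, p_d0), mobility_inert(rhos, 2.5),
               tolerance = 1e-14)
})

test_that("immobile ring reduces to the closed-form ring factor", {
  # at f_NERD = 0 the ring factor simplifies to exp(-2 rho pi x)
  p <- nerd_params(2, 0.5, d_nerd = 0.7, f_nerd = 0)
  rho <- 500
  x_um2 <- ((2.5 + 0.7)^2 - 2.5^2) * 1e-6
  expect_equal(mobility_nerd(rho, p),
               mobility_inert(rho, 2.5) * exp(-2 * rho * pi * x_um2),
               tolerance = 1e-12)
})

test_that("NERD mobility is monotone in ring width and mobility factor", {
  rho <- 800
  for (f in c(0, 0.3, 0.9)) {
    vals <- vapply(seq(0, 2.1, by = 0.35), function(d)
      mobility_nerd(rho, nerd_params(2, 0.5, d, f)), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))       # non-increasing in d
  }
  for (d in c(0.35, 0.7, 2.1)) {
    vals <- vapply(seq(0.05, 1, by = 0.05), function(f)
      mobility_nerd(rho, nerd_params(2, 0.5, d, f)), numeric(1))
    expect_true(all(diff(vals) >= -1e-12))      # non-decreasing in f
    expect_true(all(vals <= mobility_inert(rho, 2.5) + 1e-12))
  }
})

test_that("radius fit recovers noiseless data at machine precision", {
  rho <- seq(100, 2000, length.out = 20)
  cells <- data.frame(cell_id = seq_along(rho), rho_mgfp = rho / 1.2,
                      rho_obstacle = rho,
                      ratio = mobility_inert(rho, 3.0),
                      ratio_error = 0.01)
  ds <- study_dataset(cells)
  fit <- fit_apparent_radius(ds)
  expect_equal(fit$r_app, 3.0, tolerance = 1e-7)
  expect_equal(fit$r_poi_app, 3.0 - 0.49, tolerance = 1e-7)
  # cross-check against stats::nls as an independent optimizer (tiny jitter
  # keeps nls away from its zero-residual pathology)
  jit <- cells
  set.seed(1)
  jit$ratio <- jit$ratio + rnorm(nrow(jit), 0, 1e-5)
  m <- nls(ratio ~ 1 - sqrt(1 - exp(-rho_obstacle * pi * R^2 * 1e-6 / 0.676)),
           data = jit, start = list(R = 1))
  fit_j <- fit_apparent_radius(study_dataset(jit))
  expect_equal(fit_j$r_app, unname(coef(m)), tolerance = 1e-5)
})

test_that("radius fit is invariant to cell order and duplication", {
  ds <- generate_cell_dataset(nerd_params(2.11, 0.49),
                              function(n) runif(n, 50, 2000),
                              0.05, 0.05, 40, seed = 7)
  f0 <- fit_apparent_radius(ds)
  shuf <- ds
  shuf$cells <- ds$cells[sample(nrow(ds$cells)), ]
  dup <- ds
  dup$cells <- rbind(ds$cells, ds$cells)
  expect_equal(fit_apparent_radius(shuf)$r_app, f0$r_app, tolerance = 1e-6)
  expect_equal(fit_apparent_radius(dup)$r_app, f0$r_app, tolerance = 1e-6)
})

test_that("degenerate fits are flagged", {
  flat <- data.frame(cell_id = 1:5, rho_mgfp = 1:5, rho_obstacle = 1:5,
                     ratio = rep(1, 5), ratio_error = 0.01)
  w <- capture_warnings(fit_apparent_radius(study_dataset(flat)))
  expect_true(any(grepl("unidentifiable|span", w)))
  expect_error(fit_apparent_radius(study_dataset(flat[1:2, ])),
               "at least 3 cells")
})

test_that("simulated-dataset fit error vanishes without measurement noise", {
  ds <- generate_cell_dataset(nerd_params(2.11, 0.49),
                              function(n) runif(n, 100, 2000),
                              0, 0, 30, seed = 3)
  fit <- fit_apparent_radius(ds)
  fit <- estimate_fit_error(fit, ds, n_sim = 200, seed = 4,
                            rel_err_density = 0, rel_err_ratio = 0)
  expect_lt(fit$r_app_error, 1e-6)
})

test_that("fit error is seed-reproducible and scales like 1/sqrt(n_cells)", {
  ds88 <- generate_cell_dataset(nerd_params(2.11, 0.49),
                                function(n) runif(n, 0, 2000),
                                0.05, 0.05, 88, seed = 11)
  f88 <- fit_apparent_radius(ds88)
  e1 <- estimate_fit_error(f88, ds88, n_sim = 400, seed = 5)$r_app_error
  e2 <- estimate_fit_error(f88, ds88, n_sim = 400, seed = 5)$r_app_error
  expect_identical(e1, e2)
  ds22 <- generate_cell_dataset(nerd_params(2.11, 0.49),
                                function(n) runif(n, 0, 2000),
                                0.05, 0.05, 22, seed = 11)
  f22 <- fit_apparent_radius(ds22)
  e22 <- estimate_fit_error(f22, ds22, n_sim = 400, seed = 6)$r_app_error
  expect_equal(e22 / e1, 2, tolerance = 0.3)
})

test_that("study dataset round-trips through CSV", {
  ds <- generate_cell_dataset(nerd_params(2, 0.49),
                              function(n) runif(n, 100, 1000),
                              0.05, 0.05, 10, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_study_dataset(ds, f)
  back <- read_study_dataset(f)
  expect_equal(back$cells$rho_obstacle, ds$cells$rho_obstacle,
               tolerance = 1e-9)
  expect_equal(back$cells$ratio, ds$cells$ratio, tolerance = 1e-9)
})
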