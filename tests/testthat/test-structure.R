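test_that("oriented structures load with vdW radii and leaflet metadata", {
  f <- write_mini_pdb(data.frame(elem = "C", x = 0, y = 0, z = 7),
                      z_top = 15, waters = 2)
  at <- load_oriented_structure(f)
  expect_equal(nrow(at), 1)
  expect_equal(at$vdw, 1.7)
  expect_equal(attr(at, "z_top"), 15)
  expect_equal(attr(at, "n_excluded"), 4)       # 2 waters + 2 DUM
  # without DUM atoms the boundary must be supplied
  f2 <- write_mini_pdb(data.frame(elem = "C", x = 0, y = 0, z = 7),
                       dum = FALSE)
  expect_error(load_oriented_structure(f2), "z_top")
  expect_equal(attr(load_oriented_structure(f2, z_top = 12), "z_top"), 12)
  expect_error(load_oriented_structure(tempfile()), "no such file")
})

test_that("unknown elements fall back with a warning", {
  f <- write_mini_pdb(data.frame(elem = c("C", "XX"), x = c(0, 3),
                                 y = 0, z = 7))
  expect_warning(at <- load_oriented_structure(f), "XX")
  expect_equal(at$vdw[2], 1.7)
})

test_that("leaflet slab selection uses a closed z interval", {
  f <- write_mini_pdb(data.frame(elem = "C", x = c(0, 1, 2, 3),
                                 y = 0, z = c(-10, 0, 7, 15)), z_top = 15)
  at <- load_oriented_structure(f)
  sel <- select_leaflet(at)
  expect_equal(sel$z, c(0, 7, 15))              # both boundaries retained
  expect_error(select_leaflet(at, 20, 30), "no atoms")
  expect_error(select_leaflet(at, 5, 5), "below")
  low <- write_mini_pdb(data.frame(elem = "C", x = 0, y = 0, z = -10))
  expect_error(select_leaflet(load_oriented_structure(low, z_top = 15)),
               "no atoms")
})

test_that("projected hull radius reproduces closed-form geometries", {
  # single carbon: disc of its vdW radius (1.7 A = 0.17 nm)
  f1 <- write_mini_pdb(data.frame(elem = "C", x = 0, y = 0, z = 7))
  r1 <- inplane_hull_radius(select_leaflet(load_oriented_structure(f1)))
  expect_equal(as.numeric(r1), 0.17, tolerance = 1e-4)
  # two carbons 10 A apart: stadium, area = pi r^2 + 2 r d = 43.08 A^2
  f2 <- write_mini_pdb(data.frame(elem = c("C", "C"), x = c(0, 10),
                                  y = 0, z = 7))
  r2 <- inplane_hull_radius(select_leaflet(load_oriented_structure(f2)))
  stadium <- pi * 1.7^2 + 2 * 1.7 * 10
  expect_equal(as.numeric(r2), sqrt(stadium / pi) / 10, tolerance = 1e-4)
  expect_equal(attr(r2, "area_nm2"), stadium / 100, tolerance = 1e-4)
})

test_that("hull radius is invariant under rotation and translation", {
  pts <- data.frame(elem = c("C", "N", "O", "S"),
                    x = c(0, 5, -3, 2), y = c(0, 1, 4, -6), z = 7)
  r0 <- inplane_hull_radius(select_leaflet(
    load_oriented_structure(write_mini_pdb(pts))))
  th <- 0.7
  rot <- pts
  rot$x <- cos(th) * pts$x - sin(th) * pts$y + 12
  rot$y <- sin(th) * pts$x + cos(th) * pts$y - 4
  r1 <- inplane_hull_radius(select_leaflet(
    load_oriented_structure(write_mini_pdb(rot))))
  expect_equal(as.numeric(r1), as.numeric(r0), tolerance = 1e-5)
})

test_that("adding atoms never shrinks the hull radius", {
  base <- data.frame(elem = "C", x = c(0, 4), y = c(0, 2), z = 7)
  r_base <- inplane_hull_radius(select_leaflet(
    load_oriented_structure(write_mini_pdb(base))))
  grown <- rbind(base, data.frame(elem = "C", x = 1, y = 8, z = 7))
  r_grown <- inplane_hull_radius(select_leaflet(
    load_oriented_structure(write_mini_pdb(grown))))
  expect_gte(as.numeric(r_grown), as.numeric(r_base))
  inside <- rbind(base, data.frame(elem = "H", x = 2, y = 1, z = 7))
  r_in <- inplane_hull_radius(select_leaflet(
    load_oriented_structure(write_mini_pdb(inside))))
  expect_equal(as.numeric(r_in), as.numeric(r_base), tolerance = 1e-9)
})

test_that("atoms on a circle give a radius between the ring and its buffer", {
  n <- 16; rho0 <- 6; vdw <- 1.7
  ring <- data.frame(elem = "C",
                     x = rho0 * cos(2 * pi * (1:n) / n),
                     y = rho0 * sin(2 * pi * (1:n) / n), z = 7)
  r <- inplane_hull_radius(select_leaflet(
    load_oriented_structure(write_mini_pdb(ring))))
  expect_lte(as.numeric(r), (rho0 + vdw) / 10)
  expect_gte(as.numeric(r), rho0 / 10)
})

test_that("hull area agrees with a rasterization oracle within 0.5%", {
  pts <- data.frame(elem = c("C", "N", "O", "S", "C"),
                    x = c(0, 6, -4, 3, -2), y = c(0, 2, 5, -5, -3), z = 7)
  at <- select_leaflet(load_oriented_structure(write_mini_pdb(pts)))
  area_geom <- attr(inplane_hull_radius(at), "area_nm2") * 100   # A^2
  # rasterize the union of discs, then take the pixel convex hull; the
  # half-pixel boundary bias at this resolution is ~0.3%
  res <- 0.02
  gx <- seq(min(at$x) - 3, max(at$x) + 3, by = res)
  gy <- seq(min(at$y) - 3, max(at$y) + 3, by = res)
  inside <- matrix(FALSE, length(gy), length(gx))
  for (i in seq_len(nrow(at)))
    inside <- inside | (outer((gy - at$y[i])^2, (gx - at$x[i])^2, "+") <=
                          at$vdw[i]^2)
  ij <- which(inside, arr.ind = TRUE)
  px <- gx[ij[, 2]]; py <- gy[ij[, 1]]
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h]
  area_ras <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  expect_equal(area_geom, area_ras, tolerance = 0.005)
})

test_that("centers-only mode drops the vdW buffering", {
  pts <- data.frame(elem = "C", x = c(0, 10, 0), y = c(0, 0, 10), z = 7)
  at <- select_leaflet(load_oriented_structure(write_mini_pdb(pts)))
  r_centers <- inplane_hull_radius(at, mode = "centers")
  expect_equal(as.numeric(r_centers), sqrt(50 / pi) / 10, tolerance = 1e-9)
  expect_gt(as.numeric(inplane_hull_radius(at)), as.numeric(r_centers))
})

test_that("lipid tracer radius follows the area-per-lipid closed form", {
  r <- lipid_tracer_radius(0.625, 0)
  expect_equal(unname(r["r_min"]), sqrt(0.625 / pi), tolerance = 1e-9)
  expect_equal(unname(r["r_min"]), 0.446, tolerance = 1e-3)
  expect_equal(unname(r["r_min"]), unname(r["r_max"]))
  expect_equal(unname(r["r_mid"]), unname(r["r_min"]))
  # default headgroup area reproduces the working tracer estimate
  d <- lipid_tracer_radius()
  expect_equal(unname(d["r_mid"]), 0.49, tolerance = 0.02)
  expect_equal(attr(d, "half_range"), 0.05, tolerance = 0.2)
})
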