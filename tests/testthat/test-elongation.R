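# Cell elongation tensor, regional means, peak alignment.

test_that("regular hexagons carry zero elongation", {
  for (cfg in list(c(1, 0, 0), c(3.7, 12, -4))) {
    hexa <- cell_polygon(regular_polygon(6, r = cfg[1],
                                         center = cfg[2:3], phase = 0.3))
    e <- elongation_tensor(hexa)
    expect_lt(abs(e$eps_xx), 1e-5)
    expect_lt(abs(e$eps_xy), 1e-5)
  }
})

test_that("polygonal ellipses match the closed form (a-b)/(a+b)", {
  e <- elongation_tensor(cell_polygon(ellipse_polygon(2, 1)))
  expect_equal(e$eps_xx, 1 / 3, tolerance = 1e-3)
  expect_lt(abs(e$eps_xy), 1e-6)
  # rotation by 45 degrees moves the signal into the off-diagonal component
  e45 <- elongation_tensor(cell_polygon(ellipse_polygon(2, 1, theta = pi / 4)))
  expect_lt(abs(e45$eps_xx), 1e-6)
  expect_equal(e45$eps_xy, 1 / 3, tolerance = 1e-3)
  expect_equal(e45$angle, pi / 4, tolerance = 1e-3)
})

test_that("the tensor rotates by the double angle", {
  set.seed(3)
  base <- ellipse_polygon(1.8, 1, n = 120)
  e0 <- elongation_tensor(cell_polygon(base))
  for (theta in c(0.3, 1.1, 2.0)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    e1 <- elongation_tensor(cell_polygon(base %*% t(R)))
    expect_equal(e1$eps_xx,
                 cos(2 * theta) * e0$eps_xx - sin(2 * theta) * e0$eps_xy,
                 tolerance = 1e-5)
    expect_equal(e1$eps_xy,
                 sin(2 * theta) * e0$eps_xx + cos(2 * theta) * e0$eps_xy,
                 tolerance = 1e-5)
  }
})

test_that("the tensor is invariant to translation and uniform scaling", {
  v <- ellipse_polygon(2, 1, n = 100)
  e0 <- elongation_tensor(cell_polygon(v))
  e1 <- elongation_tensor(cell_polygon(sweep(v * 3.7, 2, c(11, -5), `+`)))
  expect_equal(e1$eps_xx, e0$eps_xx, tolerance = 1e-9)
  expect_equal(e1$eps_xy, e0$eps_xy, tolerance = 1e-9)
})

test_that("quadrature agrees with Monte-Carlo integration on random polygons", {
  set.seed(11)
  for (rep in 1:6) {
    # random star-shaped polygon: jittered radii around a circle
    nv <- sample(5:9, 1)
    rr <- runif(nv, 0.5, 1.5)
    th <- sort(runif(nv, 0, 2 * pi))
    v <- cbind(rr * cos(th), rr * sin(th))
    e <- elongation_tensor(cell_polygon(v))
    mc <- mc_elongation(v, n_points = 2e5)
    expect_lt(abs(e$eps_xx - mc$eps_xx), 3 * mc$se_xx)
    expect_lt(abs(e$eps_xy - mc$eps_xy), 3 * mc$se_xy)
  }
})

test_that("degenerate polygons are rejected", {
  expect_error(cell_polygon(rbind(c(0, 0), c(1, 1))), ">= 3")
  expect_error(cell_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))), "zero area")
})

test_that("mean Q averages the PD component over a region", {
  hexes <- lapply(1:6, function(i)
    cell_polygon(regular_polygon(6, center = c(2 * i, 0)),
                 cell_id = i, region = "blade"))
  mesh <- cell_mesh(hexes)
  expect_lt(abs(mean_Q(mesh)), 1e-5)
  # affine shear: every cell acquires the same eps_xx = q
  q <- 0.05
  a <- exp(q); b <- exp(-q)
  sheared <- cell_mesh(lapply(hexes, function(c)
    cell_polygon(c$vertices %*% diag(c(a, b)), c$cell_id, c$region)))
  qs <- mean_Q(sheared)
  expect_equal(qs, mean_Q(sheared, weighted = TRUE), tolerance = 1e-10)
  expect_gt(qs, 0)
  # +q and -q cells cancel: a 90-degree rotation flips eps_xx exactly
  rot90 <- matrix(c(0, 1, -1, 0), 2, 2)
  mixed <- cell_mesh(c(
    lapply(hexes[1:3], function(c)
      cell_polygon(c$vertices %*% diag(c(a, b)), c$cell_id, c$region)),
    lapply(hexes[4:6], function(c)
      cell_polygon(c$vertices %*% diag(c(a, b)) %*% t(rot90),
                   c$cell_id, c$region))))
  expect_lt(abs(mean_Q(mixed)), 1e-5)
  expect_error(mean_Q(mesh, region = "hinge"), "no cells")
})

test_that("peak alignment recovers an exact parabola", {
  tt <- seq(15, 31, by = 5 / 60)
  vv <- 0.2 - 0.001 * (tt - 23)^2
  al <- align_to_peak(tt, vv)
  expect_equal(al$peak_time, 23, tolerance = 1e-8)
  expect_equal(al$times_rpce, tt - 23, tolerance = 1e-8)
})

test_that("peak alignment under noise meets the calibrated precision", {
  # parabola truth + sd 0.005 noise: median error < 0.25 h
  # (100-seed calibration observed median ~0.12 h)
  tt <- seq(15, 31, by = 5 / 60)
  mu <- 0.2 - 0.001 * (tt - 23)^2
  errs <- vapply(1:40, function(s) {
    set.seed(s)
    abs(align_to_peak(tt, mu + rnorm(length(tt), 0, 0.005))$peak_time - 23)
  }, numeric(1))
  expect_lt(median(errs), 0.25)
})

test_that("boundary maxima fall back with a flag", {
  tt <- seq(0.1, 10, by = 0.1)
  vv <- sqrt(tt)  # concave rise, maximum at the series end
  al <- align_to_peak(tt, vv, window = 20)
  expect_true("truncated_window" %in% al$flags)
  # the one-sided window pushes the vertex beyond the data: argmax fallback
  expect_true("vertex_outside_window" %in% al$flags)
  expect_equal(al$peak_time, 10)
})

test_that("upward-opening quadratic is an error", {
  tt <- seq(-5, 5, by = 0.1)
  expect_error(align_to_peak(tt, 0.1 * (tt)^2 - 1e-6 * tt, window = 10),
               "no maximum")
})

test_that("mesh and series JSON IO round trips", {
  mesh <- cell_mesh(lapply(1:3, function(i)
    cell_polygon(regular_polygon(6, center = c(2 * i, 0)), i, "blade")))
  path <- tempfile(fileext = ".json")
  write_cell_mesh(mesh, path)
  back <- read_cell_mesh(path)
  expect_length(back, 3)
  expect_equal(back[[2]]$vertices, mesh[[2]]$vertices, tolerance = 1e-12)
  expect_equal(back[[2]]$region, "blade")
  ser <- mesh_series(c(0, 1), list(mesh, mesh))
  spath <- file.path(tempdir(), "series_roundtrip.json")
  write_mesh_series(ser, spath)
  back2 <- read_mesh_series(spath)
  expect_equal(back2$times, c(0, 1))
  expect_length(back2$meshes[[2]], 3)
})

test_that("elongation tables carry one row per cell", {
  mesh <- cell_mesh(list(
    cell_polygon(regular_polygon(6), "a", "blade"),
    cell_polygon(ellipse_polygon(2, 1, n = 60), "b", "blade")))
  tab <- elongation_table(mesh)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$cell_id, c("a", "b"))
  expect_lt(abs(tab$eps_xx[1]), 1e-5)
  expect_equal(tab$eps_xx[2], 1 / 3, tolerance = 5e-3)
})
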