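plane_z0 <- list(point = c(0, 0, 0), normal = c(0, 0, 1))

test_that("hemisphere direct parameters match the analytic values", {
  hemi <- hemisphere_mesh(radius = 3, n_theta = 96, n_phi = 48)
  sphere <- uv_sphere_mesh(radius = 3, n_theta = 96, n_phi = 48)
  g <- direct_parameters(hemi, sphere, plane_z0)
  expect_equal(g$H, 3, tolerance = 0.01)
  expect_equal(g$H_max, 3, tolerance = 0.01)
  expect_equal(g$N_max, 6, tolerance = 0.01 * 6)
  expect_equal(g$N_area, 9 * pi, tolerance = 0.01 * 9 * pi)
  expect_equal(g$N_perimet, 6 * pi, tolerance = 0.01 * 6 * pi)
  expect_equal(g$V_sac, 2 / 3 * pi * 27, tolerance = 0.01 * 2 / 3 * pi * 27)
  expect_equal(g$L_max, 6, tolerance = 0.01 * 6)
  expect_gte(g$V_sacpar, g$V_sac)
  # isoperimetric inequality of the planar neck loop
  expect_gte(g$N_perimet^2, 4 * pi * g$N_area * (1 - 1e-6))
})

test_that("hemisphere ratio indices: BF = 1, CP = 1/2, UI = 0", {
  hemi <- hemisphere_mesh(radius = 3, n_theta = 96, n_phi = 48)
  sphere <- uv_sphere_mesh(radius = 3, n_theta = 96, n_phi = 48)
  g <- direct_parameters(hemi, sphere, plane_z0)
  idx <- ratio_indices(g, hemi, parent_diameter = 2.4)
  expect_equal(idx$BF, 1, tolerance = 0.01)
  expect_equal(idx$CP, 0.5, tolerance = 0.01)
  expect_lt(idx$UI, 0.02)
  expect_equal(idx$AR, g$H_max / g$N_max, tolerance = 1e-12)
  expect_equal(idx$SR, g$H_max / 2.4, tolerance = 1e-12)
})

test_that("sphere meshes score UI and NSI of zero", {
  sphere <- sphere_field_mesh(radius = 3, spacing = 0.12)
  hull <- convex_hull(sphere)
  ui <- 1 - mesh_volume(sphere) / hull$volume
  nsi <- 1 - (36 * pi)^(1 / 3) * mesh_volume(sphere)^(2 / 3) / mesh_area(sphere)
  expect_lt(abs(ui), 0.02)
  expect_lt(abs(nsi), 0.02)
  expect_equal(mesh_diameter(sphere), 6, tolerance = 0.02 * 6)
})

test_that("convex hull volume agrees with an independent oracle", {
  set.seed(7)
  pts <- matrix(rnorm(300 * 3), ncol = 3)
  hull <- convex_hull(pts)
  # cross-check against scipy's Qhull through the system python
  csv <- tempfile(fileext = ".csv")
  write.table(pts, csv, row.names = FALSE, col.names = FALSE, sep = ",")
  out <- tryCatch(
    system2("python", c("-c", shQuote(paste0(
      "import numpy as np; from scipy.spatial import ConvexHull; ",
      "p = np.loadtxt('", csv, "', delimiter=','); ",
      "h = ConvexHull(p); print(h.volume, h.area)"))),
      stdout = TRUE, stderr = FALSE),
    error = function(e) character(0), warning = function(w) character(0))
  unlink(csv)
  if (length(out) == 1) {
    ref <- as.numeric(strsplit(trimws(out), "\\s+")[[1]])
    expect_equal(hull$volume, ref[1], tolerance = 1e-8)
    expect_equal(hull$area, ref[2], tolerance = 1e-8)
  }
  # closed-form cross-check regardless of the python oracle: cube corners
  # plus interior points hull to the cube
  cube <- rbind(as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2))),
                matrix(runif(60, 0.2, 1.8), ncol = 3))
  h2 <- convex_hull(cube)
  expect_equal(h2$volume, 8, tolerance = 1e-9)
  expect_equal(h2$area, 24, tolerance = 1e-9)
})

test_that("indices are invariant to scaling, rotation and translation", {
  hemi <- hemisphere_mesh(radius = 3, n_theta = 64, n_phi = 32)
  sphere <- uv_sphere_mesh(radius = 3, n_theta = 64, n_phi = 32)
  base_g <- direct_parameters(hemi, sphere, plane_z0)
  base <- ratio_indices(base_g, hemi, parent_diameter = 2.4)

  s <- 2.5
  scale_mesh <- function(m) { m$vertices <- m$vertices * s; m }
  g2 <- direct_parameters(scale_mesh(hemi), scale_mesh(sphere), plane_z0)
  i2 <- ratio_indices(g2, scale_mesh(hemi), parent_diameter = 2.4 * s)
  for (f in c("AR", "SR", "UI", "NSI", "BF", "CP")) {
    expect_equal(i2[[f]], base[[f]], tolerance = 1e-6,
                 label = paste("scaled", f))
  }
  expect_equal(g2$V_sac, base_g$V_sac * s^3, tolerance = 1e-9)

  th <- 0.7; axis_rot <- rbind(c(cos(th), -sin(th), 0),
                               c(sin(th), cos(th), 0), c(0, 0, 1))
  tilt <- rbind(c(1, 0, 0), c(0, cos(0.4), -sin(0.4)), c(0, sin(0.4), cos(0.4)))
  R <- tilt %*% axis_rot
  shift <- c(5, -2, 1)
  move <- function(m) { m$vertices <- m$vertices %*% t(R) +
    matrix(shift, nrow(m$vertices), 3, byrow = TRUE); m }
  plane_m <- list(point = as.vector(R %*% c(0, 0, 0)) + shift,
                  normal = as.vector(R %*% c(0, 0, 1)))
  g3 <- direct_parameters(move(hemi), move(sphere), plane_m)
  i3 <- ratio_indices(g3, move(hemi), parent_diameter = 2.4)
  for (f in c("H", "H_max", "L_max", "V_sac", "S_sac", "N_max", "N_area")) {
    expect_equal(g3[[f]], base_g[[f]], tolerance = 1e-6,
                 label = paste("rotated", f))
  }
  for (f in c("AR", "SR", "UI", "NSI", "BF", "CP")) {
    expect_equal(i3[[f]], base[[f]], tolerance = 1e-6,
                 label = paste("rotated", f))
  }
})

test_that("carving a concavity strictly increases the undulation index", {
  base <- sphere_field_mesh(radius = 3, spacing = 0.15)
  hullv <- convex_hull(base)$volume
  ui0 <- 1 - mesh_volume(base) / hullv
  for (seed in 1:5) {
    set.seed(seed)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    dim_mesh <- base
    r <- sqrt(rowSums(dim_mesh$vertices^2))
    ang <- acos(pmin(1, pmax(-1, (dim_mesh$vertices %*% dir) / r)))
    push <- 0.8 * pmax(0, cos(ang * pi / 0.8 / 2))^2 * (ang < 0.4)
    dim_mesh$vertices <- dim_mesh$vertices * (1 - push / r)
    ui1 <- 1 - mesh_volume(dim_mesh) / convex_hull(dim_mesh)$volume
    expect_gt(ui1, ui0 + 0.001)
  }
})
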