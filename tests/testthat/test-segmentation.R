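test_that("threshold segmentation reproduces analytic masks and fails on empty", {
  dims <- c(12, 12, 12)
  uniform <- scalar_volume(array(100, dims), 0.5)
  expect_error(threshold_segment(uniform), "segmentation failure")

  ph <- generate_phantom(test_phantom_spec())
  hu <- scalar_volume(array(ifelse(ph$masks[[1]], 300, 0), dim(ph$masks[[1]])),
                      ph$spacing, ph$origin)
  seg <- threshold_segment(hu, 180)
  expect_identical(seg$data, ph$masks[[1]])

  # HU ramp along x crossing 180 between voxel columns
  nx <- 21
  ramp <- scalar_volume(array(rep(seq(100, 300, length.out = nx), 5 * 5),
                              c(nx, 5, 5)), 1)
  seg <- threshold_segment(ramp, 180)
  crossing <- min(which(seq(100, 300, length.out = nx) >= 180))
  expect_true(all(seg$data[crossing:nx, , ]))
  expect_false(any(seg$data[1:(crossing - 1), , ]))
})

test_that("box smoothing is mass-conserving with the documented impulse response", {
  ones <- binary_volume(array(TRUE, c(5, 5, 5)), 1)
  sm <- smooth_and_resample(ones, factor = 1)
  expect_true(all(abs(sm$data - 1) < 1e-12))

  imp <- array(FALSE, c(9, 9, 9)); imp[5, 5, 5] <- TRUE
  sm <- smooth_and_resample(binary_volume(imp, 1), factor = 1)
  expect_equal(sum(sm$data > 0), 27)
  expect_equal(sm$data[5, 5, 5], 1 / 27, tolerance = 1e-12)
  expect_equal(sum(sm$data), 1, tolerance = 1e-12)

  # sphere mask: occupancy mass conserved within 1% through smoothing and
  # 5x refinement
  ph <- generate_phantom(test_phantom_spec())
  mask <- phantom_phase(ph, 1)
  sm <- smooth_and_resample(mask, factor = 5)
  expect_equal(dim(sm$data), (dim(mask$data) - 1L) * 5L + 1L)
  expect_equal(sm$spacing, mask$spacing / 5)
  mass_in <- mask_volume(mask)
  mass_out <- sum(sm$data) * prod(sm$spacing)
  expect_lt(abs(mass_out - mass_in) / mass_in, 0.01)
  expect_true(all(sm$data >= -1e-12 & sm$data <= 1 + 1e-12))
})

test_that("centerline extraction labels tubes, junctions and the sac point", {
  tube <- capsule_mask(list(c(1, 0, 0), c(-1, 0, 0)), radius = 1,
                       extent = 6, spacing = 0.4)
  cl <- extract_centerline(tube)
  expect_length(cl$endpoints, 2)
  expect_length(cl$branch_points, 0)
  expect_length(cl$branches, 0)

  y <- capsule_mask(list(c(-1, 0, 0), c(0.766, 0.643, 0), c(0.766, -0.643, 0)),
                    radius = 0.8, extent = 6, spacing = 0.4)
  cly <- extract_centerline(y)
  expect_length(cly$branch_points, 1)
  expect_equal(unname(igraph::degree(cly$graph)[cly$branch_points]), 3)

  ph <- generate_phantom(test_phantom_spec())
  cls <- extract_centerline(phantom_phase(ph, 1))
  expect_gte(length(cls$branch_points), 1)
  sac_pt <- cls$points[cls$sac_point, ]
  expect_lt(sqrt(sum((sac_pt - c(0, 0, 4))^2)), 1.5)   # within r/2 of center
  expect_equal(cls$radius[cls$sac_point], 3, tolerance = 0.25)
  expect_length(cls$branches, 2)
  # partition property
  expect_setequal(c(cls$aneurysm_points, cls$branch_centerline_points),
                  seq_len(nrow(cls$points)))

  two <- array(FALSE, c(10, 10, 10))
  two[2:3, 2:3, 2:3] <- TRUE; two[7:8, 7:8, 7:8] <- TRUE
  expect_error(extract_centerline(binary_volume(two, 1)), "2 components")
})

test_that("neck plane lands on the analytic sphere-tube waist", {
  ph <- generate_phantom(test_phantom_spec())
  v1 <- phantom_phase(ph, 1)
  mesh <- extract_isosurface(smooth_and_resample(v1, factor = 3))
  cl <- extract_centerline(v1)
  pl <- identify_neck_plane(cl, mesh)

  # analytic intersection curve of sphere (r=3 at (0,0,4)) and tube
  # (radius 1.2 about the x axis): y = 1.2 cos(psi), z = 1.2 sin(psi),
  # x^2 = 9 - y^2 - (z - 4)^2 where non-negative
  psi <- seq(0, pi, length.out = 400)
  yy <- 1.2 * cos(psi); zz <- 1.2 * sin(psi)
  xx2 <- 9 - yy^2 - (zz - 4)^2
  keep <- xx2 >= 0
  waist <- rbind(cbind(sqrt(xx2[keep]), yy[keep], zz[keep]),
                 cbind(-sqrt(xx2[keep]), yy[keep], zz[keep]))
  dist_to_plane <- abs((waist - matrix(pl$point, nrow(waist), 3, byrow = TRUE))
                       %*% pl$normal)
  expect_lt(max(dist_to_plane), 0.5)
  # normal oriented toward the dome
  expect_gt(sum(pl$normal * (c(0, 0, 4) - pl$point)), 0)
})

test_that("neck plane construction is mirror-symmetric", {
  up <- test_phantom_spec()
  down <- test_phantom_spec(sac_center = c(0, 0, -4))
  plane_of <- function(spec) {
    v <- phantom_phase(generate_phantom(spec), 1)
    identify_neck_plane(extract_centerline(v),
                        extract_isosurface(smooth_and_resample(v, factor = 3)))
  }
  pu <- plane_of(up); pd <- plane_of(down)
  expect_equal(pu$point[3], -pd$point[3], tolerance = 0.3)
  expect_equal(abs(pu$normal[3]), abs(pd$normal[3]), tolerance = 0.05)
  expect_gt(pu$normal[3], 0)
  expect_lt(pd$normal[3], 0)
})

test_that("Y-junction phantom uses the three-point plane rule", {
  spec <- test_phantom_spec(branch_axes = list(c(-1, 0, 0),
                                               c(0.766, 0.643, 0),
                                               c(0.766, -0.643, 0)))
  v1 <- phantom_phase(generate_phantom(spec), 1)
  cl <- extract_centerline(v1)
  expect_length(cl$branches, 3)
  mesh <- extract_isosurface(smooth_and_resample(v1, factor = 3))
  pl <- identify_neck_plane(cl, mesh)
  expect_equal(nrow(pl$cut_points), 3)
  expect_gt(abs(pl$normal[3]), 0.95)        # near-horizontal neck plane
  expect_gt(pl$point[3], 0.7)               # at the junction waist height
  expect_lt(pl$point[3], 1.8)
})

test_that("cut_sac conserves volume and splits a sphere into hemispheres", {
  sphere <- sphere_field_mesh(radius = 3, spacing = 0.12)
  plane <- list(point = c(0, 0, 0.0131), normal = c(0, 0, 1))
  pieces <- cut_sac(sphere, plane)
  vol_half <- 2 / 3 * pi * 27
  expect_lt(abs(mesh_volume(pieces$sac) - vol_half) / vol_half, 0.012)
  expect_lt(abs(mesh_volume(pieces$parent) - vol_half) / vol_half, 0.012)
  total <- mesh_volume(pieces$sac) + mesh_volume(pieces$parent)
  expect_lt(abs(total - mesh_volume(sphere)) / mesh_volume(sphere), 0.005)

  expect_error(cut_sac(sphere, list(point = c(0, 0, 10), normal = c(0, 0, 1))),
               "does not intersect")
})

test_that("displacement fields obey the magnitude formula", {
  # vertex spacing well above twice the shift, so nearest-vertex matching
  # recovers the rigid correspondence exactly
  coarse <- uv_sphere_mesh(radius = 3, n_theta = 8, n_phi = 4)
  same <- compute_displacement(coarse, list(coarse))
  expect_true(all(same$d == 0))
  expect_true(all(same$amplitude == 0))

  shifted <- coarse
  shifted$vertices[, 1] <- shifted$vertices[, 1] + 0.3
  f <- compute_displacement(coarse, list(coarse, shifted))
  expect_equal(unname(f$d[, 1]), rep(0, nrow(coarse$vertices)))
  expect_equal(unname(f$d[, 2]), rep(0.3, nrow(coarse$vertices)),
               tolerance = 1e-9)
  expect_equal(unname(f$amplitude), rep(0.3, nrow(coarse$vertices)),
               tolerance = 1e-9)

  fine <- uv_sphere_mesh(radius = 3, n_theta = 120, n_phi = 60)
  inflated <- uv_sphere_mesh(radius = 3.2, n_theta = 120, n_phi = 60)
  g <- compute_displacement(fine, list(fine, inflated))
  expect_true(all(abs(g$d[, 2] - 0.2) < 0.02))
  expect_true(all(g$d >= 0))

  expect_error(compute_displacement(coarse, list(coarse, list())), "empty")
})
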