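# Analytic meshes and masks used as fixtures across the suite.

# UV (latitude/longitude) sphere mesh, outward-oriented.
uv_sphere_mesh <- function(radius = 1, center = c(0, 0, 0),
                           n_theta = 48, n_phi = 24) {
  phi <- seq(0, pi, length.out = n_phi + 1)[2:n_phi]        # exclude poles
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[1:n_theta]
  ring <- function(p) cbind(radius * sin(p) * cos(theta),
                            radius * sin(p) * sin(theta),
                            radius * cos(p))
  verts <- rbind(c(0, 0, radius), do.call(rbind, lapply(phi, ring)),
                 c(0, 0, -radius))
  verts <- sweep(verts, 2, center, "+")
  top <- 1L; bottom <- nrow(verts)
  idx <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- list()
  for (j in 1:n_theta) faces[[length(faces) + 1L]] <- c(top, idx(1, j), idx(1, j + 1))
  for (i in 1:(length(phi) - 1)) {
    for (j in 1:n_theta) {
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  for (j in 1:n_theta) {
    faces[[length(faces) + 1L]] <- c(bottom, idx(length(phi), j + 1), idx(length(phi), j))
  }
  m <- surface_mesh(verts, do.call(rbind, faces))
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# Closed hemisphere (z >= 0) of given radius: spherical rings down to the
# equator plus a fan cap across the equatorial disc.
hemisphere_mesh <- function(radius = 1, n_theta = 64, n_phi = 32) {
  phi <- seq(0, pi / 2, length.out = n_phi + 1)[-1]          # last ring at z = 0
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[1:n_theta]
  ring <- function(p) cbind(radius * sin(p) * cos(theta),
                            radius * sin(p) * sin(theta),
                            radius * cos(p))
  verts <- rbind(c(0, 0, radius), do.call(rbind, lapply(phi, ring)), c(0, 0, 0))
  top <- 1L; cap_center <- nrow(verts)
  idx <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- list()
  for (j in 1:n_theta) faces[[length(faces) + 1L]] <- c(top, idx(1, j), idx(1, j + 1))
  for (i in 1:(length(phi) - 1)) {
    for (j in 1:n_theta) {
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  last <- length(phi)
  for (j in 1:n_theta) {
    faces[[length(faces) + 1L]] <- c(cap_center, idx(last, j + 1), idx(last, j))
  }
  m <- surface_mesh(verts, do.call(rbind, faces))
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# Binary mask of a union of capsules (half-lines from the origin with a
# radius), on an isotropic grid covering [-extent, extent]^3.
capsule_mask <- function(axes, radius, extent, spacing) {
  g <- seq(-extent, extent, by = spacing)
  xs <- rep(g, times = length(g)^2)
  ys <- rep(rep(g, each = length(g)), times = length(g))
  zs <- rep(g, each = length(g)^2)
  inside <- rep(FALSE, length(xs))
  for (ax in axes) {
    ax <- ax / sqrt(sum(ax^2))
    t <- pmax(xs * ax[1] + ys * ax[2] + zs * ax[3], 0)
    d2 <- (xs - t * ax[1])^2 + (ys - t * ax[2])^2 + (zs - t * ax[3])^2
    inside <- inside | d2 <= radius^2
  }
  arr <- array(inside, rep(length(g), 3))
  binary_volume(arr, spacing, rep(-extent, 3))
}

# Smooth signed-distance sphere field -> near-exact isosurface mesh.
sphere_field_mesh <- function(radius = 3, spacing = 0.12, level = 0) {
  ext <- radius + 3 * spacing
  g <- seq(-ext, ext, by = spacing)
  xs <- rep(g, times = length(g)^2)
  ys <- rep(rep(g, each = length(g)), times = length(g))
  zs <- rep(g, each = length(g)^2)
  fld <- array(radius - sqrt(xs^2 + ys^2 + zs^2), rep(length(g), 3))
  extract_isosurface(scalar_volume(fld, spacing, rep(-ext, 3)), level = level)
}

# Analytic displacement field object (for SWP tests).
synthetic_field <- function(mesh, amplitude) {
  structure(list(reference_mesh = mesh,
                 d = matrix(amplitude, nrow(mesh$vertices), 2),
                 amplitude = amplitude),
            class = "displacement_field")
}

# Default sphere-on-tube phantom used in segmentation tests (coarse, fast).
test_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(sac_radius = 3, sac_center = c(0, 0, 4), parent_radius = 1.2,
         voxel_spacing = 0.4, n_phases = 5, seed = 42),
    list(...))
  do.call(phantom_spec, args)
}
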