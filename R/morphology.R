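#' Direct geometric parameters of an isolated aneurysm sac
#'
#' Computes, on the capped sac mesh and the sac-plus-parent mesh:
#' * `H` - perpendicular dome height: maximal signed distance of sac vertices
#'   above the neck plane (mm);
#' * `H_max` - maximal sac extent from the neck centroid (mm);
#' * `L_max` - maximal sac diameter in any direction (mm);
#' * `V_sac`, `V_sacpar`, `V_par` - divergence-theorem volumes (mm^3),
#'   `V_par = V_sacpar - V_sac`;
#' * `S_sac`, `S_sacpar` - surface areas (mm^2);
#' * `N_max`, `N_perimet`, `N_area` - maximal diameter, perimeter and area of
#'   the neck cross-section polygon (largest closed loop of the plane section
#'   of the sac-plus-parent mesh).
#'
#' @param sac closed sac [surface_mesh()] (from [cut_sac()]).
#' @param sacpar closed sac-plus-parent [surface_mesh()].
#' @param plane the [identify_neck_plane()] result (normal toward the dome).
#' @return an object of class `sac_geometry` with the parameters above plus
#'   `neck_centroid` and `plane`.
#' @export
direct_parameters <- function(sac, sacpar, plane) {
  stopifnot(inherits(sac, "surface_mesh"), inherits(sacpar, "surface_mesh"))
  v_sac <- mesh_volume(sac)
  v_sacpar <- mesh_volume(sacpar)
  if (v_sac <= 0 || v_sacpar <= 0) {
    stop("meshes must be closed and outward-oriented (non-positive volume found)")
  }
  sd_ <- as.vector((sac$vertices -
                    matrix(plane$point, nrow(sac$vertices), 3, byrow = TRUE)) %*%
                   plane$normal)
  H <- max(sd_)

  loops <- mesh_plane_section(sacpar, plane$point, plane$normal)
  if (length(loops) == 0) stop("neck plane does not intersect the sac+parent mesh")
  metrics <- lapply(loops, loop_metrics, normal = plane$normal)
  largest <- which.max(vapply(metrics, `[[`, 0, "area"))
  neck <- metrics[[largest]]
  neck_centroid <- colMeans(loops[[largest]])

  H_max <- max(sqrt(rowSums(sweep(sac$vertices, 2, neck_centroid)^2)))
  structure(list(H = H, H_max = H_max, L_max = mesh_diameter(sac),
                 V_sac = v_sac, V_sacpar = v_sacpar, V_par = v_sacpar - v_sac,
                 S_sac = mesh_area(sac), S_sacpar = mesh_area(sacpar),
                 N_max = neck$diameter, N_perimet = neck$perimeter,
                 N_area = neck$area,
                 neck_centroid = neck_centroid, plane = plane),
            class = "sac_geometry")
}

#' @export
print.sac_geometry <- function(x, ...) {
  flds <- c("H", "H_max", "L_max", "V_sac", "V_sacpar", "V_par",
            "S_sac", "S_sacpar", "N_max", "N_perimet", "N_area")
  vals <- vapply(flds, function(f) x[[f]], 0)
  cat("<sac_geometry>\n")
  print(signif(vals, 5))
  invisible(x)
}

#' Ratio-based morphology indices
#'
#' * `AR` (aspect ratio) `= H_max / N_max`;
#' * `SR` (size ratio) `= H_max / parent_diameter`;
#' * `UI` (undulation index) `= 1 - V_sac / V_convex_hull`; zero for convex
#'   sacs;
#' * `NSI` (non-sphericity index) `= 1 - c V^{2/3} / S` with
#'   `c = (36*pi)^{1/3}` so that a sphere scores zero (the isoperimetric
#'   constant is configurable);
#' * `BF` (bottleneck factor) `= W_max / N_max`, `W_max` the maximal sac
#'   width parallel to the neck plane;
#' * `CP` (conicity parameter) `= 1/2 - h*/H`, `h*` the height above the
#'   neck plane of the maximal parallel cross-section; 1/2 when the sac is
#'   widest at the neck, negative when widest above mid-height.
#'
#' All six indices are dimensionless and invariant to rigid motion and
#' uniform scaling.
#'
#' @param geometry a [direct_parameters()] result.
#' @param sac the closed sac [surface_mesh()].
#' @param parent_diameter parent vessel diameter (mm); see
#'   [estimate_parent_diameter()] for a centerline-based measurement.
#' @param nsi_constant isoperimetric constant of the NSI.
#' @param n_slices number of parallel cross-sections used for `W_max`/`h*`.
#' @return an object of class `morphology_indices` with fields `AR`, `SR`,
#'   `UI`, `NSI`, `BF`, `CP` plus `W_max` and `h_star`.
#' @export
ratio_indices <- function(geometry, sac, parent_diameter,
                          nsi_constant = (36 * pi)^(1 / 3), n_slices = 41) {
  stopifnot(inherits(geometry, "sac_geometry"), parent_diameter > 0,
            geometry$N_max > 0)
  hull <- convex_hull(sac)
  if (hull$volume <= 0) stop("degenerate convex hull")
  UI <- 1 - geometry$V_sac / hull$volume
  NSI <- 1 - nsi_constant * geometry$V_sac^(2 / 3) / geometry$S_sac

  plane <- geometry$plane
  heights <- seq(1e-3, 1 - 1e-3, length.out = n_slices) * geometry$H
  W <- rep(NA_real_, n_slices)
  for (i in seq_len(n_slices)) {
    pt <- plane$point + heights[i] * plane$normal
    loops <- mesh_plane_section(sac, pt, plane$normal)
    if (length(loops) == 0) next
    pts <- do.call(rbind, loops)
    W[i] <- loop_metrics(pts, plane$normal)$diameter
  }
  if (all(is.na(W))) stop("no parallel cross-section intersects the sac")
  W_max <- max(W, na.rm = TRUE)
  h_star <- heights[which.max(W)]
  structure(list(AR = geometry$H_max / geometry$N_max,
                 SR = geometry$H_max / parent_diameter,
                 UI = UI, NSI = NSI,
                 BF = W_max / geometry$N_max,
                 CP = 0.5 - h_star / geometry$H,
                 W_max = W_max, h_star = h_star),
            class = "morphology_indices")
}

#' @export
print.morphology_indices <- function(x, ...) {
  vals <- vapply(c("AR", "SR", "UI", "NSI", "BF", "CP"), function(f) x[[f]], 0)
  cat("<morphology_indices>\n")
  print(signif(vals, 4))
  invisible(x)
}

#' Parent vessel diameter from the centerline
#'
#' Twice the mean inscribed-sphere radius of branch centerline points within
#' `3 * N_max` of the neck point.
#'
#' @param graph a [extract_centerline()] result.
#' @param n_max maximal neck diameter (mm).
#' @return diameter in mm.
#' @export
estimate_parent_diameter <- function(graph, n_max) {
  stopifnot(inherits(graph, "centerline_graph"))
  ids <- graph$branch_centerline_points
  if (length(ids) == 0) stop("no branch centerline points")
  neck <- graph$points[graph$neck_branch_point, ]
  d <- sqrt(rowSums(sweep(graph$points[ids, , drop = FALSE], 2, neck)^2))
  sel <- ids[d <= 3 * n_max]
  if (length(sel) == 0) sel <- ids[order(d)[seq_len(min(5, length(ids)))]]
  2 * mean(graph$radius[sel])
}

#' One-row summary of morphology for CSV export
#'
#' @param geometry a [direct_parameters()] result.
#' @param indices a [ratio_indices()] result.
#' @param examination_id identifier.
#' @return one-row `data.frame` with the 10 direct parameters and 6 indices.
#' @export
morphology_row <- function(geometry, indices, examination_id = "exam") {
  data.frame(examination_id = examination_id,
             H = geometry$H, H_max = geometry$H_max, L_max = geometry$L_max,
             V_sac = geometry$V_sac, V_sacpar = geometry$V_sacpar,
             S_sac = geometry$S_sac, S_sacpar = geometry$S_sacpar,
             N_max = geometry$N_max, N_perimet = geometry$N_perimet,
             N_area = geometry$N_area,
             AR = indices$AR, SR = indices$SR, UI = indices$UI,
             NSI = indices$NSI, BF = indices$BF, CP = indices$CP)
}
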