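#' Automatic neck-plane construction
#'
#' For each parent-vessel branch, the branch centerline points are projected
#' onto the vessel surface along the direction toward the aneurysm sac point;
#' among the resulting surface points, the one closest to the neck-adjacent
#' branch point is that branch's cut point. With more than two branches the
#' plane is fitted through the three cut points closest to the neck point;
#' with two branches the plane passes through both cut points and its normal
#' is the perpendicular component, relative to the cut-point line, of the
#' vector to the highest surface point of the dome (so the plane contains the
#' cut-point line and faces the dome). The normal is oriented toward the sac.
#'
#' @param graph a [extract_centerline()] result.
#' @param surface the sac-plus-parent [surface_mesh()].
#' @return an object of class `neck_plane`: `point` (mm), `normal` (unit,
#'   toward the dome), `cut_points` (one row per branch used).
#' @export
identify_neck_plane <- function(graph, surface) {
  stopifnot(inherits(graph, "centerline_graph"), inherits(surface, "surface_mesh"))
  if (length(graph$branches) < 1 || is.na(graph$neck_branch_point)) {
    stop("no parent-vessel branch adjacent to the aneurysm sac")
  }
  sac <- graph$points[graph$sac_point, ]
  neck_pt <- graph$points[graph$neck_branch_point, ]

  cut_points <- NULL
  for (members in graph$branches) {
    orig <- graph$points[members, , drop = FALSE]
    dirs <- matrix(sac, nrow(orig), 3, byrow = TRUE) - orig
    len <- sqrt(rowSums(dirs^2))
    ok <- len > 1e-9
    orig <- orig[ok, , drop = FALSE]
    dirs <- dirs[ok, , drop = FALSE] / len[ok]
    if (nrow(orig) == 0) next
    hits <- .ray_mesh_hits(orig, dirs, surface$vertices, surface$faces)
    hp <- hits$hit[!is.na(hits$t), , drop = FALSE]
    if (nrow(hp) == 0) next
    dist_to_neck <- sqrt(rowSums(sweep(hp, 2, neck_pt)^2))
    cut_points <- rbind(cut_points, hp[which.min(dist_to_neck), ])
  }
  if (is.null(cut_points) || nrow(cut_points) < 2) {
    stop("fewer than two branch cut points could be constructed")
  }

  if (nrow(cut_points) > 2) {
    d_neck <- sqrt(rowSums(sweep(cut_points, 2, neck_pt)^2))
    three <- cut_points[order(d_neck)[1:3], ]
    e1 <- three[2, ] - three[1, ]
    e2 <- three[3, ] - three[1, ]
    normal <- c(e1[2] * e2[3] - e1[3] * e2[2],
                e1[3] * e2[1] - e1[1] * e2[3],
                e1[1] * e2[2] - e1[2] * e2[1])
    if (sqrt(sum(normal^2)) < 1e-9) stop("degenerate (collinear) cut points")
    normal <- normalize(normal)
    point <- colMeans(three)
    cut_points <- three
  } else {
    c1 <- cut_points[1, ]; c2 <- cut_points[2, ]
    axis <- c2 - c1
    if (sqrt(sum(axis^2)) < 1e-9) stop("degenerate coincident cut points")
    axis <- normalize(axis)
    # highest surface point: maximal extent along the provisional dome
    # direction (sac point minus neck point)
    dome_dir <- normalize(sac - neck_pt)
    h_idx <- which.max(as.vector(surface$vertices %*% dome_dir))
    h <- surface$vertices[h_idx, ]
    w <- (h - c1) - sum((h - c1) * axis) * axis
    if (sqrt(sum(w^2)) < 1e-9) stop("highest point is collinear with the cut points")
    normal <- normalize(w)
    point <- (c1 + c2) / 2
  }
  if (sum(normal * (sac - point)) < 0) normal <- -normal
  structure(list(point = point, normal = normal, cut_points = cut_points),
            class = "neck_plane")
}

#' @export
print.neck_plane <- function(x, ...) {
  cat("<neck_plane> point (", paste(signif(x$point, 4), collapse = ", "),
      ") mm, normal (", paste(signif(x$normal, 3), collapse = ", "),
      "), ", nrow(x$cut_points), " cut points\n", sep = "")
  invisible(x)
}

#' Separate the aneurysm sac from the parent arteries
#'
#' Cuts the closed sac-plus-parent mesh at the neck plane. The sac is the
#' capped piece on the dome side of the plane; the remainder (parent
#' arteries, also capped) is returned alongside so that volume conservation
#' can be checked: sac volume + remainder volume = original volume up to the
#' shared cap.
#'
#' @param surface closed sac-plus-parent [surface_mesh()].
#' @param plane a [identify_neck_plane()] result (or a list with `point` and
#'   `normal`, normal toward the dome).
#' @return list with `sac` ([surface_mesh()], closed), `parent`
#'   ([surface_mesh()], closed) and `plane`.
#' @export
cut_sac <- function(surface, plane) {
  stopifnot(inherits(surface, "surface_mesh"))
  sd_ <- as.vector((surface$vertices -
                    matrix(plane$point, nrow(surface$vertices), 3, byrow = TRUE)) %*%
                   plane$normal)
  if (all(sd_ <= 0) || all(sd_ >= 0)) {
    stop("neck plane does not intersect the surface")
  }
  sac <- clip_mesh_plane(surface, plane$point, plane$normal, "positive")
  parent <- clip_mesh_plane(surface, plane$point, plane$normal, "negative")
  if (mesh_volume(sac) <= 0) stop("degenerate cut: sac has no volume")
  list(sac = sac, parent = parent, plane = plane)
}
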