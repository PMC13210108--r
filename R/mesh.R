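#' Triangle surface meshes
#'
#' A `surface_mesh` stores vertex coordinates in mm (world frame) and
#' 1-based triangle vertex indices. Meshes produced by
#' [extract_isosurface()] on fields whose super-level set is strictly inside
#' the grid are closed and consistently outward-oriented, which is what the
#' divergence-theorem volume in [mesh_volume()] assumes.
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param faces integer m x 3 matrix of vertex indices (1-based).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  storage.mode(faces) <- "integer"
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " triangles\n", sep = "")
  invisible(x)
}

#' Isosurface extraction from a scalar volume
#'
#' Marching-tetrahedra isosurface at `level` (0.5 by default: the midpoint of
#' a binary field after linear smoothing). Vertices are returned in world
#' coordinates (mm).
#'
#' @param vol a [scalar_volume()] (e.g. from [smooth_and_resample()]).
#' @param level iso level.
#' @return a [surface_mesh()].
#' @export
extract_isosurface <- function(vol, level = 0.5) {
  stopifnot(inherits(vol, "scalar_volume"))
  res <- .march_tetra(as.numeric(vol$data), dim(vol$data), level,
                      vol$spacing, vol$origin)
  if (nrow(res$vertices) == 0) stop("isosurface is empty at level ", level)
  surface_mesh(res$vertices, res$faces)
}

#' Mesh volume, area and centroid
#'
#' `mesh_volume()` integrates the divergence theorem over a closed, outward
#' oriented triangle mesh; `mesh_area()` sums triangle areas.
#'
#' @param mesh a [surface_mesh()].
#' @return volume in mm^3 / area in mm^2.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Convex hull of a point set or mesh
#'
#' Incremental 3D convex hull. Returns the hull as a mesh together with its
#' volume and area; used by the undulation index and for mesh diameters.
#'
#' For dense isosurface meshes (where almost every vertex lies on the hull,
#' making the incremental construction quadratic) the input is deterministically
#' strided down to at most `max_points` vertices, always retaining the extreme
#' vertices along 13 probe directions; the hull volume deficit of the stride is
#' far below mesh discretisation error at the default setting.
#'
#' @param x a [surface_mesh()] or an n x 3 coordinate matrix.
#' @param max_points stride the input down to this many points (`Inf` for the
#'   exact hull of all points).
#' @return list with `mesh` ([surface_mesh()]), `volume` (mm^3), `area` (mm^2).
#' @export
convex_hull <- function(x, max_points = 6000) {
  pts <- if (inherits(x, "surface_mesh")) x$vertices else as.matrix(x)
  if (nrow(pts) > max_points) {
    probes <- rbind(diag(3), -diag(3),
                    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1),
                    c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    extremes <- apply(pts %*% t(probes), 2, which.max)
    stride <- unique(c(seq(1, nrow(pts),
                           length.out = max_points - length(extremes)),
                       extremes))
    pts <- pts[sort(unique(as.integer(stride))), , drop = FALSE]
  }
  res <- .convex_hull3(pts)
  list(mesh = surface_mesh(pts, res$faces), volume = res$volume, area = res$area)
}

#' Mesh diameter (maximal vertex-to-vertex distance)
#'
#' Computed over convex-hull vertices, which carry the diameter of the full
#' vertex set.
#'
#' @param mesh a [surface_mesh()].
#' @return diameter in mm.
#' @export
mesh_diameter <- function(mesh) {
  hull <- convex_hull(mesh)
  ids <- sort(unique(as.vector(hull$mesh$faces)))
  pts <- hull$mesh$vertices[ids, , drop = FALSE]
  max(stats::dist(pts))
}

#' Planar cross-sections of a mesh
#'
#' Intersects the mesh with the plane `normal . (x - point) = 0` and chains
#' the per-triangle intersection segments into closed loops.
#'
#' @param mesh a [surface_mesh()].
#' @param point,normal plane definition (mm / unit vector).
#' @return list of loops; each loop is a k x 3 matrix of ordered points. Empty
#'   list when the plane misses the mesh.
#' @export
mesh_plane_section <- function(mesh, point, normal) {
  normal <- normal / sqrt(sum(normal^2))
  scale <- max(1, max(abs(mesh$vertices)))
  sd_ <- as.vector((mesh$vertices - matrix(point, nrow(mesh$vertices), 3,
                                           byrow = TRUE)) %*% normal)
  sd_[abs(sd_) < 1e-9 * scale] <- 0   # snap on-plane vertices
  f <- mesh$faces
  s1 <- sd_[f[, 1]]; s2 <- sd_[f[, 2]]; s3 <- sd_[f[, 3]]
  smin <- pmin(s1, s2, s3); smax <- pmax(s1, s2, s3)
  has_zero <- s1 == 0 | s2 == 0 | s3 == 0
  crossing <- which((smin < 0 & smax > 0) | (has_zero & smax > 0))
  if (length(crossing) == 0) return(list())

  edge_pt <- function(i, j) {
    t <- sd_[i] / (sd_[i] - sd_[j])
    mesh$vertices[i, ] + t * (mesh$vertices[j, ] - mesh$vertices[i, ])
  }
  pts_a <- matrix(0, length(crossing), 3)
  pts_b <- matrix(0, length(crossing), 3)
  keep <- logical(length(crossing))
  for (r in seq_along(crossing)) {
    tr <- f[crossing[r], ]
    d <- sd_[tr]
    pos <- tr[d > 0]; neg <- tr[d < 0]; zer <- tr[d == 0]
    ip <- NULL
    if (length(pos) == 1 && length(neg) == 2) {
      ip <- rbind(edge_pt(pos, neg[1]), edge_pt(pos, neg[2]))
    } else if (length(pos) == 2 && length(neg) == 1) {
      ip <- rbind(edge_pt(pos[1], neg), edge_pt(pos[2], neg))
    } else if (length(zer) == 1 && length(pos) == 1 && length(neg) == 1) {
      ip <- rbind(mesh$vertices[zer, ], edge_pt(pos, neg))
    } else if (length(zer) == 2 && length(pos) == 1) {
      # an entire edge lies in the plane; emit it from the positive side only
      ip <- mesh$vertices[zer, ]
    }
    if (!is.null(ip)) {
      pts_a[r, ] <- ip[1, ]; pts_b[r, ] <- ip[2, ]; keep[r] <- TRUE
    }
  }
  # drop degenerate (point-like) segments
  keep[keep] <- sqrt(rowSums((pts_a[keep, , drop = FALSE] -
                              pts_b[keep, , drop = FALSE])^2)) > 1e-8 * scale
  pts_a <- pts_a[keep, , drop = FALSE]
  pts_b <- pts_b[keep, , drop = FALSE]
  if (nrow(pts_a) == 0) return(list())

  # chain segments into loops by snapping endpoints to a tolerance grid
  tol <- 1e-6 * max(1, max(abs(mesh$vertices)))
  key <- function(p) paste(round(p / tol), collapse = "_")
  ka <- apply(pts_a, 1, key); kb <- apply(pts_b, 1, key)
  used <- logical(nrow(pts_a))
  adj <- split(seq_len(nrow(pts_a) * 2),
               c(ka, kb))  # segment occurrences indexed by endpoint key
  loops <- list()
  for (start in seq_len(nrow(pts_a))) {
    if (used[start]) next
    loop <- list(pts_a[start, ])
    cur_key <- kb[start]; cur_pt <- pts_b[start, ]
    used[start] <- TRUE
    repeat {
      loop[[length(loop) + 1L]] <- cur_pt
      occ <- adj[[cur_key]]
      nxt <- NULL
      for (o in occ) {
        seg <- if (o > nrow(pts_a)) o - nrow(pts_a) else o
        if (!used[seg]) { nxt <- o; break }
      }
      if (is.null(nxt)) break
      seg <- if (nxt > nrow(pts_a)) nxt - nrow(pts_a) else nxt
      used[seg] <- TRUE
      if (nxt > nrow(pts_a)) { cur_key <- ka[seg]; cur_pt <- pts_a[seg, ] }
      else { cur_key <- kb[seg]; cur_pt <- pts_b[seg, ] }
    }
    m <- do.call(rbind, loop)
    # drop duplicated closing point
    if (nrow(m) > 1 && sqrt(sum((m[1, ] - m[nrow(m), ])^2)) < 10 * tol) {
      m <- m[-nrow(m), , drop = FALSE]
    }
    if (nrow(m) >= 3) loops[[length(loops) + 1L]] <- m
  }
  loops
}

#' Area, perimeter and diameter of a planar loop
#' @noRd
loop_metrics <- function(loop, normal) {
  normal <- normal / sqrt(sum(normal^2))
  # in-plane basis
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * normal) * normal; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  u <- loop %*% e1; v <- loop %*% e2
  nu <- c(u[-1], u[1]); nv <- c(v[-1], v[1])
  area <- abs(sum(u * nv - nu * v)) / 2
  closed <- rbind(loop, loop[1, ])
  perim <- sum(sqrt(rowSums(diff(closed)^2)))
  diam <- if (nrow(loop) > 1) max(stats::dist(cbind(u, v))) else 0
  list(area = area, perimeter = perim, diameter = diam)
}

#' Cut a closed mesh with a plane and cap the cut
#'
#' Splits a closed mesh at the plane, keeps the requested side, and closes the
#' cut with a triangle fan per boundary loop (fanned around the loop centroid,
#' oriented so the cap normal points out of the kept half). Crossing triangles
#' are clipped exactly at the plane.
#'
#' @param mesh a closed [surface_mesh()].
#' @param point,normal plane (mm / unit vector); the kept side is
#'   `normal . (x - point) > 0` when `side = "positive"`.
#' @param side `"positive"` or `"negative"`.
#' @return a closed [surface_mesh()].
#' @export
clip_mesh_plane <- function(mesh, point, normal, side = c("positive", "negative")) {
  side <- match.arg(side)
  normal <- normal / sqrt(sum(normal^2))
  if (side == "negative") normal <- -normal
  v <- mesh$vertices
  sd_ <- as.vector((v - matrix(point, nrow(v), 3, byrow = TRUE)) %*% normal)
  scale <- max(1, max(abs(v)))
  sd_[abs(sd_) < 1e-9 * scale] <- 0

  keep_tris <- list(); cut_edges_a <- list(); cut_edges_b <- list()
  new_v <- list(); edge_cache <- new.env(hash = TRUE, parent = emptyenv())
  nv0 <- nrow(v)
  edge_vertex <- function(i, j) {
    k <- paste(min(i, j), max(i, j), sep = "_")
    got <- edge_cache[[k]]
    if (!is.null(got)) return(got)
    t <- sd_[i] / (sd_[i] - sd_[j])
    new_v[[length(new_v) + 1L]] <<- v[i, ] + t * (v[j, ] - v[i, ])
    id <- nv0 + length(new_v)
    edge_cache[[k]] <- id
    id
  }

  fm <- mesh$faces
  s1 <- sd_[fm[, 1]]; s2 <- sd_[fm[, 2]]; s3 <- sd_[fm[, 3]]
  smin <- pmin(s1, s2, s3); smax <- pmax(s1, s2, s3)
  keep_whole <- smin >= 0 & smax > 0
  keep_tris[[1L]] <- fm[keep_whole, , drop = FALSE]
  for (r in which(!(keep_whole | smax <= 0))) {
    tr <- fm[r, ]
    d <- sd_[tr]
    # rotate so the single odd vertex is first
    pos <- d > 0
    if (sum(pos) == 1) {
      o <- which(pos)
      tr <- tr[c(o, o %% 3 + 1, (o + 1) %% 3 + 1)]
      a <- edge_vertex(tr[1], tr[2]); b <- edge_vertex(tr[1], tr[3])
      keep_tris[[length(keep_tris) + 1L]] <- c(tr[1], a, b)
      cut_edges_a[[length(cut_edges_a) + 1L]] <- a
      cut_edges_b[[length(cut_edges_b) + 1L]] <- b
    } else if (sum(pos) == 2) {
      o <- which(!pos)
      tr <- tr[c(o, o %% 3 + 1, (o + 1) %% 3 + 1)]
      a <- edge_vertex(tr[1], tr[2]); b <- edge_vertex(tr[1], tr[3])
      keep_tris[[length(keep_tris) + 1L]] <- c(a, tr[2], tr[3])
      keep_tris[[length(keep_tris) + 1L]] <- c(a, tr[3], b)
      cut_edges_a[[length(cut_edges_a) + 1L]] <- b
      cut_edges_b[[length(cut_edges_b) + 1L]] <- a
    } else {  # one vertex exactly on the plane, others split
      zi <- which(d == 0); pi_ <- which(d > 0); ni <- which(d < 0)
      if (length(pi_) == 1 && length(ni) == 1) {
        m <- edge_vertex(tr[pi_], tr[ni])
        # keep triangle (zero vtx, pos vtx, m) with original winding
        ord <- c(tr[zi], tr[pi_], m)
        if ((pi_ %% 3 + 1) == zi) ord <- c(tr[pi_], tr[zi], m)
        keep_tris[[length(keep_tris) + 1L]] <- ord
        cut_edges_a[[length(cut_edges_a) + 1L]] <- tr[zi]
        cut_edges_b[[length(cut_edges_b) + 1L]] <- m
      } else if (length(pi_) == 2) {
        keep_tris[[length(keep_tris) + 1L]] <- tr
      }
    }
  }
  verts <- rbind(v, do.call(rbind, new_v))
  faces <- do.call(rbind, keep_tris)
  if (is.null(faces) || nrow(faces) == 0) {
    stop("plane does not leave any surface on the kept side")
  }

  # cap: chain boundary edges into loops, fan each around its centroid
  if (length(cut_edges_a) > 0) {
    ea <- unlist(cut_edges_a); eb <- unlist(cut_edges_b)
    # merge coincident boundary vertices (clipping may duplicate positions)
    all_ids <- unique(c(ea, eb))
    tolc <- 1e-7 * max(1, max(abs(verts)))
    ckey <- apply(round(verts[all_ids, , drop = FALSE] / tolc), 1,
                  paste, collapse = "_")
    canon <- all_ids[match(ckey, ckey)]
    names(canon) <- as.character(all_ids)
    ea <- canon[as.character(ea)]; eb <- canon[as.character(eb)]
    valid <- ea != eb
    ea <- ea[valid]; eb <- eb[valid]
    used <- logical(length(ea))
    nxt <- split(seq_along(ea), ea)
    while (any(!used)) {
      s <- which(!used)[1]
      loop <- c(ea[s], eb[s]); used[s] <- TRUE
      repeat {
        cand <- nxt[[as.character(loop[length(loop)])]]
        cand <- cand[!used[cand]]
        if (length(cand) == 0) break
        used[cand[1]] <- TRUE
        nx <- eb[cand[1]]
        if (nx == loop[1]) break
        loop <- c(loop, nx)
      }
      if (length(loop) >= 3) {
        ctr <- colMeans(verts[loop, , drop = FALSE])
        verts <- rbind(verts, ctr)
        cid <- nrow(verts)
        ring <- cbind(loop, c(loop[-1], loop[1]), cid)
        # orient cap triangles so their normals point along -normal (outward
        # of the kept positive half)
        u <- verts[ring[1, 2], ] - verts[ring[1, 1], ]
        w <- verts[cid, ] - verts[ring[1, 1], ]
        cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
                u[1] * w[2] - u[2] * w[1])
        if (sum(cr * normal) > 0) ring <- ring[, c(2, 1, 3)]
        faces <- rbind(faces, ring)
      }
    }
  }

  # drop unused vertices
  ids <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(verts)); remap[ids] <- seq_along(ids)
  surface_mesh(verts[ids, , drop = FALSE],
               matrix(remap[faces], ncol = 3))
}

#' Write a mesh as ASCII PLY with an optional per-vertex scalar
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param scalar optional per-vertex numeric (e.g. displacement amplitude in
#'   mm), stored as property `quality`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, scalar = NULL) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  has_s <- !is.null(scalar)
  if (has_s) stopifnot(length(scalar) == nv)
  header <- c("ply", "format ascii 1.0", "comment wallpulse displacement export",
              paste("element vertex", nv),
              "property float x", "property float y", "property float z",
              if (has_s) "property float quality",
              paste("element face", nf),
              "property list uchar int vertex_indices", "end_header")
  vl <- if (has_s) cbind(mesh$vertices, scalar) else mesh$vertices
  vtxt <- apply(format(vl, trim = TRUE, digits = 7), 1, paste, collapse = " ")
  ftxt <- paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1, mesh$faces[, 3] - 1)
  writeLines(c(header, vtxt, ftxt), path)
  invisible(path)
}

#' Unit-vector helper
#' @noRd
normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}
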