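#' Centerline and key-point extraction
#'
#' Skeletonises a connected binary vessel mask by topology-preserving 3D
#' thinning, builds the skeleton graph (26-connectivity, reduced to a minimum
#' spanning tree so that node degrees are meaningful), and labels key points:
#' endpoints (degree 1), branch points (degree >= 3), and the aneurysm sac
#' point, defined as the skeleton point whose inscribed sphere inside the
#' foreground is largest. Skeleton points are split into aneurysm points (the
#' component containing the sac point once the neck-adjacent branch point is
#' removed) and branch centerline points (everything else), which is the
#' partition the neck-plane construction consumes.
#'
#' @param volume a [binary_volume()] with connected foreground.
#' @return an object of class `centerline_graph` with elements `points`
#'   (n x 3, mm), `edges` (m x 2 indices), `radius` (inscribed-sphere radius
#'   per point, mm), `endpoints`, `branch_points`, `sac_point` (index),
#'   `aneurysm_points`, `branch_centerline_points`, `neck_branch_point`
#'   (index of the branch point adjacent to the sac), and `branches` (list of
#'   index vectors, one per parent-vessel branch).
#' @export
extract_centerline <- function(volume) {
  stopifnot(inherits(volume, "binary_volume"))
  mask <- volume$data
  comp <- .connected_components26(mask)
  if (comp$n != 1) {
    stop("foreground is not connected: ", comp$n, " components found")
  }

  # pad so the thinning kernel never touches the border
  d <- dim(mask)
  padded <- array(FALSE, d + 2)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  skel <- .thin3d(padded, dim(padded))[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  dim(skel) <- d

  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("skeleton collapsed to fewer than 2 points")
  pts <- sweep(sweep(idx - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")

  # inscribed-sphere radius: distance to the nearest background boundary voxel
  bg_shell <- .boundary_voxels(mask)
  shell_pts <- sweep(sweep(bg_shell - 1, 2, volume$spacing, "*"), 2,
                     volume$origin, "+")
  nn <- .nn_match(pts, shell_pts, max(volume$spacing) * 2)
  radius <- sqrt(rowSums((pts - shell_pts[nn, , drop = FALSE])^2))

  # 26-adjacency graph on skeleton voxels -> MST for clean degrees
  key <- idx[, 1] + (idx[, 2] - 1) * d[1] + (idx[, 3] - 1) * d[1] * d[2]
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(key)) assign(as.character(key[i]), i, envir = lookup)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- NULL
  ww <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nbkey <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
    for (i in which(ok)) {
      j <- lookup[[as.character(nbkey[i])]]
      if (!is.null(j) && j > i) {
        edges <- rbind(edges, c(i, j))
        ww <- c(ww, sqrt(sum(((idx[i, ] - idx[j, ]) * volume$spacing)^2)))
      }
    }
  }
  if (is.null(edges)) stop("skeleton graph has no edges")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- ww
  if (igraph::vcount(g) < nrow(pts)) {
    g <- igraph::add_vertices(g, nrow(pts) - igraph::vcount(g))
  }
  g <- igraph::mst(g)
  igraph::V(g)$name <- as.character(seq_len(nrow(pts)))

  # prune short twigs: boundary-noise spurs produced by thinning
  prune_mm <- 4 * max(volume$spacing)
  for (pass in 1:3) {
    deg <- igraph::degree(g)
    if (!any(deg >= 3)) break
    drop <- character(0)
    for (e in igraph::V(g)$name[deg == 1]) {
      path <- e
      len <- 0
      cur <- e
      prev <- NA_character_
      repeat {
        nbs <- setdiff(names(igraph::neighbors(g, cur)), prev)
        if (length(nbs) != 1) { path <- NULL; break }   # isolated or endpoint
        nxt <- nbs[1]
        len <- len + sqrt(sum((pts[as.integer(cur), ] - pts[as.integer(nxt), ])^2))
        if (len >= prune_mm) { path <- NULL; break }
        if (igraph::degree(g, nxt) >= 3) break          # reached a junction
        prev <- cur; cur <- nxt; path <- c(path, nxt)
      }
      if (!is.null(path)) drop <- union(drop, path)
    }
    if (length(drop) == 0) break
    g <- igraph::delete_vertices(g, drop)
  }
  alive <- as.integer(igraph::V(g)$name)
  pts <- pts[alive, , drop = FALSE]
  radius <- radius[alive]
  idx <- idx[alive, , drop = FALSE]
  igraph::V(g)$name <- as.character(seq_len(nrow(pts)))

  deg <- igraph::degree(g)
  endpoints <- which(deg == 1)
  branch_points <- which(deg >= 3)
  sac_point <- which.max(radius)

  # neck branch point: branch point closest to the sac point along the graph
  if (length(branch_points) > 0) {
    dists <- igraph::distances(g, v = sac_point, to = branch_points)
    neck_branch_point <- branch_points[which.min(dists)]
  } else {
    neck_branch_point <- NA_integer_
  }

  aneurysm_points <- integer(0)
  branches <- list()
  if (!is.na(neck_branch_point)) {
    # cluster of branch points near the junction (thinning can split a
    # Y-junction into several nearby degree-3 nodes)
    near <- branch_points[igraph::distances(g, v = neck_branch_point,
                                            to = branch_points) <=
                          3 * max(volume$spacing)]
    g2 <- igraph::delete_vertices(g, near)
    keep_ids <- setdiff(seq_len(nrow(pts)), near)
    comp2 <- igraph::components(g2)
    sac_comp <- comp2$membership[match(sac_point, keep_ids)]
    aneurysm_points <- sort(c(keep_ids[comp2$membership == sac_comp], near))
    for (cc in setdiff(unique(comp2$membership), sac_comp)) {
      members <- keep_ids[comp2$membership == cc]
      if (length(members) >= 2) branches[[length(branches) + 1L]] <- members
    }
  } else {
    aneurysm_points <- seq_len(nrow(pts))
  }

  structure(list(points = pts, edges = igraph::as_edgelist(g, names = FALSE),
                 radius = radius, endpoints = endpoints,
                 branch_points = branch_points, sac_point = sac_point,
                 aneurysm_points = aneurysm_points,
                 branch_centerline_points = setdiff(seq_len(nrow(pts)),
                                                    aneurysm_points),
                 neck_branch_point = neck_branch_point,
                 branches = branches, graph = g),
            class = "centerline_graph")
}

#' @export
print.centerline_graph <- function(x, ...) {
  cat("<centerline_graph> ", nrow(x$points), " points, ",
      length(x$endpoints), " endpoints, ", length(x$branch_points),
      " branch points, ", length(x$branches), " vessel branches\n", sep = "")
  invisible(x)
}

#' 26-connected components of a mask
#' @noRd
.connected_components26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nlab <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  todo <- which(mask & lab == 0L)
  while (length(todo) > 0) {
    nlab <- nlab + 1L
    queue <- todo[1]
    lab[queue] <- nlab
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      ai <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- sweep(ai, 2, offs[r, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1, drop = TRUE] + (nb[ok, 2, drop = TRUE] - 1) * d[1] +
               (nb[ok, 3, drop = TRUE] - 1) * d[1] * d[2]
        lin <- lin[mask[lin] & lab[lin] == 0L]
        if (length(lin) > 0) {
          lab[lin] <- nlab
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
    todo <- which(mask & lab == 0L)
  }
  list(labels = lab, n = nlab)
}

#' Background voxels 6-adjacent to the foreground (array indices)
#' @noRd
.boundary_voxels <- function(mask) {
  d <- dim(mask)
  shifted <- function(dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- mask[xs - dx, ys - dy, zs - dz]
    out
  }
  nb_fg <- shifted(1, 0, 0) | shifted(-1, 0, 0) | shifted(0, 1, 0) |
           shifted(0, -1, 0) | shifted(0, 0, 1) | shifted(0, 0, -1)
  which(!mask & nb_fg, arr.ind = TRUE)
}
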