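#' Barycentric vertex areas of a mesh
#'
#' One third of the area of the incident triangles per vertex; sums to the
#' total mesh area and is exact on uniform meshes.
#'
#' @param mesh a [surface_mesh()].
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  tri_area <- sqrt(cx^2 + cy^2 + cz^2) / 2
  areas <- numeric(nrow(v))
  for (k in 1:3) {
    acc <- tapply(tri_area, f[, k], sum)
    ids <- as.integer(names(acc))
    areas[ids] <- areas[ids] + acc / 3
  }
  areas
}

#' Spatial wall pulsation (SWP) detection and classification
#'
#' Vertices whose displacement amplitude exceeds the amplitude threshold are
#' grouped into edge-connected surface regions; regions below the minimum
#' area are discarded. SWP is present when the remaining pulsating area also
#' reaches the minimum fraction of the sac surface; it is focal when the
#' pulsating fraction stays below the heterogeneity cutoff and heterogeneous
#' otherwise. Defaults follow the conservative spatial-coherence criteria:
#' amplitude > 0.3 mm, region area >= 5 mm^2, >= 5% of the sac surface,
#' heterogeneous at >= 20%.
#'
#' @param field a [compute_displacement()] result on the sac mesh.
#' @param sac_area total sac surface area in mm^2 (defaults to the reference
#'   mesh area).
#' @param amp_threshold displacement amplitude threshold (mm).
#' @param area_threshold minimum region area (mm^2).
#' @param fraction_threshold minimum pulsating fraction of the sac surface.
#' @param hetero_fraction fraction at or above which SWP is heterogeneous.
#' @return an object of class `swp_result`: `classification` (`"focal"`,
#'   `"heterogeneous"` or `"none"`), `regions` (list of `vertices`, `area`,
#'   `peak_amplitude`), `pulsating_area_total` (mm^2), `pulsating_fraction`,
#'   and the thresholds used.
#' @export
detect_swp <- function(field, sac_area = NULL, amp_threshold = 0.3,
                       area_threshold = 5, fraction_threshold = 0.05,
                       hetero_fraction = 0.20) {
  stopifnot(inherits(field, "displacement_field"))
  mesh <- field$reference_mesh
  if (is.null(sac_area)) sac_area <- mesh_area(mesh)
  stopifnot(sac_area > 0)
  areas <- vertex_areas(mesh)
  hot <- which(field$amplitude > amp_threshold)
  regions <- list()
  if (length(hot) > 0) {
    f <- mesh$faces
    in_hot <- logical(nrow(mesh$vertices)); in_hot[hot] <- TRUE
    eall <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    keep <- in_hot[eall[, 1]] & in_hot[eall[, 2]]
    remap <- integer(nrow(mesh$vertices)); remap[hot] <- seq_along(hot)
    g <- igraph::graph_from_edgelist(cbind(remap[eall[keep, 1]],
                                           remap[eall[keep, 2]]),
                                     directed = FALSE)
    if (igraph::vcount(g) < length(hot)) {
      g <- igraph::add_vertices(g, length(hot) - igraph::vcount(g))
    }
    comp <- igraph::components(g)
    for (cc in seq_len(comp$no)) {
      vids <- hot[comp$membership == cc]
      a <- sum(areas[vids])
      if (a >= area_threshold) {
        regions[[length(regions) + 1L]] <-
          list(vertices = vids, area = a,
               peak_amplitude = max(field$amplitude[vids]))
      }
    }
  }
  total <- if (length(regions)) sum(vapply(regions, `[[`, 0, "area")) else 0
  fraction <- total / sac_area
  classification <- if (length(regions) == 0 || fraction < fraction_threshold) {
    "none"
  } else if (fraction < hetero_fraction) "focal" else "heterogeneous"
  structure(list(classification = classification, regions = regions,
                 pulsating_area_total = total, pulsating_fraction = fraction,
                 thresholds = list(amp = amp_threshold, area = area_threshold,
                                   fraction = fraction_threshold,
                                   hetero_fraction = hetero_fraction)),
            class = "swp_result")
}

#' @export
print.swp_result <- function(x, ...) {
  cat("<swp_result> ", x$classification, " (", length(x$regions),
      " region(s), ", signif(x$pulsating_area_total, 4), " mm^2 = ",
      signif(100 * x$pulsating_fraction, 3), "% of sac surface)\n", sep = "")
  invisible(x)
}
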