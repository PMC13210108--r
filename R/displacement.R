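#' Per-vertex wall displacement over the cardiac cycle
#'
#' For every vertex of the reference-phase mesh and every phase, the wall
#' displacement is the Euclidean distance to the corresponding vertex of that
#' phase's mesh,
#' \deqn{d_i(t) = \sqrt{\sum_{j=1}^{3} (v(t)_{i,j} - r_{i,j})^2},}
#' which is non-negative by construction and zero at the reference phase.
#' Correspondence is nearest-vertex matching on the phase mesh (no
#' regularised registration is attempted). The per-vertex amplitude is
#' `max_t d_i(t)`.
#'
#' @param reference reference-phase [surface_mesh()] (conventionally phase 1,
#'   the 0% R-R gating origin).
#' @param phase_meshes list of [surface_mesh()], one per phase, in the same
#'   world frame.
#' @return an object of class `displacement_field`: `reference_mesh`, `d`
#'   (n_vertices x n_phases, mm), `amplitude` (mm).
#' @export
compute_displacement <- function(reference, phase_meshes) {
  stopifnot(inherits(reference, "surface_mesh"), length(phase_meshes) >= 1)
  nv <- nrow(reference$vertices)
  d <- matrix(0, nv, length(phase_meshes))
  for (t in seq_along(phase_meshes)) {
    m <- phase_meshes[[t]]
    if (!inherits(m, "surface_mesh") || nrow(m$vertices) == 0) {
      stop("phase ", t, " mesh is empty")
    }
    # grid cell ~ 2x mean inter-vertex spacing of the searched mesh
    cell <- max(2 * sqrt(mesh_area(m) / nrow(m$vertices)), 1e-6)
    nn <- .nn_match(reference$vertices, m$vertices, cell)
    d[, t] <- sqrt(rowSums((reference$vertices -
                            m$vertices[nn, , drop = FALSE])^2))
  }
  structure(list(reference_mesh = reference, d = d,
                 amplitude = apply(d, 1, max)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("<displacement_field> ", nrow(x$d), " vertices x ", ncol(x$d),
      " phases, amplitude ", signif(min(x$amplitude), 3), "-",
      signif(max(x$amplitude), 3), " mm\n", sep = "")
  invisible(x)
}

#' Write a displacement field as a long-format CSV
#'
#' Columns `vertex_id`, `phase`, `d_mm`.
#'
#' @param field a [compute_displacement()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_displacement_csv <- function(field, path) {
  nv <- nrow(field$d); np <- ncol(field$d)
  df <- data.frame(vertex_id = rep(seq_len(nv), np),
                   phase = rep(seq_len(np), each = nv),
                   d_mm = as.vector(field$d))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
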