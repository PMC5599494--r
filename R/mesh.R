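#' Build a validated triangle mesh
#'
#' Constructs a manifold triangle mesh from vertex positions and face index
#' triples.  For closed meshes the orientation is normalized to outward
#' (positive enclosed volume); a mesh whose faces are consistently oriented
#' but inward is repaired by a global flip.  Validation failures (non-manifold
#' edges, inconsistent orientation, duplicate faces) raise classed errors.
#'
#' @param positions numeric matrix, one row per vertex (x, y, z).
#' @param faces integer matrix, one row per face, 1-based vertex indices with
#'   consistent winding.
#' @param closed logical; if \code{TRUE} (default) every edge must have
#'   exactly two incident faces.  Open patches are permitted only for
#'   geometry fixtures, not for simulation.
#' @return An object of class \code{"trimesh"} with elements
#'   \code{positions}, \code{faces}, \code{closed}.
#' @examples
#' m <- mesh_tetrahedron()
#' euler_characteristic(m)
#' @export
trimesh <- function(positions, faces, closed = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(positions) != 3) stop("'positions' must have 3 columns")
  if (ncol(faces) != 3) stop("'faces' must have 3 columns")
  if (nrow(positions) < 4) stop("a mesh needs at least 4 vertices")
  if (min(faces) < 1 || max(faces) > nrow(positions))
    stop("face indices out of range")
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- as.numeric(faces[, 1]) + faces[, 2] + faces[, 3] -
    as.numeric(lo) - hi
  key <- (as.numeric(lo) * (nrow(positions) + 1) + mid) *
    (nrow(positions) + 1) + hi
  if (anyDuplicated(key))
    stop(errorCondition("duplicate faces in mesh",
                        class = c("dtv_duplicate_face", "error", "condition")))
  val <- tryCatch(cpp_validate(positions, faces, closed), error = function(e) e)
  if (inherits(val, "error")) {
    msg <- conditionMessage(val)
    cls <- if (grepl("orientation", msg)) "dtv_orientation_error"
           else if (grepl("open", msg)) "dtv_open_mesh"
           else "dtv_nonmanifold"
    stop(errorCondition(msg, class = c(cls, "error", "condition")))
  }
  m <- structure(list(positions = positions, faces = faces, closed = closed),
                 class = "trimesh")
  if (closed) {
    v <- cpp_signed_volume(positions, faces)
    if (v < 0) {
      # consistently inward: repair by global orientation flip
      m$faces <- faces[, c(1L, 3L, 2L), drop = FALSE]
    }
  }
  m
}

#' @export
print.trimesh <- function(x, ...) {
  ne <- nrow(mesh_edges(x))
  cat(sprintf("trimesh: %d vertices, %d edges, %d faces (%s), chi = %d\n",
              nrow(x$positions), ne, nrow(x$faces),
              if (x$closed) "closed" else "open",
              euler_characteristic(x)))
  invisible(x)
}

#' Unique edges of a mesh
#'
#' @param mesh a [trimesh].
#' @return Two-column integer matrix of vertex pairs (smaller index first).
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2, drop = FALSE], f[, 2:3, drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  keep <- !duplicated(as.numeric(lo) * (nrow(mesh$positions) + 1) + hi)
  cbind(lo[keep], hi[keep])
}

#' Euler characteristic V - E + F
#'
#' Equals 2 for a closed genus-0 surface and is conserved by all three
#' topological moves (flip, split, merge).
#'
#' @param mesh a [trimesh].
#' @return Integer.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$positions) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Full geometry cache of a mesh
#'
#' Computes per-face areas, unit normals and centroids; per-edge lengths and
#' signed dihedral angles; per-vertex total mean curvature \eqn{M_i = \sum_j
#' l_j \theta_j / 4}, vertex area \eqn{A_i = \sum_j a_j/3} and angle deficit;
#' and the scalar totals (area, enclosed volume, area-weighted center).
#'
#' @param mesh a [trimesh].
#' @return A list; see Details in the package vignette.
#' @export
mesh_geometry <- function(mesh) {
  g <- cpp_geometry(mesh$positions, mesh$faces, mesh$closed)
  if (!mesh$closed) g$volume <- NA_real_
  g
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes over faces; positive
#' for outward orientation.
#'
#' @param mesh a closed [trimesh].
#' @return Scalar volume.
#' @examples
#' enclosed_volume(mesh_tetrahedron())  # 1/6 for the unit corner tetrahedron
#' @export
enclosed_volume <- function(mesh) {
  if (!mesh$closed)
    stop(errorCondition("enclosed volume undefined for an open mesh",
                        class = c("dtv_open_mesh", "error", "condition")))
  cpp_signed_volume(mesh$positions, mesh$faces)
}

#' Signed dihedral angle at an edge
#'
#' The angle between the outward unit normals of the two faces sharing the
#' edge, in \eqn{(-\pi, \pi)}: positive where the surface folds convexly
#' (normals diverge outward), zero for coplanar faces.  The sign flips under
#' reflection of the surface.
#'
#' @param mesh a [trimesh].
#' @param edge integer vector of length 2 (vertex pair).
#' @return Scalar angle in radians.
#' @export
edge_dihedral_angle <- function(mesh, edge) {
  g <- mesh_geometry(mesh)
  i <- which((g$edges[, 1] == min(edge) & g$edges[, 2] == max(edge)))
  if (length(i) == 0) stop("no such edge: ", edge[1], "-", edge[2])
  th <- g$edge_dihedral[i]
  if (is.na(th)) stop("edge ", edge[1], "-", edge[2], " is a boundary edge")
  th
}

#' Discrete curvature measures at vertices
#'
#' For each vertex: the total mean curvature \eqn{M_i}, the vertex area
#' \eqn{A_i}, the angle deficit \eqn{2\pi - \sum \alpha}, and the local
#' Gaussian curvature estimate \code{deficit / A_i}.  Summed over a closed
#' genus-0 mesh the angle deficit equals \eqn{4\pi} (Gauss--Bonnet).
#'
#' @param mesh a [trimesh].
#' @param vertices optional integer vector restricting the output rows.
#' @return A data.frame with columns \code{vertex}, \code{M}, \code{A},
#'   \code{angle_deficit}, \code{gaussian}.
#' @export
vertex_curvature_measures <- function(mesh, vertices = NULL) {
  g <- mesh_geometry(mesh)
  out <- data.frame(vertex = seq_len(nrow(mesh$positions)),
                    M = g$vertex_M, A = g$vertex_A,
                    angle_deficit = g$angle_deficit,
                    gaussian = g$angle_deficit / g$vertex_A)
  if (!is.null(vertices)) out <- out[vertices, , drop = FALSE]
  out
}

#' Revalidate all mesh invariants
#'
#' Full rebuild-and-check used by tests and the \code{validate} CLI
#' subcommand: manifoldness, orientation, Euler characteristic 2 and
#' \eqn{E = 3F/2} (closed meshes), positive volume, Gauss--Bonnet total
#' angle deficit \eqn{4\pi}.
#'
#' @param mesh a [trimesh].
#' @param tol tolerance for the Gauss--Bonnet check.
#' @return \code{TRUE} invisibly; errors otherwise.
#' @export
validate_mesh <- function(mesh, tol = 1e-9) {
  cpp_validate(mesh$positions, mesh$faces, mesh$closed)
  if (mesh$closed) {
    ne <- nrow(mesh_edges(mesh))
    nf <- nrow(mesh$faces)
    if (2L * ne != 3L * nf) stop("E = 3F/2 violated")
    if (euler_characteristic(mesh) != 2L)
      stop("Euler characteristic is not 2")
    if (enclosed_volume(mesh) <= 0) stop("non-positive enclosed volume")
    defect <- sum(mesh_geometry(mesh)$angle_deficit)
    if (abs(defect - 4 * pi) > tol)
      stop(sprintf("Gauss-Bonnet violated: total deficit %.12g != 4*pi",
                   defect))
  }
  invisible(TRUE)
}
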