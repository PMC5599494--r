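# The three local remeshing moves: edge flip (membrane fluidity), edge split
# (expansion) and edge merge/collapse (shrinkage).  All three preserve
# manifoldness, orientation and the Euler characteristic; illegal moves raise
# a classed condition ("dtv_illegal_move") and leave the mesh untouched.

op_apply <- function(mesh, edge, op, gate) {
  res <- cpp_apply_op(mesh$positions, mesh$faces, as.integer(edge[1]),
                      as.integer(edge[2]), op, gate, mesh$closed)
  if (!isTRUE(res$ok)) {
    stop(errorCondition(
      sprintf("%s of edge %d-%d rejected: %s", op, edge[1], edge[2],
              res$reason),
      class = c("dtv_illegal_move", paste0("dtv_illegal_", op),
                "error", "condition")))
  }
  # the C++ operations preserve manifoldness, orientation and closure, so the
  # result is assembled directly; the property tests revalidate independently
  out <- structure(list(positions = res$positions, faces = res$faces,
                        closed = mesh$closed),
                   class = "trimesh")
  attr(out, "new_vertex") <- res$new_vertex
  out
}

#' Flip an edge shared by two triangles
#'
#' Replaces the shared edge by the opposite diagonal of the triangle pair.
#' Vertex, edge and face counts are unchanged; the move is an involution on
#' the connectivity.  Legality requires that the opposite vertices are not
#' already connected, that endpoint valences stay at or above the minimum,
#' and that the resulting faces pass the quality gate.
#'
#' @param mesh a [trimesh].
#' @param edge integer vector of length 2, the vertex pair of the edge.
#' @param gate quality-gate thresholds, see [flip_legal()].
#' @return The modified mesh.  Illegal moves raise a condition of class
#'   \code{"dtv_illegal_move"} naming the reason.
#' @export
flip_edge <- function(mesh, edge, gate = default_gate()) {
  op_apply(mesh, edge, "flip", gate)
}

#' Split a pair of neighboring triangles
#'
#' Inserts a new vertex at the center of the shared edge and splits each
#' adjacent triangle toward its opposite vertex: two triangles become four.
#' The surface geometry is pointwise unchanged at the instant of the split
#' (\code{dF = +2}, \code{dV = +1}, \code{dE = +3}).
#'
#' @inheritParams flip_edge
#' @return The modified mesh, with the new vertex index in
#'   \code{attr(, "new_vertex")}.
#' @export
split_pair <- function(mesh, edge, gate = default_gate()) {
  op_apply(mesh, edge, "split", gate)
}

#' Merge a pair of neighboring triangles with their surroundings
#'
#' Collapses the shared edge to its midpoint, removing the two incident
#' triangles (\code{dF = -2}, \code{dV = -1}, \code{dE = -3}).  Legality
#' requires the link condition (the endpoints share exactly the two opposite
#' vertices as common neighbors), valence bounds, the face-quality gate, and
#' at least \code{min_faces} faces after the collapse.
#'
#' @inheritParams flip_edge
#' @return The modified mesh.
#' @export
merge_pair <- function(mesh, edge, gate = default_gate()) {
  op_apply(mesh, edge, "merge", gate)
}

#' Legality check for a topological move
#'
#' @inheritParams flip_edge
#' @param op one of \code{"flip"}, \code{"split"}, \code{"merge"}.
#' @return List with \code{ok} (logical) and \code{reason} (character).
#' @export
op_legal <- function(mesh, edge, op = c("flip", "split", "merge"),
                     gate = default_gate()) {
  op <- match.arg(op)
  cpp_op_legal(mesh$positions, mesh$faces, as.integer(edge[1]),
               as.integer(edge[2]), op, gate, mesh$closed)
}

#' @rdname op_legal
#' @export
flip_legal <- function(mesh, edge, gate = default_gate()) {
  op_legal(mesh, edge, "flip", gate)
}

#' Energy gap of a trial topological event
#'
#' \eqn{\Delta_i U = U_{total}(after) - U_{total}(before)} for the event on
#' edge \eqn{i}, with the mesh left unchanged.  Flips are evaluated over the
#' local stencil (this equals the global recomputation because only the
#' stencil's geometry changes); splits and merges are evaluated by applying
#' the move to a copy and recomputing, since a merge moves vertices and its
#' influence includes the repulsion term.
#'
#' @inheritParams flip_edge
#' @param kind one of \code{"flip"}, \code{"split"}, \code{"merge"}.
#' @param params a [mech_params].
#' @param active include the active energy term.
#' @return Scalar energy difference (in units of \eqn{k_B T}).
#' @export
trial_delta <- function(mesh, edge, kind = c("flip", "split", "merge"),
                        params = mech_params(), active = NULL,
                        gate = default_gate()) {
  kind <- match.arg(kind)
  if (is.null(active)) active <- params$kappa_act > 0
  if (kind == "flip") {
    res <- cpp_flip_delta(mesh$positions, mesh$faces, as.integer(edge[1]),
                          as.integer(edge[2]), unclass(params), gate, active,
                          mesh$closed)
    if (!isTRUE(res$ok)) {
      stop(errorCondition(
        sprintf("flip of edge %d-%d rejected: %s", edge[1], edge[2],
                res$reason),
        class = c("dtv_illegal_move", "error", "condition")))
    }
    return(res$delta)
  }
  before <- membrane_energy(mesh, params, active)$U_total
  after <- membrane_energy(op_apply(mesh, edge, kind, gate), params,
                           active)$U_total
  after - before
}
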