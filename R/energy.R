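#' Energy breakdown of a membrane configuration
#'
#' Evaluates all terms of the effective energy
#' \deqn{U = U_{cc} + U_{eff} + U_{act}}
#' where \eqn{U_{cc}} is the short-range vertex-pair repulsion, \eqn{U_{eff}}
#' comprises volume elasticity \eqn{(K_v/2)(v/v_{eq}-1)^2}, per-triangle
#' surface elasticity \eqn{(K_a/2)(a_i/a_{eq}-1)^2} and the discrete bending
#' energy \eqn{\sum_i 2K_c M_i^2/A_i}, and \eqn{U_{act}} is the polarized
#' active surface energy \eqn{\sum_i \kappa_{act}(1+\cos\phi_i)a_i/2}.
#'
#' @param mesh a [trimesh].
#' @param params a [mech_params] object.
#' @param active logical; include the active term (requires
#'   \code{kappa_act > 0}).
#' @return Named list with components \code{U_cc}, \code{U_volume},
#'   \code{U_area}, \code{U_bending}, \code{U_act}, \code{U_total}.
#' @export
membrane_energy <- function(mesh, params = mech_params(), active = NULL) {
  if (is.null(active)) active <- params$kappa_act > 0
  e <- cpp_energy(mesh$positions, mesh$faces, unclass(params), active,
                  mesh$closed)
  as.list(e)
}

#' Vertex-pair repulsion energy
#'
#' \eqn{U_{cc} = \sum_{i<j, l_{ij} < l_{rep}} (K_r/2)(l_{ij}/l_{rep}-1)^2},
#' evaluated with a uniform spatial hash of cell size \code{l_rep}.
#'
#' @param x a [trimesh] or a numeric matrix of positions.
#' @param params a [mech_params] object (only \code{K_r}, \code{l_rep} used).
#' @return Scalar energy.
#' @export
repulsion_energy <- function(x, params = mech_params()) {
  p <- if (inherits(x, "trimesh")) x$positions else as.matrix(x)
  storage.mode(p) <- "double"
  cpp_repulsion(p, params$K_r, params$l_rep)
}

#' Effective (volume, area, bending) energies
#'
#' @inheritParams membrane_energy
#' @return Named list \code{U_volume}, \code{U_area}, \code{U_bending}.
#' @export
effective_energy <- function(mesh, params = mech_params()) {
  e <- membrane_energy(mesh, params, active = FALSE)
  e[c("U_volume", "U_area", "U_bending")]
}

#' Polarized active surface energy
#'
#' \eqn{U_{act} = \sum_i \kappa_{act}(1+\cos\phi_i)a_i/2}, where \eqn{\phi_i}
#' is the angle between the +x axis and the vector from \code{center} to the
#' centroid of face \eqn{i}.  High tension at \eqn{\phi = 0} (front along +x)
#' and zero at the rear.
#'
#' @inheritParams membrane_energy
#' @param center the vesicle center; defaults to the area-weighted centroid
#'   of face centroids.
#' @return Scalar energy.
#' @export
active_energy <- function(mesh, params = mech_params(), center = NULL) {
  if (params$kappa_act == 0) return(0)
  g <- mesh_geometry(mesh)
  if (is.null(center)) center <- g$center
  d <- sweep(g$face_centroid, 2, center)
  dn <- sqrt(rowSums(d^2))
  if (any(dn == 0)) stop("face centroid coincides with the vesicle center")
  w <- params$kappa_act * (1 + d[, 1] / dn) / 2
  sum(w * g$face_area)
}

#' Per-vertex forces -grad U
#'
#' Exact analytic gradients of all energy terms.  The active-term angle
#' \eqn{\phi_i} is held constant during differentiation (it is redefined at
#' each time step), so only the triangle area is differentiated in
#' \eqn{U_{act}}.
#'
#' @inheritParams membrane_energy
#' @return Numeric matrix, one force vector per vertex.
#' @export
membrane_forces <- function(mesh, params = mech_params(), active = NULL) {
  if (is.null(active)) active <- params$kappa_act > 0
  cpp_forces(mesh$positions, mesh$faces, unclass(params), active, mesh$closed)
}
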