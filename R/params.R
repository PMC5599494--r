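#' Mechanical parameters of the membrane model
#'
#' Container for all energy and dynamics constants, in model units where the
#' unit length is \eqn{\sqrt{a_{eq}}}, the unit energy is \eqn{k_B T}, and the
#' unit time is \eqn{0.1\,\eta\,a_{eq}/k_B T} (which fixes \code{eta = 10}).
#'
#' @param K_v volume elasticity of the vesicle.
#' @param v_eq equilibrium vesicle volume.  The default corresponds to a
#'   vesicle of area \eqn{1000\,a_{eq}} at sphericity 0.85 (see
#'   [equilibrium_volume()]).
#' @param K_a surface elasticity acting on individual triangle areas.
#' @param a_eq equilibrium triangle area (1 in model units).
#' @param K_c bending rigidity.
#' @param K_r repulsive modulus of the vertex-pair constraint energy.
#' @param l_rep repulsive distance.  The default is half the edge length of
#'   the equilateral triangle of area \code{a_eq}, so equilibrium packings are
#'   repulsion-free.
#' @param kappa_act amplitude of the polarized active surface energy
#'   (0 disables the term).
#' @param eta friction coefficient between membrane and microenvironment.
#' @param k_BT thermal energy (1 in model units).
#' @return A list of class \code{"mech_params"}.
#' @examples
#' p <- mech_params(K_c = 3)
#' p$v_eq
#' @export
mech_params <- function(K_v = 1e4,
                        v_eq = equilibrium_volume(1000, 0.85),
                        K_a = 50,
                        a_eq = 1,
                        K_c = 10,
                        K_r = 1e3,
                        l_rep = 0.5 * sqrt(4 * a_eq / sqrt(3)),
                        kappa_act = 0,
                        eta = 10,
                        k_BT = 1) {
  p <- list(K_v = K_v, v_eq = v_eq, K_a = K_a, a_eq = a_eq, K_c = K_c,
            K_r = K_r, l_rep = l_rep, kappa_act = kappa_act, eta = eta,
            k_BT = k_BT)
  for (nm in c("K_v", "K_a", "K_c", "K_r", "kappa_act")) {
    if (p[[nm]] < 0) stop(sprintf("'%s' must be >= 0", nm))
  }
  if (l_rep <= 0) stop("'l_rep' must be > 0")
  if (a_eq <= 0 || v_eq <= 0) stop("'a_eq' and 'v_eq' must be > 0")
  if (eta <= 0 || k_BT < 0) stop("'eta' must be > 0 and 'k_BT' >= 0")
  class(p) <- "mech_params"
  p
}

#' Turnover and fluidity timescale parameters
#'
#' @param tau_f characteristic time of membrane fluidity (edge flips).
#' @param tau_t characteristic time of molecular turnover (splits/merges);
#'   may be \code{Inf} to disable turnover.
#' @param eps_t energetic cost of molecular turnover.
#' @param gamma_t critical strain for the energetic reduction of turnover.
#' @return A list of class \code{"turnover_params"}.  A warning is emitted
#'   when the scheduling contract \code{tau_f << tau_t} is violated.
#' @export
turnover_params <- function(tau_f = 1e-2, tau_t = 1, eps_t = 0.1,
                            gamma_t = 0.05) {
  if (tau_f <= 0) stop("'tau_f' must be > 0")
  if (tau_t <= 0) stop("'tau_t' must be > 0 (use Inf to disable turnover)")
  if (gamma_t <= 0) stop("'gamma_t' must be > 0")
  if (is.finite(tau_t) && tau_f >= tau_t) {
    warning("timescale separation violated: tau_f >= tau_t; ",
            "local fluidity should be much faster than local turnover")
  }
  structure(list(tau_f = tau_f, tau_t = tau_t, eps_t = eps_t,
                 gamma_t = gamma_t),
            class = "turnover_params")
}

#' Molecule reservoir bookkeeping
#'
#' Tracks the number of membrane molecules in the vesicle (\code{M_t}, always
#' equal to \code{N_t * m_u}) and in the implicit intracellular reservoir
#' (\code{M_r = M_tt - M_t}); the total \code{M_tt} is conserved.
#'
#' @param M_eq equilibrium number of molecules within the vesicle.
#' @param M_inst instability (standard-deviation scale) of the molecule
#'   number; larger values weaken the restoring chemical potential.
#' @param m_u molecules per triangle (1 in model units).
#' @param M_tt total molecules in vesicle plus reservoir.  Defaults to
#'   \code{2 * M_eq} so that vesicle and reservoir hold comparable amounts.
#' @param M_t current molecules within the vesicle (defaults to \code{M_eq}).
#' @return A list of class \code{"reservoir_state"} with an \code{M_r} field.
#' @export
reservoir_state <- function(M_eq = 1e3, M_inst = 1e3, m_u = 1,
                            M_tt = 2 * M_eq, M_t = M_eq) {
  if (M_inst <= 0) stop("'M_inst' must be > 0")
  if (m_u <= 0) stop("'m_u' must be > 0")
  if (M_t > M_tt) stop("'M_t' cannot exceed 'M_tt'")
  structure(list(M_eq = M_eq, M_inst = M_inst, m_u = m_u, M_tt = M_tt,
                 M_t = M_t, M_r = M_tt - M_t),
            class = "reservoir_state")
}

#' Equilibrium volume for a target area and sphericity
#'
#' Sphericity is the ratio of the enclosed volume to the volume of the sphere
#' with the same surface area, so the volume of a vesicle of area \eqn{A} and
#' sphericity \eqn{s} is \eqn{s \cdot \frac{4}{3}\pi (A/4\pi)^{3/2}}.
#' For area \eqn{1000\,a_{eq}} and sphericity 0.85 this gives the default
#' equilibrium volume 2527 (after rounding).
#'
#' @param area total membrane surface area (in units of \code{a_eq}).
#' @param sphericity target sphericity in (0, 1].
#' @return The enclosed volume, a scalar.
#' @examples
#' round(equilibrium_volume(1000, 0.85))
#' @export
equilibrium_volume <- function(area, sphericity = 0.85) {
  stopifnot(area > 0, sphericity > 0, sphericity <= 1)
  sphericity * (4 / 3) * pi * (area / (4 * pi))^1.5
}

#' Sphericity of a closed mesh
#'
#' @param mesh a [trimesh] object (closed).
#' @return Volume over the volume of the equal-area sphere; 1 for a sphere.
#' @export
sphericity <- function(mesh) {
  g <- mesh_geometry(mesh)
  g$volume / ((4 / 3) * pi * (g$total_area / (4 * pi))^1.5)
}

# quality gate defaults shared by all topological operations
default_gate <- function(min_angle_deg = 5, min_valence = 3, max_valence = 12,
                         min_faces = 8) {
  list(min_angle = min_angle_deg * pi / 180, min_valence = min_valence,
       max_valence = max_valence, min_faces = min_faces)
}
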