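#' Generate an equilibrated initial vesicle
#'
#' Builds a closed genus-0 triangulation with exactly \code{face_count}
#' faces: \code{face_count/2 + 2} points are placed on the unit sphere as a
#' Fibonacci lattice and triangulated by their convex hull (which has exactly
#' \eqn{2V - 4} faces), the mesh is scaled to total area
#' \code{face_count * a_eq}, and the configuration is equilibrated by
#' noiseless gradient descent with greedy edge-flip sweeps (turnover off)
#' until the energy change per step falls below \code{tol}.
#'
#' @param face_count even integer, at least 20.
#' @param sphericity target sphericity; sets the equilibrium volume through
#'   [equilibrium_volume()] unless \code{params} overrides \code{v_eq}.
#' @param params a [mech_params]; the default uses bending rigidity
#'   \code{K_c = 10} for the equilibration, the standard initial-condition
#'   protocol.
#' @param seed RNG seed for the flip sweeps during relaxation.
#' @param tol energy-plateau stopping criterion (energy change per step).
#' @param max_steps cap on relaxation steps.
#' @param dt relaxation step size.
#' @return A [trimesh] with attribute \code{"relax"} reporting steps run and
#'   convergence.
#' @examples
#' v <- generate_vesicle(64, seed = 1)
#' nrow(v$faces)
#' @export
generate_vesicle <- function(face_count, sphericity = 0.85, params = NULL,
                             seed = 1, tol = 1e-6, max_steps = 60000,
                             dt = 5e-3) {
  face_count <- as.integer(face_count)
  if (face_count %% 2L != 0L || face_count < 20L)
    stop("'face_count' must be an even integer >= 20")
  if (is.null(params)) {
    params <- mech_params(K_c = 10,
                          v_eq = equilibrium_volume(face_count, sphericity))
  }
  n <- face_count %/% 2L + 2L
  p <- fibonacci_sphere(n)
  f <- cpp_convex_hull(p)
  if (nrow(f) != face_count) {
    stop(sprintf("failed to reach exact face count: hull has %d faces, %d requested",
                 nrow(f), face_count))
  }
  m <- trimesh(p, f)
  a0 <- mesh_geometry(m)$total_area
  m$positions <- m$positions * sqrt(face_count * params$a_eq / a0)
  relax_mesh(m, params, seed = seed, tol = tol, max_steps = max_steps,
             dt = dt)
}

#' Noiseless relaxation with greedy flip sweeps
#'
#' Gradient descent on the total energy (zero temperature) interleaved with
#' greedy edge flips (accepted only when they lower the energy), used to
#' equilibrate generated meshes.  Stops when the per-step energy change drops
#' below \code{tol} or after \code{max_steps} steps.
#'
#' @param mesh a closed [trimesh].
#' @param params a [mech_params].
#' @param seed RNG seed (edge order within sweeps is randomized).
#' @param tol stopping criterion on the per-step energy change.
#' @param max_steps step cap.
#' @param dt descent step size.
#' @param tau_f flip-attempt timescale during relaxation; the default
#'   attempts a tenth of the edges per step.
#' @return The relaxed [trimesh] with attribute \code{"relax"}.
#' @export
relax_mesh <- function(mesh, params = mech_params(), seed = 1, tol = 1e-6,
                       max_steps = 20000, dt = 1e-3, tau_f = 10 * dt) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim_config(mech = params,
                    turnover = turnover_params(tau_f = tau_f, tau_t = Inf),
                    reservoir = reservoir_state(M_eq = nrow(mesh$faces)),
                    dt = dt, sample_every = 0, seed = NULL, noise = FALSE,
                    active = FALSE)
  ctrl <- ctrl_list(cfg, max_steps, greedy = TRUE, stop_tol = tol)
  ctrl$log_events <- FALSE
  out <- cpp_simulate(mesh$positions, mesh$faces, unclass(params), ctrl,
                      cfg$gate, zero_state(nrow(mesh$faces)))
  res <- trimesh(out$positions, out$faces)
  attr(res, "relax") <- list(steps = out$steps_run,
                             converged = out$converged)
  res
}

# Fibonacci lattice on the unit sphere: n points in generic position.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * i
  cbind(r * cos(th), r * sin(th), z)
}
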