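#' Simulation configuration
#'
#' Bundles the physical parameters, the turnover/fluidity timescales, the
#' reservoir state and the run schedule.  Defaults follow the model's
#' standard parameter table: \code{dt = 1e-3}, \code{tau_f = 1e-2} (one
#' topology sweep per mechanical step, attempt probability
#' \code{dt/tau_f = 0.1} per edge).
#'
#' @param mech a [mech_params].
#' @param turnover a [turnover_params].
#' @param reservoir a [reservoir_state].  Its \code{M_t} is synchronized to
#'   \code{N_t * m_u} when the run starts.
#' @param dt integration time step (must satisfy \code{dt <= tau_f}).
#' @param t_end total simulated time.
#' @param sample_every record observables every this many steps.
#' @param seed RNG seed (all randomness flows through R's RNG).
#' @param noise include thermal noise (FALSE gives gradient descent).
#' @param active include the active surface energy (default: on when
#'   \code{kappa_act > 0}).
#' @param gate quality-gate thresholds for topological moves.
#' @param log_flip_attempts log rejected/unattempted flips in the event log
#'   (accepted flips and all turnover attempts are always logged).
#' @param frame_every export a mesh frame every this many steps (0 = none).
#' @param frames_dir directory for frame export (OFF format).
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(mech = mech_params(),
                       turnover = turnover_params(),
                       reservoir = reservoir_state(),
                       dt = 1e-3,
                       t_end = 1,
                       sample_every = 100,
                       seed = 1,
                       noise = TRUE,
                       active = NULL,
                       gate = default_gate(),
                       log_flip_attempts = FALSE,
                       frame_every = 0,
                       frames_dir = NULL) {
  if (dt <= 0) stop("'dt' must be > 0")
  if (dt > turnover$tau_f)
    warning("dt > tau_f: attempt probabilities are capped at 1")
  if (is.null(active)) active <- mech$kappa_act > 0
  structure(list(mech = mech, turnover = turnover, reservoir = reservoir,
                 dt = dt, t_end = t_end, sample_every = sample_every,
                 seed = seed, noise = noise, active = active, gate = gate,
                 log_flip_attempts = log_flip_attempts,
                 frame_every = frame_every, frames_dir = frames_dir),
            class = "sim_config")
}

obs_colnames <- c("t", "N_t", "M_t", "area", "volume", "sphericity",
                  "U_cc", "U_volume", "U_area", "U_bending", "U_act",
                  "U_total", "cx", "cy", "cz", "mean_gaussian",
                  "flip_attempts", "flips", "turnover_attempts",
                  "splits", "merges")

event_colnames <- c("t", "kind", "v1", "v2", "delta", "mu_r", "accepted",
                    "angle", "strain")

# one observable row computed in R (used for the t = 0 record)
obs_row <- function(mesh, M_t, params, active, state) {
  g <- mesh_geometry(mesh)
  e <- membrane_energy(mesh, params, active)
  sph <- g$volume / ((4 / 3) * pi * (g$total_area / (4 * pi))^1.5)
  c(state$t, nrow(mesh$faces), M_t, g$total_area, g$volume, sph,
    e$U_cc, e$U_volume, e$U_area, e$U_bending, e$U_act, e$U_total,
    g$center[1], g$center[2], g$center[3],
    mean(g$angle_deficit / g$vertex_A),
    state$flip_att, state$flip_acc, state$turn_att, state$splits,
    state$merges)
}

ctrl_list <- function(config, steps, mechanics = TRUE, greedy = FALSE,
                      stop_tol = 0) {
  list(dt = config$dt, steps = as.integer(steps),
       sample_every = as.integer(config$sample_every),
       tau_f = config$turnover$tau_f, tau_t = config$turnover$tau_t,
       eps_t = config$turnover$eps_t, gamma_t = config$turnover$gamma_t,
       m_u = config$reservoir$m_u, M_eq = config$reservoir$M_eq,
       M_inst = config$reservoir$M_inst, M_tt = config$reservoir$M_tt,
       use_noise = isTRUE(config$noise), use_act = isTRUE(config$active),
       greedy = greedy, turnover_on = is.finite(config$turnover$tau_t),
       stop_tol = stop_tol, mechanics = mechanics,
       log_flip_attempts = isTRUE(config$log_flip_attempts),
       log_events = TRUE)
}

zero_state <- function(M_t) {
  list(t = 0, M_t = M_t, flip_att = 0, flip_acc = 0, turn_att = 0,
       splits = 0, merges = 0)
}

#' Run a membrane simulation
#'
#' Integrates the overdamped Langevin equation for the vertex positions and
#' interleaves one topological sweep per mechanical step: each edge is
#' attempted for a flip with probability \code{dt/tau_f} and for a turnover
#' move with probability \code{dt/tau_t}.  Identical seed and configuration
#' give a bit-identical event log and final mesh.
#'
#' @param config a [sim_config].
#' @param mesh starting [trimesh]; defaults to a generated, equilibrated
#'   vesicle with \code{M_eq / m_u} triangles.
#' @return Object of class \code{"dtv_sim"}: final \code{mesh},
#'   \code{observables} and \code{events} data frames, final
#'   \code{reservoir}, run \code{state} counters and the \code{config}.
#'   In the event log \code{accepted} is 1 for applied events, 0 for moves
#'   rejected by the Metropolis draw, and -1 for illegal moves; \code{angle}
#'   is the polar angle of the event site about the vesicle center and
#'   \code{strain} the area strain of the face pair.
#' @export
run_simulation <- function(config, mesh = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(mesh)) {
    nf <- round(config$reservoir$M_eq / config$reservoir$m_u)
    mesh <- generate_vesicle(nf, params = config$mech)
  }
  if (!mesh$closed) stop("simulation requires a closed mesh")
  res <- config$reservoir
  res$M_t <- nrow(mesh$faces) * res$m_u
  res$M_r <- res$M_tt - res$M_t

  steps <- max(1L, as.integer(round(config$t_end / config$dt)))
  state <- zero_state(res$M_t)
  obs <- list(obs_row(mesh, res$M_t, config$mech, config$active, state))
  events <- list()
  frames <- config$frame_every > 0 && !is.null(config$frames_dir)
  if (frames) dir.create(config$frames_dir, showWarnings = FALSE,
                         recursive = TRUE)
  chunk <- if (frames) config$frame_every else steps
  done <- 0L
  frame_id <- 0L
  P <- mesh$positions
  F <- mesh$faces
  if (frames) {
    write_mesh(mesh, file.path(config$frames_dir,
                               sprintf("frame_%06d.off", frame_id)))
  }
  while (done < steps) {
    n <- min(chunk, steps - done)
    out <- cpp_simulate(P, F, unclass(config$mech),
                        ctrl_list(config, n), config$gate, state)
    P <- out$positions
    F <- out$faces
    state <- out$state
    if (nrow(out$observables) > 0) obs <- c(obs, list(out$observables))
    if (nrow(out$events) > 0) events <- c(events, list(out$events))
    done <- done + n
    if (frames) {
      frame_id <- frame_id + 1L
      write_mesh(trimesh(P, F), file.path(config$frames_dir,
                                          sprintf("frame_%06d.off", frame_id)))
    }
  }
  res$M_t <- state$M_t
  res$M_r <- res$M_tt - res$M_t
  obs <- do.call(rbind, obs)
  colnames(obs) <- obs_colnames
  ev <- if (length(events)) do.call(rbind, events)
        else matrix(numeric(0), ncol = 9)
  colnames(ev) <- event_colnames
  ev <- as.data.frame(ev)
  if (nrow(ev)) ev$kind <- c("flip", "split", "merge")[ev$kind]
  structure(list(mesh = trimesh(P, F), observables = as.data.frame(obs),
                 events = ev, reservoir = res, state = state,
                 config = config),
            class = "dtv_sim")
}

#' @export
print.dtv_sim <- function(x, ...) {
  o <- x$observables
  cat(sprintf(
    "dtv_sim: t = %g, N_t %d -> %d, area %.1f -> %.1f, M_t = %d (M_tt = %d)\n",
    x$state$t, o$N_t[1], nrow(x$mesh$faces), o$area[1],
    o$area[nrow(o)], x$reservoir$M_t, x$reservoir$M_tt))
  cat(sprintf("  events: %d flips, %d splits, %d merges\n",
              x$state$flip_acc, x$state$splits, x$state$merges))
  invisible(x)
}

#' Single Euler--Maruyama step
#'
#' \eqn{r_i \leftarrow r_i + (\Delta t/\eta)(F_i) + w}, with per-component
#' displacement noise of variance \eqn{2 k_B T \Delta t/\eta} (the
#' discretization of delta-correlated thermal noise).
#'
#' @param mesh a [trimesh].
#' @param params a [mech_params].
#' @param dt time step.
#' @param noise include thermal noise.
#' @param active include the active energy term.
#' @return The mesh with updated positions.
#' @export
langevin_step <- function(mesh, params = mech_params(), dt = 1e-3,
                          noise = TRUE, active = NULL) {
  f <- membrane_forces(mesh, params, active)
  p <- mesh$positions + (dt / params$eta) * f
  if (noise && params$k_BT > 0) {
    p <- p + matrix(rnorm(length(p), sd = sqrt(2 * params$k_BT * dt /
                                                 params$eta)),
                    ncol = 3)
  }
  if (!all(is.finite(p))) stop("langevin_step produced non-finite positions")
  mesh$positions <- p
  mesh
}

#' One topological sweep without mechanics
#'
#' Iterates the edges in random order and performs flip attempts followed by
#' turnover attempts, exactly as inside [run_simulation()], but with the
#' vertex positions frozen.
#'
#' @param mesh a closed [trimesh].
#' @param reservoir a [reservoir_state].
#' @param mech a [mech_params].
#' @param turnover a [turnover_params].
#' @param dt time step used for the attempt probabilities.
#' @param gate quality-gate thresholds.
#' @param active include the active term in flip energetics.
#' @return List: \code{mesh}, updated \code{reservoir}, \code{events}
#'   data frame, \code{state} counters.
#' @export
topology_sweep <- function(mesh, reservoir = reservoir_state(),
                           mech = mech_params(),
                           turnover = turnover_params(), dt = 1e-3,
                           gate = default_gate(), active = FALSE) {
  cfg <- sim_config(mech = mech, turnover = turnover, reservoir = reservoir,
                    dt = dt, t_end = dt, sample_every = 0, seed = NULL,
                    noise = FALSE, active = active, gate = gate,
                    log_flip_attempts = TRUE)
  state <- zero_state(nrow(mesh$faces) * reservoir$m_u)
  out <- cpp_simulate(mesh$positions, mesh$faces, unclass(mech),
                      ctrl_list(cfg, 1, mechanics = FALSE), gate, state)
  reservoir$M_t <- out$state$M_t
  reservoir$M_r <- reservoir$M_tt - reservoir$M_t
  ev <- out$events
  colnames(ev) <- event_colnames
  ev <- as.data.frame(ev)
  if (nrow(ev)) ev$kind <- c("flip", "split", "merge")[ev$kind]
  list(mesh = trimesh(out$positions, out$faces), reservoir = reservoir,
       events = ev, state = out$state)
}
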