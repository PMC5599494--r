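# Thermodynamics of fluidity and turnover: acceptance probabilities for
# edge flips (canonical ensemble) and for triangle-pair splits/merges
# (grand-canonical, coupled to the molecule reservoir).

#' Chemical potential of the molecule reservoir
#'
#' The reservoir Gibbs free energy is the cubic
#' \deqn{G_r = \frac{k_B T}{12 m_u M_{inst}^2} |M_t - M_{eq}|^3,}
#' so the chemical potential \eqn{\mu_r = -\partial G_r/\partial M_t} is
#' \deqn{\mu_r = -\frac{k_B T}{4 m_u M_{inst}^2} (M_t - M_{eq})|M_t - M_{eq}|.}
#' It vanishes at equilibrium, is odd about \eqn{M_{eq}}, and biases splits
#' when the vesicle holds too few molecules and merges when it holds too many.
#'
#' @param reservoir a [reservoir_state].
#' @param k_BT thermal energy.
#' @return Scalar \eqn{\mu_r} (energy per molecule).
#' @examples
#' r <- reservoir_state(M_eq = 1000, M_inst = 100, M_t = 1100)
#' chemical_potential(r)  # -k_BT/4
#' @export
chemical_potential <- function(reservoir, k_BT = 1) {
  x <- reservoir$M_t - reservoir$M_eq
  -(k_BT / (4 * reservoir$m_u * reservoir$M_inst^2)) * x * abs(x)
}

#' Reservoir Gibbs free energy
#'
#' @inheritParams chemical_potential
#' @param M_t vesicle molecule count at which to evaluate (defaults to the
#'   current state).
#' @return Scalar free energy.
#' @export
reservoir_free_energy <- function(reservoir, M_t = reservoir$M_t, k_BT = 1) {
  (k_BT / (12 * reservoir$m_u * reservoir$M_inst^2)) *
    abs(M_t - reservoir$M_eq)^3
}

#' Energetic cost of a turnover event
#'
#' \deqn{\Delta_i E = \epsilon_t \{1 \mp \frac{1}{\gamma_t}
#'   (\langle a_i\rangle/a_{eq} - 1)\},}
#' minus for splitting and plus for merging: stretching beyond the critical
#' strain \eqn{\gamma_t} makes splitting energetically favorable
#' (\eqn{\Delta_i E < 0}) and compression favors merging.
#'
#' @param mean_area \eqn{\langle a_i\rangle}, the average area of the two
#'   triangles adjacent to the edge (the pre-event pair for both directions).
#' @param a_eq equilibrium triangle area.
#' @param eps_t energetic cost at zero strain.
#' @param gamma_t critical strain.
#' @param direction \code{"split"} or \code{"merge"}.
#' @return Scalar energy cost (may be negative).
#' @export
turnover_cost <- function(mean_area, a_eq = 1, eps_t = 0.1, gamma_t = 0.05,
                          direction = c("split", "merge")) {
  direction <- match.arg(direction)
  stopifnot(mean_area > 0)
  strain <- mean_area / a_eq - 1
  sgn <- if (direction == "split") -1 else 1
  eps_t * (1 + sgn * strain / gamma_t)
}

#' Flip attempt-and-accept probability per mechanical step
#'
#' Realizes the flip rate \eqn{P_{fi} = \tau_f^{-1}\exp(-\Delta_i U/k_BT)}
#' by attempting each edge with probability \eqn{\Delta t/\tau_f} per step
#' and accepting with the Metropolis factor
#' \eqn{\min(1, \exp(-\Delta_i U/k_BT))}.
#'
#' @param delta_U energy gap of the flip.
#' @param tau_f fluidity timescale (Inf disables flips).
#' @param dt mechanical time step; must satisfy \code{dt <= tau_f}.
#' @param k_BT thermal energy.
#' @return List with \code{attempt} and \code{accept} probabilities and their
#'   product \code{prob}.
#' @export
flip_acceptance <- function(delta_U, tau_f, dt, k_BT = 1) {
  if (is.infinite(tau_f)) {
    return(list(attempt = 0, accept = 0, prob = 0))
  }
  if (dt > tau_f) {
    warning("dt > tau_f: attempt probability capped at 1; ",
            "the realized flip rate underestimates 1/tau_f")
  }
  attempt <- min(1, dt / tau_f)
  accept <- min(1, exp(-delta_U / k_BT))
  list(attempt = attempt, accept = accept, prob = attempt * accept)
}

#' Turnover attempt-and-accept probability per mechanical step
#'
#' Each edge is attempted with probability \eqn{\Delta t/\tau_t}; the
#' direction (split or merge) is drawn uniformly; the move is accepted with
#' \eqn{\min(1, \exp(-(\Delta_i E \mp 2 m_u \mu_r)/k_BT))} (minus for
#' splitting, plus for merging; the factor 2 counts the transformed
#' triangles).  On acceptance, 2\eqn{m_u} molecules transfer between vesicle
#' and reservoir.
#'
#' @param delta_E turnover cost from [turnover_cost()].
#' @param mu_r reservoir chemical potential from [chemical_potential()].
#' @param m_u molecules per triangle.
#' @param tau_t turnover timescale (Inf disables turnover entirely).
#' @param dt mechanical time step.
#' @param direction \code{"split"} or \code{"merge"}.
#' @param k_BT thermal energy.
#' @return List with \code{attempt}, \code{direction_prob} (1/2),
#'   \code{accept} and the overall per-step \code{prob}.
#' @export
turnover_acceptance <- function(delta_E, mu_r, m_u = 1, tau_t = 1, dt = 1e-3,
                                direction = c("split", "merge"), k_BT = 1) {
  direction <- match.arg(direction)
  if (is.infinite(tau_t)) {
    return(list(attempt = 0, direction_prob = 0.5, accept = 0, prob = 0))
  }
  if (dt > tau_t) warning("dt > tau_t: attempt probability capped at 1")
  attempt <- min(1, dt / tau_t)
  sgn <- if (direction == "split") -1 else 1
  accept <- min(1, exp(-(delta_E + sgn * 2 * m_u * mu_r) / k_BT))
  list(attempt = attempt, direction_prob = 0.5, accept = accept,
       prob = attempt * 0.5 * accept)
}

# apply a turnover event's molecule transfer to the reservoir
reservoir_transfer <- function(reservoir, direction) {
  d <- if (direction == "split") 2 * reservoir$m_u else -2 * reservoir$m_u
  reservoir$M_t <- reservoir$M_t + d
  reservoir$M_r <- reservoir$M_tt - reservoir$M_t
  reservoir
}
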