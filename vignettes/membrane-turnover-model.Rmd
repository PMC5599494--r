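---
title: "A dynamically triangulated membrane model with molecular turnover"
author: "dtvesicle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamically triangulated membrane model with molecular turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtvesicle)
```

## The model

`dtvesicle` simulates a closed cellular membrane (a vesicle) as a
dynamically triangulated surface.  Each triangle stands for a patch of
membrane containing a fixed number `m_u` of molecules, so the triangle count
`N_t` doubles as a molecule count `M_t = N_t * m_u`.  The model couples
three layers of dynamics:

1. **Mechanics.**  Vertex positions $r_i$ follow the overdamped Langevin
   equation $\eta\,\dot r_i = -\nabla U + w_i$ with delta-correlated Gaussian
   noise, $\langle w_i(t)\otimes w_j(t')\rangle = 2\eta k_BT\,
   \delta_{ij}\delta(t-t')\,\mathbf{1}$.  The energy is
   $U = U_{cc} + U_{eff} + U_{act}$ with

   * a short-range vertex-pair repulsion
     $U_{cc} = \sum_{i<j} \tfrac{K_r}{2}(l_{ij}/l_{rep}-1)^2\,
     [l_{ij} < l_{rep}]$ that maintains a discrete mesh scale,
   * volume elasticity $\tfrac{K_v}{2}(v/v_{eq}-1)^2$,
     per-triangle surface elasticity
     $\sum_i \tfrac{K_a}{2}(a_i/a_{eq}-1)^2$, and the discrete bending
     energy $\sum_i 2K_c\,M_i^2/A_i$ built from the total mean curvature
     $M_i = \sum_j l_j\theta_j/4$ and vertex area $A_i = \sum_j a_j/3$
     around each vertex,
   * an optional polarized active tension
     $U_{act} = \sum_i \tfrac{\kappa_{act}}{2}(1+\cos\phi_i)\,a_i$, where
     $\phi_i$ is the angle between the $+x$ axis and the vector from the
     vesicle center to the face centroid, held constant within a time step.

2. **Fluidity.**  In-plane lipid rearrangement is modelled by edge flips.
   Per mechanical step each edge is attempted with probability
   $\Delta t/\tau_f$ and accepted with the Metropolis factor
   $\min(1, e^{-\Delta_i U/k_BT})$, realizing the flip rate
   $\tau_f^{-1} e^{-\Delta_i U/k_BT}$.  Flips conserve every count; they
   only exchange the diagonal of a triangle pair.

3. **Turnover.**  Exchange of molecules with an implicit intracellular
   reservoir is modelled by splitting a triangle pair (insert the midpoint
   vertex of the shared edge; $+2$ faces) or merging it (collapse the edge
   to its midpoint; $-2$ faces).  Each edge is attempted with probability
   $\Delta t/\tau_t$, the direction is a fair coin, and the move is accepted
   with $\min(1, e^{-(\Delta_i E \mp 2 m_u \mu_r)/k_BT})$ (minus for
   splitting).  The cost is linear in the local area strain,
   $\Delta_i E = \epsilon_t\{1 \mp (\langle a_i\rangle/a_{eq}-1)/\gamma_t\}$,
   evaluated on the pre-event pair of faces for both directions, so
   stretched membrane splits cheaply and compressed membrane merges cheaply.
   The reservoir enters through the grand-canonical chemical potential of a
   cubic free energy,
   $\mu_r = -\tfrac{k_BT}{4 m_u M_{inst}^2}(M_t-M_{eq})|M_t-M_{eq}|$,
   which restores the molecule count toward $M_{eq}$ on the scale
   $M_{inst}$.  Accepted events transfer $2m_u$ molecules, conserving
   $M_{tt} = M_t + M_r$ to the integer.

Model units: length $l = \sqrt{a_{eq}}$, energy $k_BT$, and time
$\tau = 0.1\,\eta\,a_{eq}/k_BT$.  Setting $l = \tau = k_BT = 1$ forces
$\eta = 10$, which is baked into the defaults.

## Default parameters

| symbol | default | meaning |
|---|---|---|
| `K_v` | $10^4$ | volume elasticity |
| `K_a` | 50 | surface elasticity per triangle |
| `K_c` | 1–10 (default 10) | bending rigidity |
| `kappa_act` | 0 (1–3 when active) | active surface tension amplitude |
| `v_eq` | 2527 | equilibrium volume (area $1000\,a_{eq}$, sphericity 0.85) |
| `K_r` | $10^3$ | repulsive modulus |
| `l_rep` | $0.5\sqrt{4 a_{eq}/\sqrt3} \approx 0.76$ | repulsive distance |
| `tau_f` | $10^{-2}$ | fluidity timescale |
| `tau_t` | 1 or $\infty$ | turnover timescale |
| `eps_t` | 0.1 | turnover cost at zero strain |
| `gamma_t` | 0.05 | critical strain |
| `M_eq` | $10^3$ | equilibrium vesicle molecules |
| `M_inst` | 10–$10^3$ | molecule-number instability |
| `dt` | $10^{-3}$ | integration step |

`l_rep` is half the edge length of the equilateral triangle of area
`a_eq`: it sits below the minimum vertex spacing of every regular-polygon
fan of such triangles, so equilibrium packings are repulsion-free.  It is a
configuration key, as are the quality-gate thresholds below.

`M_tt` defaults to `2 * M_eq`, making vesicle and reservoir comparable
pools; splits additionally require `M_r >= 2 m_u` so the reservoir count
can never go negative.

## Numerical choices

* **Integrator.**  Explicit Euler–Maruyama with displacement noise of
  per-component variance $2 k_BT \Delta t/\eta$.  One topological sweep runs
  after every mechanical step; with the default $\Delta t/\tau_f = 0.1$ the
  per-edge attempt probabilities stay well below 1.
* **Forces.**  All gradients are analytic (standard closed forms for area,
  volume and dihedral-angle derivatives), vectorized in C++; the test suite
  checks every term against central finite differences at relative
  $10^{-5}$.  The active-term angle $\phi_i$ is frozen during
  differentiation, which is what makes $U$ non-conservative and the model
  capable of sustained migration.
* **Repulsion.**  The all-pairs sum is short-ranged by construction and is
  evaluated with a uniform spatial hash of cell size `l_rep`; tests compare
  it against the $O(n^2)$ double loop.
* **Flip energetics.**  $\Delta_i U$ for a flip is evaluated on the local
  stencil (the two faces, five edges and four vertices whose geometry
  changes), using a running total for the volume term.  A test asserts
  equality with global recomputation at $10^{-9}$.  Because a merge moves
  vertices (and so touches the repulsion term non-locally), trial deltas
  for splits and merges are computed by applying the move to a copy and
  recomputing; in the simulation loop turnover acceptance uses only
  $\Delta_i E$ and $\mu_r$, never the mechanical gap.
* **Quality gate.**  Any event that would create a face with minimum angle
  below 5 degrees, or a vertex valence outside $[3, 12]$, or (for merges)
  fewer than 8 faces, is rejected; a rejected event leaves the mesh
  bit-identical.  Merges additionally require the link condition — the edge
  endpoints share exactly the two opposite vertices — so the surface stays
  a closed orientable 2-manifold.  The valence floor applies to interior
  vertices; boundary vertices occur only in open test patches.
* **Determinism.**  All randomness flows through R's RNG; a seed plus a
  configuration reproduces the event log and final mesh bit-exactly.
* **Degenerate inputs.**  Zero-area faces, non-manifold edges, inconsistent
  winding and duplicate faces are rejected at construction with distinct
  error classes; a consistently inward-oriented closed mesh is repaired by
  a global orientation flip.

## The initial vesicle

`generate_vesicle(F)` places $F/2+2$ points on the unit sphere as a
Fibonacci lattice and triangulates them by their convex hull, which for
points in convex position has exactly $2V-4$ faces — this is how an exact
face count (e.g. the standard 1000-triangle initial state, hence 502
vertices and 1500 edges) is guaranteed, where icosphere subdivision could
not hit it.  The mesh is scaled to total area $F a_{eq}$ and equilibrated at
$K_c = 10$ with turnover off, by noiseless gradient descent interleaved with
greedy edge flips, until the energy change per step falls below `tol`
(default $10^{-6}$; both the tolerance and the step cap are arguments).

Two practical notes on this equilibration.  First, the descent step used by
the generator is $5\times10^{-3}$, five times the simulation default: with
noise off the scheme remains stable and the relaxation, whose slowest mode
is the deflation of the sphere toward sphericity 0.85 at constant area, is
correspondingly faster.  Second, that deflation is a buckling transition:
a perfectly spherical start can linger near the symmetric state, and the
residual volume pressure then compresses the triangles by a few percent.
At 320 faces the descent buckles and reaches the target area within 1%;
at 1000 faces the approach is slower and a few-percent area deficit can
remain within the default step budget.  The face-count, manifoldness and
Euler-characteristic guarantees are exact regardless, since they are fixed
by the hull construction.

## What the simulations show

With turnover disabled ($\tau_t = \infty$) the triangle and molecule counts
are constants of motion and the vesicle fluctuates at essentially constant
area.  With turnover enabled, the strain coupling in $\Delta_i E$ biases
events: low bending rigidity lets thermal fluctuations stretch the
membrane, favoring splits and growth; high rigidity compresses it, favoring
merges — reproducing the inverse relation between final molecule count and
$K_c$.  With the polarized active tension on, the front of the vesicle (the
$+x$ side, where tension is high) compresses and merges while the rear
stretches and splits; the resulting directional molecule transport moves
the vesicle along the $x$ axis even though the active force is internal.
Without turnover the same tension only deforms the vesicle slightly.  The
package's acceptance tests reproduce these regimes on scaled-down systems
(320 faces, $10^4$ steps, a few seeds); the problem sizes are chosen so the
whole suite runs in minutes while leaving the qualitative contrasts —
drift versus growth, monotonicity in $K_c$, migration with versus without
turnover — unambiguous.

## What the generator does and does not emulate

The synthetic initial condition is an equilibrated, homogeneous,
genus-0 vesicle.  It does not emulate membrane heterogeneity (spatially
varying rigidity or tension), osmotic pressure, explicit proteins or
trafficking intermediates, hydrodynamic interactions, or self-contact;
the repulsion term is the only excluded-volume mechanism, and
self-intersection is not detected.  Passing tests therefore speak to the
model's internal consistency and to the qualitative regimes above, not to
quantitative agreement with any particular experimental membrane.

## Timescale contract

The model assumes local fluidity is much faster than local turnover
($\tau_f \ll \tau_t$); constructing `turnover_params` with the ordering
violated warns but does not stop, since short diagnostic runs outside the
contract are legitimate.  The scheduling also caps per-step attempt
probabilities at 1, with a warning, when $\Delta t$ exceeds a timescale.

## Known limitations

* The flip/turnover sweep visits a snapshot of the edge list; edges created
  within a sweep become eligible the next step.  At the default
  $\Delta t/\tau$ ratios this bias is negligible.
* Sphericity is reported as $v / [\tfrac43\pi(A/4\pi)^{3/2}]$; for strongly
  lobed shapes it is a summary, not a shape descriptor.
* The event log records the polar angle of the event site about the
  area-weighted centroid; for vesicles that migrate far during a window the
  angle mixes translation and shape change.
* Whether the discrete per-vertex active forces sum exactly to zero is
  logged as a diagnostic, not asserted: the physical claim of internal
  force balance is about the continuum limit, not the discretization.
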