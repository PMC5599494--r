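# Independent oracles and shared fixtures for the test suite.

# central finite differences of the total energy; the active-term weights are
# frozen at the unperturbed configuration, matching the model's definition of
# the active force (phi is a constant per time step)
fd_forces <- function(mesh, params, active = FALSE, h = 1e-6) {
  w <- NULL
  if (active) {
    g0 <- mesh_geometry(mesh)
    d <- sweep(g0$face_centroid, 2, g0$center)
    w <- params$kappa_act * (1 + d[, 1] / sqrt(rowSums(d^2))) / 2
  }
  energy_at <- function(pos) {
    mesh$positions <- pos
    u <- membrane_energy(mesh, params, active = FALSE)$U_total
    if (active) u <- u + sum(w * mesh_geometry(mesh)$face_area)
    u
  }
  p0 <- mesh$positions
  g <- matrix(0, nrow(p0), 3)
  for (i in seq_len(nrow(p0))) {
    for (k in 1:3) {
      pp <- p0
      pp[i, k] <- pp[i, k] + h
      up <- energy_at(pp)
      pp[i, k] <- pp[i, k] - 2 * h
      um <- energy_at(pp)
      g[i, k] <- -(up - um) / (2 * h)
    }
  }
  g
}

# O(n^2) double-loop repulsion oracle
brute_repulsion <- function(pos, K_r, l_rep) {
  u <- 0
  n <- nrow(pos)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      l <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (l < l_rep) u <- u + K_r / 2 * (l / l_rep - 1)^2
    }
  }
  u
}

# icosphere with a reproducible random perturbation of the vertex positions
perturbed_icosphere <- function(subdivisions = 1, radius = 2, sd = 0.02,
                                seed = 42) {
  set.seed(seed)
  m <- mesh_icosphere(subdivisions, radius = radius)
  m$positions <- m$positions +
    matrix(rnorm(length(m$positions), sd = sd), ncol = 3)
  m
}

# asserts all structural invariants of a closed genus-0 mesh
expect_closed_invariants <- function(mesh, tol = 1e-9) {
  nv <- nrow(mesh$positions)
  ne <- nrow(mesh_edges(mesh))
  nf <- nrow(mesh$faces)
  expect_identical(nv - ne + nf, 2L)
  expect_identical(2L * ne, 3L * nf)
  expect_true(validate_mesh(mesh, tol = tol))
}

# expensive fixtures built once per test run
.cache <- new.env(parent = emptyenv())

cached_vesicle <- function(faces = 320, seed = 1) {
  key <- sprintf("vesicle_%d_%d", faces, seed)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- generate_vesicle(faces, seed = seed)
  }
  .cache[[key]]
}
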