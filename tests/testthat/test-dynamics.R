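free_params <- function() {
  mech_params(K_v = 0, K_a = 0, K_c = 0, K_r = 0, kappa_act = 0)
}

test_that("the integrator is exact for zero force at zero temperature", {
  m <- mesh_tetrahedron()
  p <- free_params()
  p$k_BT <- 0
  m2 <- langevin_step(m, p, dt = 1e-2, noise = TRUE)
  expect_identical(m2$positions, m$positions)
})

test_that("free diffusion reproduces the Brownian mean-square displacement", {
  # per component and step: Var = 2 kBT dt / eta
  set.seed(21)
  p <- free_params()  # kBT = 1, eta = 10
  dt <- 1e-3
  m <- mesh_tetrahedron()
  steps <- 2000
  incr <- matrix(NA_real_, steps, 12)
  for (s in seq_len(steps)) {
    m2 <- langevin_step(m, p, dt = dt)
    incr[s, ] <- as.numeric(m2$positions - m$positions)
    m <- m2
  }
  v <- var(as.numeric(incr))
  expected <- 2 * p$k_BT * dt / p$eta
  n <- length(incr)
  # 3-sigma band for a chi^2_{n-1} sample variance
  expect_lt(abs(v / expected - 1), 3 * sqrt(2 / (n - 1)))
})

test_that("runs are bit-reproducible from the seed", {
  m <- mesh_icosphere(1, radius = sqrt(80 / (4 * pi)))
  cfg <- sim_config(
    mech = mech_params(K_c = 3, v_eq = equilibrium_volume(80, 0.85)),
    turnover = turnover_params(tau_t = 0.5),
    reservoir = reservoir_state(M_eq = 80, M_inst = 100, M_tt = 400),
    t_end = 0.1, sample_every = 20, seed = 31)
  s1 <- run_simulation(cfg, m)
  s2 <- run_simulation(cfg, m)
  expect_identical(s1$observables, s2$observables)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$mesh$positions, s2$mesh$positions)
  expect_identical(s1$mesh$faces, s2$mesh$faces)
})

test_that("without turnover N_t and M_t are constants of motion", {
  m <- mesh_icosphere(1, radius = sqrt(80 / (4 * pi)))
  cfg <- sim_config(
    mech = mech_params(K_c = 3, v_eq = equilibrium_volume(80, 0.85)),
    turnover = turnover_params(tau_t = Inf),
    reservoir = reservoir_state(M_eq = 80, M_tt = 160),
    t_end = 0.2, sample_every = 20, seed = 41)
  sim <- run_simulation(cfg, m)
  expect_true(all(sim$observables$N_t == 80))
  expect_true(all(sim$observables$M_t == 80))
  expect_identical(sim$state$splits + sim$state$merges, 0)
  expect_gt(sim$state$flip_acc, 0)  # fluidity stays active
})

test_that("the sweep is a no-op when both timescales are infinite", {
  m <- mesh_icosphere(1)
  sw <- suppressWarnings(topology_sweep(
    m, turnover = turnover_params(tau_f = Inf, tau_t = Inf)))
  expect_identical(sw$mesh$faces, m$faces)
  expect_identical(sw$state$flip_att + sw$state$turn_att, 0)
  expect_identical(nrow(sw$events), 0L)
})

test_that("flip attempts scale linearly with dt/tau_f", {
  m <- mesh_icosphere(1, radius = sqrt(80 / (4 * pi)))
  run_with_tau <- function(tau_f, seed) {
    cfg <- sim_config(
      mech = mech_params(K_c = 3, v_eq = equilibrium_volume(80, 0.85)),
      turnover = turnover_params(tau_f = tau_f, tau_t = Inf),
      reservoir = reservoir_state(M_eq = 80, M_tt = 160),
      t_end = 0.5, sample_every = 0, seed = seed)
    run_simulation(cfg, m)$state$flip_att
  }
  n1 <- run_with_tau(2e-2, 51)   # expected  E * steps * dt/tau_f
  n2 <- run_with_tau(1e-2, 52)
  # each is Binomial(120 * 500, p); compare to the expected 2x ratio
  exp1 <- 120 * 500 * 1e-3 / 2e-2
  exp2 <- 2 * exp1
  expect_lt(abs(n1 - exp1), 3 * sqrt(exp1))
  expect_lt(abs(n2 - exp2), 3 * sqrt(exp2))
})

test_that("edge-order randomization leaves flip statistics seed-consistent", {
  m <- mesh_icosphere(1, radius = sqrt(80 / (4 * pi)))
  rates <- vapply(c(61, 62, 63), function(seed) {
    cfg <- sim_config(
      mech = mech_params(K_c = 3, v_eq = equilibrium_volume(80, 0.85)),
      turnover = turnover_params(tau_t = Inf),
      reservoir = reservoir_state(M_eq = 80, M_tt = 160),
      t_end = 0.3, sample_every = 0, seed = seed)
    s <- run_simulation(cfg, m)
    s$state$flip_acc / s$state$flip_att
  }, numeric(1))
  # acceptance fractions from independent seeds agree within a 3-sigma
  # binomial band around their mean
  pm <- mean(rates)
  n_att <- 120 * 300 * 0.1
  expect_true(all(abs(rates - pm) < 3 * sqrt(pm * (1 - pm) / n_att) + 0.02))
})

test_that("numerical blow-up aborts with a diagnostic", {
  m <- mesh_icosphere(1)
  cfg <- suppressWarnings(sim_config(
    mech = mech_params(K_v = 1e8, v_eq = 1, K_c = 0),
    turnover = turnover_params(tau_t = Inf),
    reservoir = reservoir_state(M_eq = 80, M_tt = 160),
    dt = 10, t_end = 1000, sample_every = 0, seed = 71))
  expect_error(suppressWarnings(run_simulation(cfg, m)), "unstable")
})

test_that("observables and the event log are internally consistent", {
  m <- mesh_icosphere(2)
  m$positions <- m$positions * sqrt(320 / mesh_geometry(m)$total_area)
  cfg <- sim_config(
    mech = mech_params(K_c = 3, v_eq = equilibrium_volume(320, 0.85)),
    turnover = turnover_params(tau_t = 0.2),
    reservoir = reservoir_state(M_eq = 320, M_inst = 1000, M_tt = 640),
    t_end = 0.2, sample_every = 40, seed = 81, log_flip_attempts = TRUE)
  sim <- run_simulation(cfg, m)
  o <- sim$observables
  # recorded area equals the geometry of the final mesh at the last sample
  g <- mesh_geometry(sim$mesh)
  expect_equal(o$area[nrow(o)], g$total_area, tolerance = 1e-9)
  expect_identical(o$N_t[nrow(o)], as.numeric(nrow(sim$mesh$faces)))
  expect_true(all(diff(o$flip_attempts) >= 0))
  expect_true(all(o$sphericity > 0 & o$sphericity <= 1))
  expect_equal(o$U_total, o$U_cc + o$U_volume + o$U_area + o$U_bending +
                 o$U_act, tolerance = 1e-9)
  # event log totals match the counters
  ev <- sim$events
  expect_identical(sum(ev$kind == "split" & ev$accepted == 1),
                   as.integer(sim$state$splits))
  expect_identical(sum(ev$kind == "merge" & ev$accepted == 1),
                   as.integer(sim$state$merges))
  expect_identical(sum(ev$kind == "flip"),
                   as.integer(sim$state$flip_att))
  expect_true(all(ev$angle >= 0 & ev$angle <= pi, na.rm = TRUE))
})
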