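test_that("all fixture meshes pass the full invariant suite", {
  for (m in list(mesh_tetrahedron(), mesh_octahedron(), mesh_icosahedron(),
                 mesh_icosphere(2))) {
    expect_closed_invariants(m)
  }
})

test_that("the generator hits the exact face count", {
  v20 <- generate_vesicle(20, seed = 1, max_steps = 500)
  expect_identical(nrow(v20$faces), 20L)
  expect_identical(nrow(v20$positions), 12L)  # icosahedron-equivalent
  expect_closed_invariants(v20)

  v128 <- generate_vesicle(128, seed = 1, max_steps = 3000)
  expect_identical(nrow(v128$faces), 128L)
  expect_identical(nrow(v128$positions), 66L)
  expect_identical(nrow(mesh_edges(v128)), 192L)
  expect_closed_invariants(v128)

  expect_error(generate_vesicle(21), "even")
  expect_error(generate_vesicle(10), "even integer >= 20")
})

test_that("OFF and PLY round-trips are exact", {
  m <- perturbed_icosphere(1)
  for (fmt in c("off", "ply")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_mesh(m, path)
    back <- read_mesh(path)
    expect_identical(back$faces, m$faces)
    expect_equal(back$positions, m$positions, tolerance = 0)
    unlink(path)
  }
})

test_that("malformed mesh files raise parse errors naming the line", {
  p1 <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 1"), p1)  # face line too short
  err <- tryCatch(read_mesh(p1), error = function(e) e)
  expect_s3_class(err, "dtv_parse_error")
  expect_match(conditionMessage(err), ":7:")

  p2 <- tempfile(fileext = ".off")
  writeLines(c("not-off", "1 2 3"), p2)
  expect_error(read_mesh(p2), class = "dtv_parse_error")

  # a structurally non-manifold file surfaces the validation error
  p3 <- tempfile(fileext = ".off")
  writeLines(c("OFF", "5 3 0", "0 0 0", "1 0 0", "0 1 0", "0 0 1", "1 1 1",
               "3 0 1 2", "3 1 0 3", "3 1 0 4"), p3)
  expect_error(read_mesh(p3, closed = FALSE), class = "dtv_nonmanifold")
  unlink(c(p1, p2, p3))
})

test_that("vesicle round-trip preserves connectivity bit-exactly", {
  v <- generate_vesicle(64, seed = 2, max_steps = 1000)
  path <- tempfile(fileext = ".off")
  write_mesh(v, path)
  expect_identical(read_mesh(path)$faces, v$faces)
  unlink(path)
})

test_that("configuration files round-trip through parse and serialize", {
  cfg <- config_from_keys(list(K_c = 3, tau_t = 1, M_inst = 500, faces = 320,
                               t_end = 2.5, seed = 9))
  path <- tempfile(fileext = ".yml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(unclass(cfg2$mech), unclass(cfg$mech))
  expect_equal(unclass(cfg2$turnover), unclass(cfg$turnover))
  expect_equal(cfg2$reservoir$M_inst, 500)
  expect_equal(cfg2$t_end, 2.5)
  expect_identical(attr(cfg2, "extra"), attr(cfg, "extra"))
  # tau_t = Inf survives the YAML round trip
  cfgInf <- config_from_keys(list(tau_t = Inf))
  write_config(cfgInf, path)
  expect_identical(read_config(path)$turnover$tau_t, Inf)
  unlink(path)
})

test_that("the CLI composes generate, validate and reproducible runs", {
  wd <- tempfile()
  dir.create(wd)
  mesh_path <- file.path(wd, "v.off")
  expect_identical(dtv_cli(c("generate", "--faces", "64", "--seed", "3",
                             "--out", mesh_path)), 0L)
  expect_identical(dtv_cli(c("validate", "--mesh", mesh_path)), 0L)

  run_once <- function(out) {
    dtv_cli(c("run", "--mesh", mesh_path, "--out", out,
              "--faces", "64", "--meq", "64", "--mtt", "128",
              "--veq", as.character(equilibrium_volume(64, 0.85)),
              "--kc", "3", "--tau-t", "0.5", "--t-end", "0.05",
              "--seed", "5"))
  }
  expect_identical(run_once(file.path(wd, "r1")), 0L)
  expect_identical(run_once(file.path(wd, "r2")), 0L)
  o1 <- readLines(file.path(wd, "r1", "observables.tsv"))
  o2 <- readLines(file.path(wd, "r2", "observables.tsv"))
  expect_identical(o1, o2)
  e1 <- readLines(file.path(wd, "r1", "events.tsv"))
  expect_identical(e1, readLines(file.path(wd, "r2", "events.tsv")))

  # tau_t = inf from the command line: turnover fully disabled
  expect_identical(dtv_cli(c("run", "--mesh", mesh_path,
                             "--out", file.path(wd, "r3"),
                             "--meq", "64", "--mtt", "128",
                             "--veq", as.character(equilibrium_volume(64, 0.85)),
                             "--tau-t", "inf", "--t-end", "0.05",
                             "--seed", "5")), 0L)
  ev <- read.table(file.path(wd, "r3", "events.tsv"), header = TRUE,
                   sep = "\t")
  expect_false(any(ev$kind %in% c("split", "merge")))

  # frames + observe subcommand
  # (reuses the final mesh as a single frame)
  dir.create(file.path(wd, "frames"))
  file.copy(file.path(wd, "r1", "final.off"),
            file.path(wd, "frames", "frame_0.off"))
  expect_identical(dtv_cli(c("observe", "--frames", file.path(wd, "frames"),
                             "--out", file.path(wd, "obs.tsv"))), 0L)
  expect_true(file.exists(file.path(wd, "obs.tsv")))

  # unknown keys and bad values are usage errors
  expect_identical(dtv_cli(c("run", "--bogus", "1")), 1L)
  expect_identical(dtv_cli(c("run", "--kc", "not-a-number")), 1L)
  expect_identical(dtv_cli(character(0)), 1L)
  unlink(wd, recursive = TRUE)
})

test_that("checkpoints restore mesh and reservoir state exactly", {
  m <- mesh_icosphere(1, radius = sqrt(80 / (4 * pi)))
  cfg <- sim_config(
    mech = mech_params(K_c = 3, v_eq = equilibrium_volume(80, 0.85)),
    turnover = turnover_params(tau_t = 0.5),
    reservoir = reservoir_state(M_eq = 80, M_inst = 100, M_tt = 400),
    t_end = 0.05, sample_every = 10, seed = 91)
  sim <- run_simulation(cfg, m)
  path <- tempfile(fileext = ".json")
  write_checkpoint(sim, path)
  ck <- read_checkpoint(path)
  expect_equal(ck$mesh$positions, sim$mesh$positions, tolerance = 1e-12)
  expect_identical(ck$mesh$faces, sim$mesh$faces)
  expect_equal(ck$reservoir$M_t, sim$reservoir$M_t)
  expect_equal(ck$state$t, sim$state$t, tolerance = 1e-12)
  unlink(path)
})
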