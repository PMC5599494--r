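test_that("edge flip exchanges the diagonal and is an involution", {
  quad <- mesh_planar_quad()  # faces (1,2,3), (1,3,4); diagonal 1-3
  flipped <- flip_edge(quad, c(1, 3))
  expect_identical(nrow(flipped$faces), 2L)
  expect_identical(nrow(flipped$positions), 4L)
  e <- mesh_edges(flipped)
  expect_true(any(e[, 1] == 2 & e[, 2] == 4))   # new diagonal 2-4
  expect_false(any(e[, 1] == 1 & e[, 2] == 3))
  back <- flip_edge(flipped, c(2, 4))
  lex <- function(f) f[order(f[, 1], f[, 2], f[, 3]), ]
  expect_identical(lex(back$faces), lex(quad$faces))
})

test_that("illegal flips are rejected with a named reason", {
  # tetrahedron: opposite vertices of any edge are already connected
  res <- flip_legal(mesh_tetrahedron(), c(1, 2))
  expect_false(res$ok)
  expect_match(res$reason, "already share an edge")
  expect_error(flip_edge(mesh_tetrahedron(), c(1, 2)),
               class = "dtv_illegal_move")
  # a flip that would create a sliver face fails the quality gate
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1e-4, 0), c(0.5, -1e-4, 0),
             c(0, 1, 1))
  f <- rbind(c(1, 2, 3), c(2, 1, 4), c(1, 3, 5), c(3, 2, 5), c(2, 4, 5),
             c(4, 1, 5))
  m <- trimesh(p, f)
  res <- flip_legal(m, c(1, 2))
  expect_false(res$ok)
  expect_match(res$reason, "quality")
})

test_that("split inserts the midpoint vertex with exact count bookkeeping", {
  ico <- mesh_icosahedron()
  v0 <- enclosed_volume(ico)
  sp <- split_pair(ico, mesh_edges(ico)[1, ])
  expect_identical(nrow(sp$positions), 13L)
  expect_identical(nrow(sp$faces), 22L)
  expect_identical(nrow(mesh_edges(sp)), 33L)
  expect_closed_invariants(sp)
  # the new vertex lies on the old edge: geometry pointwise unchanged
  expect_equal(enclosed_volume(sp), v0, tolerance = 1e-12)
  expect_equal(mesh_geometry(sp)$total_area, mesh_geometry(ico)$total_area,
               tolerance = 1e-12)
})

test_that("merge collapses the edge to its midpoint", {
  ico <- mesh_icosahedron()
  ed <- mesh_edges(ico)[1, ]
  mid <- colMeans(ico$positions[ed, ])
  mg <- merge_pair(ico, ed)
  expect_identical(nrow(mg$positions), 11L)
  expect_identical(nrow(mg$faces), 18L)
  expect_identical(nrow(mesh_edges(mg)), 27L)
  expect_closed_invariants(mg)
  expect_true(any(apply(mg$positions, 1, function(r)
    sqrt(sum((r - mid)^2)) < 1e-12)))
})

test_that("merge respects the link condition and the floor on face count", {
  # flipping an octahedron edge gives the new edge endpoints four common
  # neighbors; collapsing it would be non-manifold
  oct <- mesh_octahedron()
  fl <- flip_edge(oct, c(1, 2))
  newe <- mesh_edges(fl)[!(paste(mesh_edges(fl)[, 1], mesh_edges(fl)[, 2]) %in%
                           paste(mesh_edges(oct)[, 1], mesh_edges(oct)[, 2])), ]
  res <- op_legal(fl, newe, "merge")
  expect_false(res$ok)
  expect_match(res$reason, "link condition")
  # octahedron: below the minimum face count
  res2 <- op_legal(oct, c(1, 2), "merge")
  expect_false(res2$ok)
  expect_match(res2$reason, "minimum")
})

test_that("split followed by merging the new vertex restores the counts", {
  m <- mesh_icosphere(1)
  ed <- mesh_edges(m)[10, ]
  sp <- split_pair(m, ed)
  nv <- attr(sp, "new_vertex")
  mg <- merge_pair(sp, sort(c(nv, ed[1])))
  expect_identical(dim(mg$faces), dim(m$faces))
  expect_identical(dim(mg$positions), dim(m$positions))
  expect_closed_invariants(mg)
})

test_that("trial deltas agree with global recomputation", {
  # symmetric square quad: the flip exchanges congruent triangles
  p <- mech_params(K_v = 0, K_a = 50, K_c = 0, K_r = 0)
  expect_equal(trial_delta(mesh_planar_quad(), c(1, 3), "flip", p), 0,
               tolerance = 1e-12)

  m <- perturbed_icosphere(1, radius = 2)
  prm <- mech_params(K_v = 100, v_eq = 30, K_a = 50, K_c = 10, K_r = 100,
                     l_rep = 1.0)
  edges <- mesh_edges(m)
  n <- 0
  for (k in seq_len(nrow(edges))) {
    ed <- edges[k, ]
    if (!flip_legal(m, ed)$ok) next
    d_local <- trial_delta(m, ed, "flip", prm)
    after <- flip_edge(m, ed)
    d_global <- membrane_energy(after, prm)$U_total -
      membrane_energy(m, prm)$U_total
    expect_equal(d_local, d_global, tolerance = 1e-9)
    n <- n + 1
    if (n >= 25) break
  }
  expect_gte(n, 10)

  # splitting a uniformly under-stretched sphere moves areas further from
  # a_eq, so the area-term delta is positive
  sphere <- mesh_icosphere(2)
  g <- mesh_geometry(sphere)
  sphere$positions <- sphere$positions * sqrt(0.9 / mean(g$face_area))
  pa <- mech_params(K_v = 0, K_a = 50, K_c = 0, K_r = 0)
  expect_gt(trial_delta(sphere, mesh_edges(sphere)[3, ], "split", pa), 0)
})

test_that("random event sequences preserve every structural invariant", {
  set.seed(123)
  m <- mesh_icosphere(1, radius = sqrt(80 / (4 * pi)))  # areas near a_eq
  res <- reservoir_state(M_eq = 80, M_inst = 100, M_tt = 400,
                         M_t = nrow(m$faces))
  accepted <- 0
  for (i in 1:400) {
    edges <- mesh_edges(m)
    ed <- edges[sample(nrow(edges), 1), ]
    kind <- sample(c("flip", "split", "merge"), 1)
    ok <- op_legal(m, ed, kind)
    if (!ok$ok) next
    m <- switch(kind,
                flip = flip_edge(m, ed),
                split = split_pair(m, ed),
                merge = merge_pair(m, ed))
    if (kind != "flip") {
      res <- reservoir_transfer(res, if (kind == "split") "split" else "merge")
    }
    accepted <- accepted + 1
    nv <- nrow(m$positions)
    nf <- nrow(m$faces)
    expect_identical(res$M_t, nf * res$m_u)          # molecule bookkeeping
    expect_identical(res$M_t + res$M_r, res$M_tt)    # conservation
    expect_identical(nv - nrow(mesh_edges(m)) + nf, 2L)
    if (accepted %% 50 == 0) expect_closed_invariants(m)
  }
  expect_gt(accepted, 150)
  expect_closed_invariants(m)
})
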