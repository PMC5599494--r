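test_that("building canonical meshes yields the expected counts", {
  tet <- mesh_tetrahedron()
  expect_identical(nrow(tet$positions), 4L)
  expect_identical(nrow(mesh_edges(tet)), 6L)
  expect_identical(euler_characteristic(tet), 2L)

  ico <- mesh_icosahedron()
  expect_identical(nrow(mesh_edges(ico)), 30L)  # E = 3F/2
  expect_identical(euler_characteristic(ico), 2L)
  expect_closed_invariants(ico)
})

test_that("mesh validation distinguishes the failure modes", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  # an edge with three incident faces is non-manifold
  f3 <- rbind(c(1, 2, 3), c(2, 1, 4), c(2, 1, 5))
  expect_error(trimesh(p, f3, closed = FALSE), class = "dtv_nonmanifold")
  # two faces traversing a shared edge in the same direction
  fsame <- rbind(c(1, 2, 3), c(1, 2, 4))
  expect_error(trimesh(p, fsame, closed = FALSE),
               class = "dtv_orientation_error")
  # duplicate faces
  fdup <- rbind(c(1, 2, 3), c(3, 1, 2), c(1, 2, 4))
  expect_error(trimesh(p, fdup, closed = FALSE),
               class = "dtv_duplicate_face")
  # a closed mesh must not have boundary edges
  expect_error(trimesh(p[1:4, ], rbind(c(1, 2, 3)), closed = TRUE),
               class = "dtv_open_mesh")
})

test_that("a consistently inward-oriented mesh is repaired by a global flip", {
  tet <- mesh_tetrahedron()
  inward <- tet$faces[, c(1, 3, 2)]
  expect_lt(cpp_signed_volume(tet$positions, inward), 0)
  m <- trimesh(tet$positions, inward)
  expect_gt(enclosed_volume(m), 0)
})

test_that("enclosed volume matches closed forms and symmetries", {
  tet <- mesh_tetrahedron()
  expect_equal(enclosed_volume(tet), 1 / 6, tolerance = 1e-12)

  p <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  cube <- trimesh(p, f)
  expect_equal(enclosed_volume(cube), 1, tolerance = 1e-12)

  # translation invariance
  shifted <- cube
  shifted$positions <- shifted$positions + 17.3
  expect_equal(enclosed_volume(shifted), 1, tolerance = 1e-9)

  # orientation reversal negates the signed volume
  expect_equal(cpp_signed_volume(cube$positions, cube$faces[, c(1, 3, 2)]),
               -1, tolerance = 1e-12)

  # icosphere volume approaches (4/3) pi R^3 from below under refinement
  R <- 1.7
  vols <- vapply(1:3, function(s) enclosed_volume(mesh_icosphere(s, R)),
                 numeric(1))
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < 4 / 3 * pi * R^3))
  expect_equal(vols[3], 4 / 3 * pi * R^3, tolerance = 0.01)

  expect_error(enclosed_volume(mesh_planar_quad()), class = "dtv_open_mesh")
})

test_that("signed dihedral angles follow the convex-positive convention", {
  quad <- mesh_planar_quad()
  expect_equal(edge_dihedral_angle(quad, c(1, 3)), 0, tolerance = 1e-12)

  p <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  cube <- trimesh(p, f)
  expect_equal(edge_dihedral_angle(cube, c(1, 2)), pi / 2, tolerance = 1e-12)

  # regular tetrahedron: exterior fold angle pi - acos(1/3)
  pt <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  ft <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  rt <- trimesh(pt, ft)
  expect_equal(edge_dihedral_angle(rt, c(1, 2)), pi - acos(1 / 3),
               tolerance = 1e-12)

  # sign flips under reflection
  refl <- rt
  refl$positions[, 3] <- -refl$positions[, 3]
  refl$faces <- refl$faces[, c(1, 3, 2)]  # restore outward orientation
  expect_equal(edge_dihedral_angle(refl, c(1, 2)), pi - acos(1 / 3),
               tolerance = 1e-12)
  # ... but an unrepaired reflection (inward normals) negates the angle
  g <- cpp_geometry(refl$positions, refl$faces[, c(1, 3, 2)], TRUE)
  i <- which(g$edges[, 1] == 1 & g$edges[, 2] == 2)
  expect_equal(g$edge_dihedral[i], -(pi - acos(1 / 3)), tolerance = 1e-12)
})

test_that("vertex curvature measures satisfy the discrete identities", {
  # interior vertex of a flat hexagonal fan: zero mean curvature and deficit
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  p <- rbind(c(0, 0, 0), cbind(cos(th), sin(th), 0))
  f <- cbind(1, 2:7, c(3:7, 2))
  fan <- trimesh(p, f, closed = FALSE)
  vc <- vertex_curvature_measures(fan, 1)
  expect_equal(vc$M, 0, tolerance = 1e-12)
  expect_equal(vc$angle_deficit, 0, tolerance = 1e-12)

  # icosahedron: five equilateral corners per vertex, deficit pi/3
  ico <- mesh_icosahedron()
  expect_equal(vertex_curvature_measures(ico, 3)$angle_deficit, pi / 3,
               tolerance = 1e-12)

  # total mean curvature of a sphere: sum M_i -> 4 pi R under refinement
  R <- 1.3
  sums <- vapply(1:3, function(s)
    sum(mesh_geometry(mesh_icosphere(s, R))$vertex_M), numeric(1))
  err <- abs(sums / (4 * pi * R) - 1)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.005)
})

test_that("Gauss-Bonnet and the area partition hold exactly", {
  for (m in list(mesh_tetrahedron(), mesh_octahedron(),
                 perturbed_icosphere(1))) {
    g <- mesh_geometry(m)
    expect_equal(sum(g$angle_deficit), 4 * pi, tolerance = 1e-9)
    expect_equal(sum(g$vertex_A), sum(g$face_area), tolerance = 1e-12)
    expect_equal(sum(g$face_area), g$total_area, tolerance = 1e-12)
  }
})

test_that("geometry errors on degenerate faces", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(2, 1, 4))  # first face has zero area
  expect_error(cpp_geometry(p, f, FALSE), "zero-area")
})
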