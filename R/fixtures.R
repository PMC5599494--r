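# Canonical small meshes used as fixtures and as seeds for refinement.

#' Platonic-solid and test meshes
#'
#' Small canonical meshes: the unit-corner tetrahedron, a regular octahedron,
#' a regular icosahedron, an icosphere obtained by subdividing the
#' icosahedron and reprojecting onto the sphere, and an open planar quad
#' (two coplanar triangles) used in geometry unit tests.
#'
#' @param radius circumscribed radius where applicable.
#' @param subdivisions number of 1-to-4 subdivision rounds for the icosphere
#'   (faces = 20 * 4^subdivisions).
#' @return A [trimesh].
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
mesh_tetrahedron <- function() {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  trimesh(p, f)
}

#' @rdname fixtures
#' @export
mesh_octahedron <- function(radius = 1) {
  p <- radius * rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                      c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 2),
             c(6, 3, 2), c(6, 4, 3), c(6, 5, 4), c(6, 2, 5))
  trimesh(p, f)
}

#' @rdname fixtures
#' @export
mesh_icosahedron <- function(radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  p <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  p <- p / sqrt(1 + phi^2) * radius
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  trimesh(p, f)
}

#' @rdname fixtures
#' @export
mesh_icosphere <- function(subdivisions = 2, radius = 1) {
  m <- mesh_icosahedron(radius = 1)
  p <- m$positions
  f <- m$faces
  for (s in seq_len(subdivisions)) {
    key2id <- new.env(hash = TRUE, parent = emptyenv())
    midpoint <- function(i, j) {
      k <- paste(min(i, j), max(i, j))
      id <- key2id[[k]]
      if (is.null(id)) {
        mp <- (p[i, ] + p[j, ]) / 2
        mp <- mp / sqrt(sum(mp^2))
        p <<- rbind(p, mp)
        id <- nrow(p)
        key2id[[k]] <- id
      }
      id
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(c, ca, bc)
      nf[4 * t, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  p <- p / sqrt(rowSums(p^2)) * radius
  trimesh(p, f)
}

#' @rdname fixtures
#' @export
mesh_planar_quad <- function() {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4))
  trimesh(p, f, closed = FALSE)
}
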