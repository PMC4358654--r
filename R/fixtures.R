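# Deterministic synthetic geometry used throughout the tests and examples:
# a lattice point cloud, a helical polyline (a stand-in for trajectory data
# such as vectorcardiograms), a closed cube and an icosphere.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic geometry fixture
#'
#' Produces small, fully deterministic geometry resources for tests,
#' examples and benchmarks:
#'
#' * `grid_points`: an `nx * ny * nz` lattice point cloud with unit spacing
#'   (params `nx`, `ny`, `nz`, default 3 each; optional Gaussian `jitter`
#'   standard deviation, driven by `seed`).
#' * `helix_line`: `n` samples (default 100) of a helix with `turns`
#'   (default 3), `radius` 1 and `height` 2, auto-connected into a chain of
#'   `n - 1` edges.
#' * `cube_mesh`: the unit cube, 8 vertices and 12 outward-wound triangles.
#' * `sphere_mesh`: an icosphere with `subdivisions` (default 2, giving 162
#'   vertices and 320 faces) and `radius` 1.
#'
#' @param kind One of `"grid_points"`, `"helix_line"`, `"cube_mesh"`,
#'   `"sphere_mesh"`.
#' @param params Named list overriding the per-kind defaults above.
#' @param seed Integer seed for the (optional) random components.
#' @return A `u3d_geometry` of the matching class.
#' @examples
#' make_fixture("grid_points")                    # 27 points
#' make_fixture("sphere_mesh")                    # 162 vertices, 320 faces
#' @export
make_fixture <- function(kind = c("grid_points", "helix_line", "cube_mesh",
                                  "sphere_mesh"),
                         params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- function(name, default) params[[name]] %||% default
  switch(kind,
    grid_points = {
      nx <- p("nx", 3L); ny <- p("ny", 3L); nz <- p("nz", 3L)
      g <- as.matrix(expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1,
                                 z = seq_len(nz) - 1))
      jitter <- p("jitter", 0)
      if (jitter > 0)
        g <- g + with_seed(seed, matrix(stats::rnorm(length(g), sd = jitter),
                                        nrow(g)))
      u3d_point_cloud(g)
    },
    helix_line = {
      n <- p("n", 100L); turns <- p("turns", 3)
      radius <- p("radius", 1); height <- p("height", 2)
      t <- seq(0, 1, length.out = n)
      u3d_line_set(cbind(radius * cos(2 * pi * turns * t),
                         radius * sin(2 * pi * turns * t),
                         height * t))
    },
    cube_mesh = {
      side <- p("side", 1)
      v <- side * rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                        c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
      f <- rbind(c(1, 4, 3), c(1, 3, 2),   # bottom (z = 0)
                 c(5, 6, 7), c(5, 7, 8),   # top (z = side)
                 c(1, 2, 6), c(1, 6, 5),   # front (y = 0)
                 c(2, 3, 7), c(2, 7, 6),   # right (x = side)
                 c(3, 4, 8), c(3, 8, 7),   # back (y = side)
                 c(4, 1, 5), c(4, 5, 8))   # left (x = 0)
      u3d_mesh(v, f)
    },
    sphere_mesh = icosphere(p("subdivisions", 2L), p("radius", 1)))
}

# icosphere: subdivide the icosahedron, projecting onto the sphere;
# subdivision level s gives 20 * 4^s faces (s = 2: 320 faces, 162 vertices)
icosphere <- function(subdivisions = 2L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    midpoint <- new.env(parent = emptyenv())
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- get0(key, envir = midpoint)
      if (!is.null(hit)) return(hit)
      m <- (vlist[[a]] + vlist[[b]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1L]] <<- m
      idx <- length(vlist)
      assign(key, idx, envir = midpoint)
      idx
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(c, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  u3d_mesh(radius * v, f)
}
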