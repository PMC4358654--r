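test_that("group paths are created, reused and validated", {
  sc <- u3d_scene()
  sc <- u3d_add_group(sc, "A/B")
  expect_identical(u3d_get_node(sc, "A/B")$kind, "group")
  expect_identical(u3d_get_node(sc, "A")$kind, "group")
  n_nodes <- function(s) length(u3dio:::flatten_nodes(s))
  before <- n_nodes(sc)
  sc2 <- u3d_add_group(sc, "A/B")  # idempotent
  expect_identical(n_nodes(sc2), before)
  expect_identical(u3d_get_node(sc2, "A/B"), u3d_get_node(sc, "A/B"))
  expect_error(u3d_add_group(sc, ""), "empty")
  expect_error(u3d_add_group(sc, "A//B"), "non-empty")
})

test_that("a group path may not run through a model node", {
  sc <- u3d_scene()
  sc <- u3d_add_resource(sc, "g", u3d_point_cloud(diag(3)))
  sc <- u3d_add_model(sc, "M", "g", path = "A")
  expect_error(u3d_add_group(sc, "A/M/deeper"), "model node")
})

test_that("models share resources and resolve references", {
  sc <- u3d_scene()
  sc <- u3d_add_resource(sc, "shared", make_fixture("cube_mesh"))
  sc <- u3d_add_model(sc, "Left", "shared", path = "A")
  sc <- u3d_add_model(sc, "Right", "shared", path = "B")
  expect_length(sc$resources, 1)  # still one resource for two models
  models <- u3dio:::scene_model_nodes(sc)
  expect_identical(vapply(models, `[[`, character(1), "geometry_ref"),
                   c("shared", "shared"))
  expect_error(u3d_add_model(sc, "Bad", "missing"), "does not resolve")
  # model under "/" is a direct child of the root
  sc <- u3d_add_model(sc, "Top", "shared", path = "/")
  kids <- vapply(sc$root$children, `[[`, character(1), "name")
  expect_true("Top" %in% kids)
})

test_that("sibling name collisions auto-suffix with a warning", {
  sc <- u3d_scene()
  sc <- u3d_add_resource(sc, "g", u3d_point_cloud(diag(3)))
  sc <- u3d_add_model(sc, "Obj", "g")
  expect_warning(sc <- u3d_add_model(sc, "Obj", "g"), "renamed to 'Obj_2'")
  expect_warning(sc <- u3d_add_model(sc, "Obj", "g"), "renamed to 'Obj_3'")
  nms <- vapply(sc$root$children, `[[`, character(1), "name")
  expect_identical(nms, c("Obj", "Obj_2", "Obj_3"))
})

test_that("vertex normals match the brute-force area-weighted oracle", {
  # plane cases
  tri <- u3d_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), matrix(1:3, 1))
  expect_equal(compute_vertex_normals(tri)$normals,
               matrix(rep(c(0, 0, 1), each = 3), 3,
                      dimnames = list(NULL, c("x", "y", "z"))))
  rev_tri <- u3d_mesh(tri$positions, matrix(c(1, 3, 2), 1))
  expect_equal(unname(compute_vertex_normals(rev_tri)$normals),
               matrix(rep(c(0, 0, -1), each = 3), 3))
  # vertex on three mutually orthogonal equal-area faces with outward
  # normals +x, +y, +z: expected (1,1,1)/sqrt(3), from the hand oracle
  p <- rbind(c(0, 0, 0), c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(1, 2, 3))
  nm <- compute_vertex_normals(u3d_mesh(p, f))$normals
  expect_equal(unname(nm[1, ]), rep(1 / sqrt(3), 3), tolerance = 1e-12)
  # randomized meshes against the oracle; all unit length
  set.seed(11)
  for (rep in 1:5) {
    m <- make_fixture("sphere_mesh", list(subdivisions = 1L))
    m$positions <- m$positions * matrix(runif(3, 0.5, 2), nrow(m$positions),
                                        3, byrow = TRUE)
    got <- compute_vertex_normals(u3d_mesh(m$positions, m$faces))$normals
    expect_equal(unname(got),
                 unname(oracle_vertex_normals(m$positions, m$faces)),
                 tolerance = 1e-12)
    expect_true(all(abs(sqrt(rowSums(got^2)) - 1) < 1e-6))
  }
  # existing normals are preserved untouched
  withn <- compute_vertex_normals(tri)
  tweaked <- withn
  expect_identical(compute_vertex_normals(tweaked)$normals, withn$normals)
})

test_that("degenerate-only incidence falls back to (0,0,1) with a warning", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))  # collinear: zero area
  m <- u3d_mesh(p, matrix(1:3, 1))
  expect_warning(out <- compute_vertex_normals(m), "fallback")
  expect_equal(unname(out$normals), matrix(rep(c(0, 0, 1), each = 3), 3))
})

test_that("validate_geometry reports exactly the broken invariants", {
  expect_identical(nrow(validate_geometry(make_fixture("cube_mesh"))), 0L)
  deg <- u3d_mesh(diag(3), rbind(c(1, 2, 2)))
  iss <- validate_geometry(deg)
  expect_identical(iss$kind, "degenerate_face")
  expect_true(iss$droppable)
  bad_edge <- u3d_line_set(diag(3), rbind(c(1, 6)))
  iss <- validate_geometry(bad_edge)
  expect_identical(iss$kind, "index_out_of_range")
  expect_false(iss$droppable)
  loop <- u3d_line_set(diag(3), rbind(c(2, 2)))
  expect_identical(validate_geometry(loop)$kind, "zero_length_edge")
})

test_that("material channels are clamped and validated", {
  m <- u3d_material(diffuse = c(2, -1, 0.5), opacity = 0.25)
  expect_identical(m$diffuse, c(1, 0, 0.5))
  expect_identical(m$opacity, 0.25)
  expect_identical(u3d_material()$ambient, 0.1 * c(0.65, 0.65, 0.65))
  expect_error(u3d_material(diffuse = c(1, NA, 0)), "finite")
})
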