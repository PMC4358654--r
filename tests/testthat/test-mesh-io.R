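test_that("OBJ vertices and faces convert from 1-based indices", {
  m <- read_obj(text = c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"))
  expect_equal(nrow(m$positions), 3)
  expect_equal(unname(m$faces), matrix(c(1L, 2L, 3L), 1))
})

test_that("OBJ polygons fan-triangulate from the first corner", {
  m <- read_obj(text = c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
                         "f 1 2 3 4"))
  expect_equal(unname(m$faces), rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
})

test_that("OBJ negative indices resolve relative to vertices seen so far", {
  # -1 = last vertex, -2 = one before, ...; oracle worked by hand:
  # after 3 vertices, f -1 -2 -3 is face (3, 2, 1)
  m <- read_obj(text = c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f -1 -2 -3"))
  expect_equal(unname(m$faces), matrix(c(3L, 2L, 1L), 1))
})

test_that("OBJ corner forms, comments and unknown records are handled", {
  expect_warning(
    m <- read_obj(text = c("# cmt", "o thing", "v 0 0 0", "v 1 0 0",
                           "v 0 1 0", "vt 0 0", "f 1/1 2/1 3/1")),
    "ignored 2 unsupported")
  expect_equal(unname(m$faces), matrix(1:3, 1))
  expect_error(read_obj(text = c("v 0 0 0", "f 1 2 3")),
               "nonexistent vertex")
  # per-vertex normals picked up and normalized
  m <- read_obj(text = c("v 0 0 0", "v 1 0 0", "v 0 1 0",
                         "vn 0 0 2", "vn 0 0 2", "vn 0 0 2", "f 1 2 3"))
  expect_equal(unname(m$normals), matrix(rep(c(0, 0, 1), each = 3), 3))
})

test_that("read_obj inverts write_obj on fixture meshes", {
  for (kind in c("cube_mesh", "sphere_mesh")) {
    m <- compute_vertex_normals(make_fixture(kind))
    path <- tempfile(fileext = ".obj")
    write_obj(m, path)
    back <- read_obj(path)
    expect_identical(back$positions, m$positions)
    expect_identical(back$faces, m$faces)
    expect_equal(back$normals, m$normals, tolerance = 1e-12)
  }
})

test_that("ASCII PLY parses, binary PLY is rejected by name", {
  ply <- c("ply", "format ascii 1.0",
           "element vertex 4",
           "property float x", "property float y", "property float z",
           "element face 2",
           "property list uchar int vertex_indices",
           "end_header",
           "0 0 0", "1 0 0", "1 1 0", "0 1 0",
           "3 0 1 2", "3 0 2 3")
  m <- read_ply_ascii(text = ply)
  expect_equal(nrow(m$positions), 4)
  expect_equal(unname(m$faces), rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  bin <- sub("ascii", "binary_little_endian", ply, fixed = TRUE)
  expect_error(read_ply_ascii(text = bin),
               "unsupported PLY format 'binary_little_endian'")
})

test_that("PLY extra properties are ignored and counts are enforced", {
  ply <- c("ply", "format ascii 1.0",
           "element vertex 3",
           "property float x", "property float y", "property float z",
           "property uchar red",
           "element face 1",
           "property list uchar int vertex_indices",
           "end_header",
           "0 0 0 255", "1 0 0 255", "0 1 0 255",
           "3 0 1 2")
  m <- read_ply_ascii(text = ply)
  expect_equal(unname(m$positions), rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  # header promises more rows than the body provides
  truncated <- c("ply", "format ascii 1.0", "element vertex 5",
                 "property float x", "property float y", "property float z",
                 "end_header", "0 0 0", "1 1 1")
  expect_error(read_ply_ascii(text = truncated), "truncated")
  # a quad face fan-triangulates
  quad <- c("ply", "format ascii 1.0", "element vertex 4",
            "property float x", "property float y", "property float z",
            "element face 1", "property list uchar int vertex_indices",
            "end_header", "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3")
  expect_equal(nrow(read_ply_ascii(text = quad)$faces), 2)
})

test_that("fixtures have the documented sizes and structure", {
  expect_equal(nrow(make_fixture("grid_points")$positions), 27)
  h <- make_fixture("helix_line")
  expect_equal(nrow(h$positions), 100)
  expect_equal(nrow(h$edges), 99)
  cu <- make_fixture("cube_mesh")
  expect_equal(dim(cu$positions), c(8L, 3L))
  expect_equal(nrow(cu$faces), 12)
  # closed surface: every undirected edge shared by exactly two faces
  edge_counts <- function(f) {
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    table(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_true(all(edge_counts(cu$faces) == 2))
  sp <- make_fixture("sphere_mesh")
  expect_equal(nrow(sp$positions), 162)
  expect_equal(nrow(sp$faces), 320)
  expect_true(all(edge_counts(sp$faces) == 2))
  expect_equal(unname(sqrt(rowSums(sp$positions^2))), rep(1, 162),
               tolerance = 1e-12)
  # determinism for a fixed seed, also with jitter on
  a <- make_fixture("grid_points", list(jitter = 0.1), seed = 9)
  b <- make_fixture("grid_points", list(jitter = 0.1), seed = 9)
  expect_identical(a, b)
})
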