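demo_scene <- function() {
  sc <- u3d_scene(metadata = c(Title = "VCG"))
  sc <- u3d_add_resource(sc, "grid", make_fixture("grid_points"))
  sc <- u3d_add_resource(sc, "helix", make_fixture("helix_line"))
  sc <- u3d_add_resource(sc, "cube", make_fixture("cube_mesh"))
  sc <- u3d_add_model(sc, "Pts", "grid", path = "A/B")
  sc <- u3d_add_model(sc, "Trace", "helix", path = "A",
                      diffuse = c(1, 0, 0), opacity = 0.5)
  u3d_add_model(sc, "Cube", "cube")
}

test_that("the file magic spells U3D and declared sizes are honest", {
  bytes <- write_u3d(u3d_scene())
  expect_identical(bytes[1:3], as.raw(c(0x55, 0x33, 0x44)))
  dec <- decode_scene(bytes)  # checks declared file size internally
  expect_identical(dec$file_size, as.numeric(length(bytes)))
  expect_length(dec$resources, 0)
  expect_identical(summarize_u3d(bytes)$n_models, 0L)

  bytes <- write_u3d(demo_scene())
  idx <- parse_blocks(bytes)
  expect_true(all(idx$offset %% 4 == 0))
  extents <- 12 + 4 * ceiling(idx$data_size / 4) +
    4 * ceiling(idx$metadata_size / 4)
  expect_identical(sum(extents), as.numeric(length(bytes)))
  dec <- decode_scene(bytes)
  # declaration size covers everything before the continuation section
  first_cont <- min(idx$offset[grepl("continuation", idx$kind)])
  expect_identical(dec$declaration_size,
                   sum(extents[idx$offset < first_cont]))
})

test_that("serialization is deterministic", {
  sc <- demo_scene()
  expect_identical(write_u3d(sc), write_u3d(sc))
})

test_that("node chains reproduce the tree and materials reach the models", {
  bytes <- write_u3d(demo_scene())
  dec <- decode_scene(bytes)
  expect_same_tree(dec$root, demo_scene()$root)
  # find the transparent model and check its material and blending path
  find_model <- function(node, name) {
    if (node$kind == "model") return(if (node$name == name) node)
    for (ch in node$children) {
      hit <- find_model(ch, name)
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  trace <- find_model(dec$root, "Trace")
  expect_identical(trace$material$diffuse, c(1, 0, 0))
  expect_identical(trace$material$opacity, 0.5)
  expect_true(attr(trace$material, "alpha_blended"))
  opaque <- find_model(dec$root, "Cube")
  expect_false(attr(opaque$material, "alpha_blended"))
})

test_that("models sharing geometry share one declaration block", {
  sc <- u3d_scene()
  sc <- u3d_add_resource(sc, "shared", make_fixture("sphere_mesh",
                                                    list(subdivisions = 1L)))
  sc <- u3d_add_model(sc, "A", "shared")
  sc <- u3d_add_model(sc, "B", "shared")
  idx <- parse_blocks(write_u3d(sc))
  expect_identical(sum(idx$kind == "base_mesh_continuation"), 1L)
  s <- summarize_u3d(write_u3d(sc))
  expect_identical(s$n_models, 2L)
  expect_identical(s$n_resources, 1L)
})

test_that("identical materials are deduplicated, distinct ones are not", {
  sc <- u3d_scene()
  sc <- u3d_add_resource(sc, "g", make_fixture("cube_mesh"))
  sc <- u3d_add_model(sc, "A", "g", diffuse = c(1, 0, 0))
  sc <- u3d_add_model(sc, "B", "g", diffuse = c(1, 0, 0))
  expect_identical(summarize_u3d(write_u3d(sc))$n_materials, 1L)
  sc <- u3d_add_model(sc, "C", "g", diffuse = c(1, 0, 0), opacity = 0.5)
  expect_identical(summarize_u3d(write_u3d(sc))$n_materials, 2L)
})

test_that("quantized positions respect the half-step error bound", {
  set.seed(99)
  pts <- matrix(runif(3000, -50, 50), ncol = 3)
  sc <- u3d_scene()
  sc <- u3d_add_resource(sc, "p", u3d_point_cloud(pts))
  sc <- u3d_add_model(sc, "P", "p")
  for (quant in c(1000, 8192)) {
    dec <- decode_scene(write_u3d(sc, config = u3d_config(position_quant = quant)))
    g <- dec$resources$p
    expect_identical(nrow(g$positions), nrow(pts))  # count and order kept
    expect_lt(max(abs(g$positions - pts)), 0.5 / quant + 1e-12)
    expect_identical(attr(g, "position_tolerance"), 0.5 / quant)
  }
  # zero is a fixed point of quantization
  sc0 <- u3d_scene()
  sc0 <- u3d_add_resource(sc0, "o", u3d_point_cloud(matrix(0, 1, 3)))
  sc0 <- u3d_add_model(sc0, "O", "o")
  dec <- decode_scene(write_u3d(sc0))
  expect_identical(unname(dec$resources$o$positions), matrix(0, 1, 3))
})

test_that("line sets preserve topology; degenerate edges drop with warning", {
  helix <- make_fixture("helix_line")
  sc <- u3d_scene()
  sc <- u3d_add_resource(sc, "h", helix)
  sc <- u3d_add_model(sc, "H", "h")
  dec <- decode_scene(write_u3d(sc))
  expect_identical(dec$resources$h$edges, helix$edges)  # chain of 99
  # an edge joining a node to itself is dropped before export
  sc2 <- u3d_scene()
  sc2 <- u3d_add_resource(sc2, "l",
                          u3d_line_set(diag(3), rbind(c(1, 2), c(2, 2))))
  sc2 <- u3d_add_model(sc2, "L", "l")
  expect_warning(bytes <- write_u3d(sc2), "dropping 1 degenerate")
  expect_identical(unname(decode_scene(bytes)$resources$l$edges),
                   rbind(c(1L, 2L)))
  # empty edge list is a valid file with zero segments
  sc3 <- u3d_scene()
  sc3 <- u3d_add_resource(sc3, "e",
                          u3d_line_set(diag(3), matrix(integer(0), ncol = 2)))
  sc3 <- u3d_add_model(sc3, "E", "e")
  expect_identical(summarize_u3d(write_u3d(sc3))$n_line_segments, 0L)
})

test_that("meshes round-trip bit-exactly, with or without normals", {
  sp <- make_fixture("sphere_mesh")
  sc <- u3d_scene()
  sc <- u3d_add_resource(sc, "s", sp)
  sc <- u3d_add_model(sc, "S", "s")
  dec <- decode_scene(write_u3d(sc))
  g <- dec$resources$s
  expect_identical(g$positions, f32_matrix(sp$positions))
  expect_identical(g$faces, sp$faces)
  expect_identical(nrow(g$faces), 320L)
  expect_true(all(abs(sqrt(rowSums(g$normals^2)) - 1) < 1e-6))
  # exclude-normals attribute
  dec2 <- decode_scene(write_u3d(sc, config = u3d_config(write_normals = FALSE)))
  expect_true(dec2$declarations$s$exclude_normals)
  expect_null(dec2$resources$s$normals)
  # single full-resolution base mesh: min resolution = max resolution = n
  expect_identical(dec$declarations$s$min_resolution, 162)
  expect_identical(dec$declarations$s$max_resolution, 162)
})

test_that("degenerate faces are dropped before export with a warning", {
  m <- u3d_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 2, 2)))
  sc <- u3d_scene()
  sc <- u3d_add_resource(sc, "m", m)
  sc <- u3d_add_model(sc, "M", "m")
  expect_warning(bytes <- write_u3d(sc), "degenerate")
  expect_identical(summarize_u3d(bytes)$n_faces, 1L)
})

test_that("empty or unresolvable scenes fail before any bytes are written", {
  sc <- u3d_scene()
  sc <- u3d_add_resource(sc, "empty",
                         u3d_point_cloud(matrix(numeric(0), ncol = 3)))
  expect_error(u3d_add_model(sc, "E", "empty"), "no positions")
  # zero-model scene is explicitly allowed
  expect_silent(write_u3d(u3d_scene()))
})

test_that("metadata and config extras land on the header block", {
  sc <- u3d_scene(metadata = c(Title = "VCG", Author = "lab"))
  bytes <- write_u3d(sc, config = u3d_config(
    creator_metadata = c(Creator = "u3dio"), root_node_name = "World"))
  dec <- decode_scene(bytes)
  expect_identical(dec$metadata[["Title"]], "VCG")
  expect_identical(dec$metadata[["Creator"]], "u3dio")
  expect_identical(dec$root$name, "World")
})

test_that("default lighting and view blocks appear only when enabled", {
  sc <- demo_scene()
  off <- summarize_u3d(write_u3d(sc))
  expect_identical(off$n_lights + off$n_views, 0L)
  on <- summarize_u3d(write_u3d(sc, config = u3d_config(
    emit_default_lighting = TRUE, emit_default_view = TRUE)))
  expect_identical(on$n_lights, 1L)
  expect_identical(on$n_views, 1L)
  # the view targets the scene bounding-box centre
  dec <- decode_scene(write_u3d(sc, config = u3d_config(emit_default_view = TRUE)))
  bb <- u3dio:::scene_bbox(sc)
  expect_equal(dec$views[[1]]$target, as_f32((bb[1, ] + bb[2, ]) / 2),
               tolerance = 1e-7)
})

test_that("sharing one resource across models beats duplicating it", {
  mesh <- make_fixture("sphere_mesh")  # 162 vertices, well over 100
  shared <- u3d_scene()
  shared <- u3d_add_resource(shared, "m", mesh)
  dup <- u3d_scene()
  for (k in 1:3) {
    shared <- u3d_add_model(shared, sprintf("S%d", k), "m")
    dup <- u3d_add_resource(dup, sprintf("m%d", k), mesh)
    dup <- u3d_add_model(dup, sprintf("S%d", k), sprintf("m%d", k))
  }
  expect_lt(length(write_u3d(shared)), length(write_u3d(dup)))
})
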