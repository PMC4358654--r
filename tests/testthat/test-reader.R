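test_that("parse_blocks partitions the stream exactly", {
  set.seed(31)
  for (i in 1:10) {
    bytes <- suppressWarnings(write_u3d(random_scene()))
    idx <- parse_blocks(bytes)
    expect_identical(idx$kind[1], "file_header")
    extents <- 12 + 4 * ceiling(idx$data_size / 4) +
      4 * ceiling(idx$metadata_size / 4)
    expect_identical(idx$offset, cumsum(c(0, head(extents, -1))))
    expect_identical(sum(extents), as.numeric(length(bytes)))
  }
})

test_that("truncated or misaligned streams error with an offset", {
  bytes <- write_u3d(u3d_scene())
  expect_error(parse_blocks(bytes[-length(bytes)]), "offset")
  expect_error(parse_blocks(c(bytes, as.raw(1))),
               sprintf("truncated block header at offset %d", length(bytes)))
  expect_error(parse_blocks(as.raw(1:5)), "shorter than one block header")
  # growing the declared size of the last block overruns the stream
  corrupt <- bytes
  last_off <- max(parse_blocks(bytes)$offset)
  corrupt[last_off + 5] <- as.raw(0xFF)
  expect_error(parse_blocks(corrupt), "exceeds stream end")
})

test_that("unknown block types are reported, not fatal", {
  bytes <- write_u3d(u3d_scene())
  w <- bit_writer()
  bw_raw(w, bytes)
  bw_u32(w, c(0xFFFFFFEE, 4, 0, 42))  # fictitious block type
  ext <- bw_bytes(w)
  # keep the header's declared file size honest after appending
  ext[25:28] <- writeBin(length(ext), raw(), size = 4)
  idx <- parse_blocks(ext)
  expect_identical(idx$kind[nrow(idx)], "unknown")
  expect_identical(decode_scene(ext)$root$name, "Scene")
})

test_that("decode_scene inverts write_u3d on randomized scenes", {
  set.seed(123)
  for (i in 1:25) {
    sc <- random_scene()
    bytes <- suppressWarnings(write_u3d(sc))
    dec <- decode_scene(bytes)
    expect_same_tree(dec$root, sc$root)
    expect_identical(as.list(dec$metadata), as.list(sc$metadata))
    used <- unique(vapply(u3dio:::scene_model_nodes(sc), `[[`,
                          character(1), "geometry_ref"))
    expect_setequal(names(dec$resources), used)
    for (id in used) {
      orig <- sc$resources[[id]]
      got <- dec$resources[[id]]
      expect_identical(class(got), class(orig))
      expect_identical(nrow(got$positions), nrow(orig$positions))
      if (inherits(orig, "u3d_mesh")) {
        expect_identical(got$positions, f32_matrix(orig$positions))
        expect_identical(got$faces, orig$faces)
      } else {
        expect_lt(max(abs(got$positions - orig$positions), 0), 5e-4 + 1e-12)
        if (inherits(orig, "u3d_line_set"))
          expect_identical(got$edges, orig$edges)
      }
    }
  }
})

test_that("summaries count models, resources and elements correctly", {
  sc <- u3d_scene()
  sc <- u3d_add_resource(sc, "g", make_fixture("grid_points"))
  sc <- u3d_add_resource(sc, "h", make_fixture("helix_line"))
  sc <- u3d_add_resource(sc, "c", make_fixture("cube_mesh"))
  for (id in c("g", "h", "c"))
    sc <- u3d_add_model(sc, toupper(id), id)
  s <- summarize_u3d(write_u3d(sc))
  expect_identical(s$n_models, 3L)
  expect_identical(s$n_resources, 3L)
  expect_identical(unlist(s$resources_by_kind),
                   c(pointset = 1L, lineset = 1L, mesh = 1L))
  expect_identical(s$n_points, 27L)
  expect_identical(s$n_line_segments, 99L)
  expect_identical(s$n_faces, 12L)
  # two models over one resource
  sc2 <- u3d_scene()
  sc2 <- u3d_add_resource(sc2, "m", make_fixture("cube_mesh"))
  sc2 <- u3d_add_model(sc2, "A", "m")
  sc2 <- u3d_add_model(sc2, "B", "m")
  s2 <- summarize_u3d(write_u3d(sc2))
  expect_identical(s2$n_models, 2L)
  expect_identical(s2$n_resources, 1L)
})
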