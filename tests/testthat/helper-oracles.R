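# Independent oracles and generators shared across the test files.

# brute-force area-weighted vertex normals: plain per-face loop, kept
# deliberately independent of compute_vertex_normals()
oracle_vertex_normals <- function(p, f) {
  acc <- matrix(0, nrow(p), 3)
  for (i in seq_len(nrow(f))) {
    a <- p[f[i, 1], ]; b <- p[f[i, 2], ]; c <- p[f[i, 3], ]
    e1 <- b - a; e2 <- c - a
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    for (v in f[i, ]) acc[v, ] <- acc[v, ] + cr
  }
  acc / sqrt(rowSums(acc^2))
}

# brute-force row filter: literal scan over 0-based data-row indices
oracle_filter_count <- function(n_rows, start_row, stride, max_rows = NULL,
                                match_keep = rep(TRUE, n_rows)) {
  kept <- 0L
  for (i in seq_len(n_rows) - 1L) {
    if (i >= start_row && (i - start_row) %% stride == 0 && match_keep[i + 1L])
      kept <- kept + 1L
  }
  if (!is.null(max_rows)) kept <- min(kept, max_rows)
  kept
}

random_object_spec <- function() {
  type <- sample(c("pointset", "lineset", "mesh"), 1)
  u3d_object_spec(
    object_type = type,
    geometry_id = sample(c("g1", "g2", "0", "12"), 1),
    name = if (runif(1) < 0.8) paste0("obj", sample.int(1e6, 1)),
    group_path = if (runif(1) < 0.5) paste(sample(LETTERS, sample(1:3, 1)),
                                           collapse = "/"),
    diffuse = if (runif(1) < 0.7) runif(3),
    specular = if (runif(1) < 0.5) runif(3),
    opacity = if (runif(1) < 0.7) runif(1),
    metadata = if (runif(1) < 0.3) setNames(c("v1", "v2"), c("key1", "key2")))
}

# a randomized small scene over the fixture matrix; deterministic given the
# caller's RNG state
random_scene <- function() {
  kinds <- sample(c("grid_points", "helix_line", "cube_mesh", "sphere_mesh"),
                  sample(1:3, 1), replace = TRUE)
  sc <- u3d_scene(metadata = c(Seed = as.character(sample.int(1e6, 1))))
  for (k in seq_along(kinds)) {
    params <- switch(kinds[k],
      grid_points = list(nx = sample(2:4, 1), ny = sample(2:4, 1), nz = 2L,
                         jitter = 0.1),
      helix_line = list(n = sample(c(10L, 40L), 1)),
      sphere_mesh = list(subdivisions = 1L),
      list())
    id <- sprintf("res_%d", k)
    sc <- u3d_add_resource(sc, id, make_fixture(kinds[k], params,
                                                seed = sample.int(1e6, 1)))
    path <- sample(c("/", "A", "A/B", "C"), 1)
    n_models <- sample(1:2, 1)  # sometimes two models share the resource
    for (m in seq_len(n_models)) {
      sc <- u3d_add_model(sc, sprintf("model_%d_%d", k, m), id, path = path,
                          diffuse = round(runif(3), 3),
                          opacity = sample(c(1, 0.5), 1))
    }
  }
  sc
}

# compare a decoded tree against the scene that produced it: structure,
# names, kinds and model geometry references must match exactly
expect_same_tree <- function(decoded_root, scene_root) {
  strip <- function(node) {
    if (node$kind == "group") {
      list(kind = "group", name = node$name,
           children = lapply(node$children, strip))
    } else {
      list(kind = "model", name = node$name, ref = node$geometry_ref)
    }
  }
  expect_identical(strip(decoded_root), strip(scene_root))
}

f32_matrix <- function(m) {
  matrix(as_f32(m), ncol = ncol(m), dimnames = dimnames(m))
}
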