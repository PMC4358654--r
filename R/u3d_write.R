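# Scene -> U3D byte stream.
#
# File layout: file header block (carrying the scene metadata), one modifier
# chain per scene node (group nodes first in preorder, so parents precede
# children; model chains carry the model node plus its shading modifier),
# shader and material resources (deduplicated across models), optional
# default light/view resources and nodes, one model-resource modifier chain
# per geometry resource holding the declaration block, and finally the
# continuation blocks with the bulk geometry data. Output is byte-identical
# across runs for identical input: nothing time- or locale-dependent is
# written.

#' Encoder configuration
#'
#' @param position_quant Position quantization factor (steps per model
#'   unit) for point and line positions; the inverse-quantization error is
#'   at most `0.5 / position_quant` per axis. The default 1000 keeps about
#'   three decimal digits. Mesh positions are stored as raw 32-bit floats
#'   and are not quantized.
#' @param normal_quant Quantization factor reserved for normals (carried in
#'   the declarations; base-mesh normals are stored as raw floats).
#' @param write_normals Emit per-vertex normals for meshes; when `FALSE`
#'   the mesh declaration carries the exclude-normals attribute and PDF
#'   viewers shade flat.
#' @param emit_default_lighting Emit one ambient light resource + node.
#'   Off by default: PDF viewers supply their own default lighting.
#' @param emit_default_view Emit a perspective view node framing the scene
#'   bounding box.
#' @param root_node_name Overrides the scene root group's name, `NULL` to
#'   keep it.
#' @param creator_metadata Extra key/value pairs merged into the file
#'   metadata.
#' @return An object of class `u3d_config`.
#' @export
u3d_config <- function(position_quant = 1000, normal_quant = 16384,
                       write_normals = TRUE,
                       emit_default_lighting = FALSE,
                       emit_default_view = FALSE,
                       root_node_name = NULL,
                       creator_metadata = character()) {
  if (!is.numeric(position_quant) || position_quant <= 0)
    stop("position_quant must be > 0")
  if (!is.numeric(normal_quant) || normal_quant <= 0)
    stop("normal_quant must be > 0")
  if (!is.null(root_node_name) &&
      (!is.character(root_node_name) || !nzchar(root_node_name)))
    stop("root_node_name must be a non-empty string")
  structure(list(position_quant = as.numeric(position_quant),
                 normal_quant = as.numeric(normal_quant),
                 write_normals = isTRUE(write_normals),
                 emit_default_lighting = isTRUE(emit_default_lighting),
                 emit_default_view = isTRUE(emit_default_view),
                 root_node_name = root_node_name,
                 creator_metadata = creator_metadata),
            class = "u3d_config")
}

# ---- low-level framing -----------------------------------------------------

u3d_block <- function(type, data, meta = raw(0), continuation = FALSE) {
  structure(list(type = type, data = data, meta = meta,
                 continuation = continuation), class = "u3d_block")
}

pad4 <- function(n) as.integer(ceiling(n / 4) * 4)

# serialized length of a framed block
block_extent <- function(b) 12L + pad4(length(b$data)) + pad4(length(b$meta))

frame_block <- function(b) {
  w <- bit_writer()
  bw_u32(w, c(b$type, length(b$data), length(b$meta)))
  bw_raw(w, b$data); bw_align4(w)
  bw_raw(w, b$meta); bw_align4(w)
  bw_bytes(w)
}

metadata_bytes <- function(metadata) {
  w <- bit_writer()
  bw_u32(w, length(metadata))
  for (k in names(metadata)) {
    bw_u32(w, 0)            # attributes: plain string value
    bw_string(w, k)
    bw_string(w, metadata[[k]])
  }
  bw_bytes(w)
}

node_header <- function(w, name, parent, transform) {
  bw_string(w, name)
  bw_u32(w, 1)              # parent count
  bw_string(w, parent)
  bw_f32(w, as.numeric(transform))   # column-major 4x4, identity by default
  w
}

# wrap framed child blocks into a modifier chain's data payload
chain_data <- function(name, chain_type, framed_children) {
  w <- bit_writer()
  bw_string(w, name)
  bw_u32(w, c(chain_type, 0))        # chain type, attributes
  bw_align4(w)                        # children stay 32-bit aligned in-file
  bw_u32(w, length(framed_children))
  for (fc in framed_children) bw_raw(w, fc)
  bw_bytes(w)
}

# ---- node blocks -----------------------------------------------------------

blk_group_node <- function(name, parent, transform = diag(4)) {
  w <- node_header(bit_writer(), name, parent, transform)
  u3d_block(U3D_BLOCK$group_node, bw_bytes(w))
}

blk_model_node <- function(name, parent, transform, resource_name) {
  w <- node_header(bit_writer(), name, parent, transform)
  bw_string(w, resource_name)
  bw_u32(w, 3)              # visibility: front and back faces
  u3d_block(U3D_BLOCK$model_node, bw_bytes(w))
}

blk_shading_modifier <- function(name, kind, shader_name) {
  attrs <- switch(kind, mesh = SHADING_MESH, lineset = SHADING_LINE,
                  pointset = SHADING_POINT)
  w <- bit_writer()
  bw_string(w, name)
  bw_u32(w, c(attrs, 1, 1))  # attributes, shader list count, shader count
  bw_string(w, shader_name)
  u3d_block(U3D_BLOCK$shading_modifier, bw_bytes(w))
}

#' Serialize the scene tree to node modifier-chain blocks
#'
#' Emits one modifier chain per node, parents before children so the
#' on-disk parent links (by name) reproduce the scene tree. A model chain
#' carries the model node plus a shading modifier binding its shader.
#'
#' @param scene A `u3d_scene`.
#' @param shader_names Named character: model node name -> shader name (as
#'   produced by [encode_shading_resources()]).
#' @return A list of `u3d_block` objects.
#' @keywords internal
encode_node_blocks <- function(scene, shader_names) {
  nodes <- flatten_nodes(scene)
  nms <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop(sprintf("duplicate node name '%s' in scene tree (names must be unique file-wide)",
                 nms[duplicated(nms)][1]), call. = FALSE)
  blocks <- list()
  for (nd in nodes) {
    if (nd$kind == "group") {
      child <- blk_group_node(nd$name, nd$parent, nd$transform)
      ctype <- CHAIN_NODE
      framed <- list(frame_block(child))
    } else {
      model <- blk_model_node(nd$name, nd$parent, nd$transform, nd$geometry_ref)
      kind <- u3d_geometry_kind(scene$resources[[nd$geometry_ref]])
      shading <- blk_shading_modifier(nd$name, kind, shader_names[[nd$name]])
      ctype <- CHAIN_NODE
      framed <- list(frame_block(model), frame_block(shading))
    }
    blocks[[length(blocks) + 1L]] <-
      u3d_block(U3D_BLOCK$modifier_chain, chain_data(nd$name, ctype, framed))
  }
  blocks
}

# ---- shading resources -----------------------------------------------------

blk_material <- function(name, m) {
  w <- bit_writer()
  bw_string(w, name)
  bw_u32(w, 0x3F)           # all channels present
  bw_f32(w, c(m$ambient, m$diffuse, m$specular, m$emissive,
              m$reflectivity, m$opacity))
  u3d_block(U3D_BLOCK$material_resource, bw_bytes(w))
}

blk_shader <- function(name, material_name, blended) {
  w <- bit_writer()
  bw_string(w, name)
  bw_u32(w, SHADER_LIGHTING + if (blended) SHADER_ALPHA_BLEND else 0)
  bw_f32(w, 0)              # alpha test reference
  bw_u32(w, c(0,            # alpha test function (always pass)
              if (blended) 1 else 0,  # framebuffer blend function
              1,            # render pass enabled
              0, 0))        # shader channels, alpha texture channels
  bw_string(w, material_name)
  u3d_block(U3D_BLOCK$lit_shader, bw_bytes(w))
}

#' Build shader and material resource blocks for a scene
#'
#' Materials are deduplicated: models with identical colour/opacity share
#' one material resource and one untextured lit shader. An opacity below 1
#' switches the shader onto the alpha-blending path.
#'
#' @param scene A `u3d_scene`.
#' @return A list with `blocks` (list of `u3d_block`) and `shader_names`
#'   (named character: model node name -> shader name).
#' @keywords internal
encode_shading_resources <- function(scene) {
  models <- scene_model_nodes(scene)
  keys <- character(0)
  blocks <- list()
  shader_names <- character(0)
  for (nd in models) {
    key <- material_key(nd$material)
    pos <- match(key, keys)
    if (is.na(pos)) {
      keys <- c(keys, key)
      pos <- length(keys)
      mat_name <- sprintf("Material_%d", pos)
      shd_name <- sprintf("Shader_%d", pos)
      blended <- nd$material$opacity < 1
      blocks[[length(blocks) + 1L]] <- blk_shader(shd_name, mat_name, blended)
      blocks[[length(blocks) + 1L]] <- blk_material(mat_name, nd$material)
    }
    shader_names[[nd$name]] <- sprintf("Shader_%d", pos)
  }
  list(blocks = blocks, shader_names = shader_names)
}

# ---- geometry blocks -------------------------------------------------------

shading_description <- function(w) {
  bw_u32(w, c(0, 0, 0))     # attributes, texture layer count, original id
  w
}

quantize_positions <- function(positions, quant) {
  fq <- as_f32(quant)
  q <- round(positions * fq)
  if (any(abs(q) >= 2^31))
    stop("position quantization overflow; lower position_quant or rescale the model",
         call. = FALSE)
  q
}

write_quantized_positions <- function(w, positions, quant) {
  q <- quantize_positions(positions, quant)
  ctxs <- c(CTX_POS_X, CTX_POS_Y, CTX_POS_Z)
  for (ax in 1:3) {
    d <- diff(c(0, q[, ax]))               # predict from the previous point
    zig <- ifelse(d >= 0, 2 * d, -2 * d - 1)
    bw_compressed(w, ctxs[ax], zig)
  }
  w
}

# corner indices: uniform static context when the index set is small enough,
# raw u32 words otherwise (the reader derives the same choice from the count)
write_position_indices <- function(w, idx0, n_positions) {
  if (n_positions <= STATIC_MAX) {
    bw_compressed(w, STATIC_CTX + n_positions, idx0)
  } else {
    bw_u32(w, idx0)
  }
  w
}

geometry_decl_tail <- function(w, quant) {
  bw_f32(w, c(quant$position, quant$normal))  # inverse quantization factors
  bw_u32(w, c(0, 0))                           # reserved resource parameters
  w
}

#' Encode a point cloud as declaration + continuation blocks
#'
#' The declaration announces the counts and quantization factors; the
#' continuation stores zigzagged, quantized position differences in the
#' per-axis dynamic contexts. Decoded positions land within
#' `0.5 / position_quant` of the originals on every axis.
#'
#' @param resource A non-empty [u3d_point_cloud()].
#' @param name Resource name on disk.
#' @param quant List with `position` and `normal` quantization factors.
#' @return A list with elements `declaration` and `continuation`.
#' @keywords internal
encode_point_set <- function(resource, name, quant) {
  n <- nrow(resource$positions)
  if (n == 0) stop("cannot encode an empty point set", call. = FALSE)
  d <- bit_writer()
  bw_string(d, name)
  bw_u32(d, c(0, 0))        # chain index, reserved
  bw_u32(d, c(n, n, 0, 0, 0, 0, 1))  # points, positions, normals, diffuse,
                                     # specular, texcoord, shading count
  shading_description(d)
  geometry_decl_tail(d, quant)

  cont <- bit_writer()
  bw_string(cont, name)
  bw_u32(cont, 0)           # chain index
  write_quantized_positions(cont, resource$positions, quant$position)

  list(declaration = u3d_block(U3D_BLOCK$point_set_declaration, bw_bytes(d)),
       continuation = u3d_block(U3D_BLOCK$point_set_continuation,
                                bw_bytes(cont), continuation = TRUE))
}

#' Encode a line set as declaration + continuation blocks
#'
#' Positions are quantized like point clouds; each edge stores its two
#' 0-based endpoint indices in dedicated dynamic contexts.
#'
#' @param resource A [u3d_line_set()] with in-range edges.
#' @inheritParams encode_point_set
#' @return A list with elements `declaration` and `continuation`.
#' @keywords internal
encode_line_set <- function(resource, name, quant) {
  n <- nrow(resource$positions)
  if (n == 0) stop("cannot encode an empty line set", call. = FALSE)
  ne <- nrow(resource$edges)
  d <- bit_writer()
  bw_string(d, name)
  bw_u32(d, c(0, 0))
  bw_u32(d, c(ne, n, 0, 0, 0, 0, 1))  # lines, positions, ...
  shading_description(d)
  geometry_decl_tail(d, quant)

  cont <- bit_writer()
  bw_string(cont, name)
  bw_u32(cont, 0)
  write_quantized_positions(cont, resource$positions, quant$position)
  if (ne) {
    bw_compressed(cont, CTX_EDGE_A, resource$edges[, 1] - 1)
    bw_compressed(cont, CTX_EDGE_B, resource$edges[, 2] - 1)
  }
  list(declaration = u3d_block(U3D_BLOCK$line_set_declaration, bw_bytes(d)),
       continuation = u3d_block(U3D_BLOCK$line_set_continuation,
                                bw_bytes(cont), continuation = TRUE))
}

#' Encode a triangle mesh as declaration + base-mesh continuation blocks
#'
#' The mesh is written as a single full-resolution base mesh (minimum
#' resolution = maximum resolution = vertex count; no progressive levels of
#' detail). Positions and normals are raw 32-bit floats, so they decode
#' bit-exactly; face corner indices are coded in a uniform static context
#' sized by the vertex count.
#'
#' @param resource A [u3d_mesh()]; must carry normals unless
#'   `write_normals` is `FALSE`.
#' @param write_normals Include per-vertex normals.
#' @inheritParams encode_point_set
#' @return A list with elements `declaration` and `continuation`.
#' @keywords internal
encode_mesh <- function(resource, name, quant, write_normals = TRUE) {
  n <- nrow(resource$positions)
  if (n == 0) stop("cannot encode an empty mesh", call. = FALSE)
  nf <- nrow(resource$faces)
  if (write_normals && is.null(resource$normals))
    stop("mesh has no normals; compute_vertex_normals() first or disable write_normals",
         call. = FALSE)
  nn <- if (write_normals) n else 0L
  attrs <- if (write_normals) 0 else MESH_ATTR_EXCLUDE_NORMALS

  d <- bit_writer()
  bw_string(d, name)
  bw_u32(d, 0)              # chain index
  bw_u32(d, attrs)
  bw_u32(d, c(nf, n, nn, 0, 0, 0, 1))  # faces, positions, normals, ...
  shading_description(d)
  bw_u32(d, c(n, n))        # minimum resolution = maximum resolution
  geometry_decl_tail(d, quant)

  cont <- bit_writer()
  bw_string(cont, name)
  bw_u32(cont, 0)
  bw_u32(cont, c(nf, n, nn))
  bw_f32(cont, as.numeric(t(resource$positions)))
  if (write_normals) bw_f32(cont, as.numeric(t(resource$normals)))
  if (nf) {
    # per-face shading id over a single-entry uniform context (zero bits)
    bw_compressed(cont, STATIC_CTX + 1, rep(0, nf))
    write_position_indices(cont, as.numeric(t(resource$faces)) - 1, n)
  }
  list(declaration = u3d_block(U3D_BLOCK$mesh_declaration, bw_bytes(d)),
       continuation = u3d_block(U3D_BLOCK$base_mesh_continuation,
                                bw_bytes(cont), continuation = TRUE))
}

# ---- light / view ----------------------------------------------------------

encode_light_view_defaults <- function(scene, config) {
  blocks <- list()
  root <- scene$root$name
  if (config$emit_default_lighting) {
    res <- bit_writer()
    bw_string(res, "DefaultLightResource")
    bw_u32(res, c(1, 0))    # attributes (enabled), type 0 = ambient
    bw_f32(res, c(1, 1, 1, 1))  # colour + intensity
    blocks[[length(blocks) + 1L]] <-
      u3d_block(U3D_BLOCK$light_resource, bw_bytes(res))
    nd <- node_header(bit_writer(), "DefaultLight", root, diag(4))
    bw_string(nd, "DefaultLightResource")
    blocks[[length(blocks) + 1L]] <- u3d_block(
      U3D_BLOCK$modifier_chain,
      chain_data("DefaultLight", CHAIN_NODE,
                 list(frame_block(u3d_block(U3D_BLOCK$light_node, bw_bytes(nd))))))
  }
  if (config$emit_default_view) {
    bb <- scene_bbox(scene)
    target <- (bb[1, ] + bb[2, ]) / 2
    diag_len <- sqrt(sum((bb[2, ] - bb[1, ])^2))
    res <- bit_writer()
    bw_string(res, "DefaultViewResource")
    bw_u32(res, 0)          # fog disabled
    blocks[[length(blocks) + 1L]] <-
      u3d_block(U3D_BLOCK$view_resource, bw_bytes(res))
    nd <- node_header(bit_writer(), "DefaultView", root, diag(4))
    bw_string(nd, "DefaultViewResource")
    bw_u32(nd, 0)           # attributes: perspective projection
    bw_f32(nd, c(0.01, max(3 * diag_len, 10) * 100,  # near / far clip
                 34.515,                              # vertical field of view
                 target,                              # framing target
                 max(2 * diag_len, 1)))               # eye distance
    blocks[[length(blocks) + 1L]] <- u3d_block(
      U3D_BLOCK$modifier_chain,
      chain_data("DefaultView", CHAIN_NODE,
                 list(frame_block(u3d_block(U3D_BLOCK$view_node, bw_bytes(nd))))))
  }
  blocks
}

scene_bbox <- function(scene) {
  models <- scene_model_nodes(scene)
  refs <- unique(vapply(models, `[[`, character(1), "geometry_ref"))
  if (length(refs) == 0) return(rbind(c(0, 0, 0), c(0, 0, 0)))
  pts <- do.call(rbind, lapply(refs, function(r) scene$resources[[r]]$positions))
  rbind(apply(pts, 2, min), apply(pts, 2, max))
}

# ---- file assembly ---------------------------------------------------------

#' Write a scene to a U3D file
#'
#' Serializes the scene to an ECMA-363 U3D byte stream: validates the
#' geometry (degenerate faces and zero-length edges are dropped with a
#' warning; unresolvable references abort before any bytes are produced),
#' computes missing mesh normals, deduplicates materials and emits the
#' block sequence. Output is deterministic: the same scene and
#' configuration always produce the identical byte stream.
#'
#' @param scene A `u3d_scene`.
#' @param file Output path, or `NULL` to only return the bytes.
#' @param config A [u3d_config()].
#' @return The U3D byte stream as a raw vector, invisibly when `file` is
#'   given.
#' @examples
#' sc <- u3d_scene()
#' sc <- u3d_add_resource(sc, "cube", make_fixture("cube_mesh"))
#' sc <- u3d_add_model(sc, "Cube", "cube", diffuse = c(1, 0, 0))
#' bytes <- write_u3d(sc)
#' @export
write_u3d <- function(scene, file = NULL, config = u3d_config()) {
  stopifnot(inherits(scene, "u3d_scene"), inherits(config, "u3d_config"))
  if (!is.null(config$root_node_name))
    scene$root$name <- config$root_node_name

  models <- scene_model_nodes(scene)
  for (nd in models) {
    if (!nd$geometry_ref %in% names(scene$resources))
      stop(sprintf("model '%s' references unknown geometry '%s'",
                   nd$name, nd$geometry_ref), call. = FALSE)
  }
  used <- unique(vapply(models, `[[`, character(1), "geometry_ref"))
  # clean + complete geometries (only validated/encoded when referenced)
  for (id in used) {
    g <- drop_degenerate(scene$resources[[id]])
    if (inherits(g, "u3d_mesh") && config$write_normals)
      g <- compute_vertex_normals(g)
    scene$resources[[id]] <- g
  }

  quant <- list(position = as_f32(config$position_quant),
                normal = as_f32(config$normal_quant))

  shading <- encode_shading_resources(scene)
  blocks <- c(encode_node_blocks(scene, shading$shader_names),
              shading$blocks,
              encode_light_view_defaults(scene, config))
  continuations <- list()
  for (id in used) {
    g <- scene$resources[[id]]
    enc <- switch(u3d_geometry_kind(g),
      pointset = encode_point_set(g, id, quant),
      lineset = encode_line_set(g, id, quant),
      mesh = encode_mesh(g, id, quant, config$write_normals))
    blocks[[length(blocks) + 1L]] <- u3d_block(
      U3D_BLOCK$modifier_chain,
      chain_data(id, CHAIN_MODEL_RESOURCE,
                 list(frame_block(enc$declaration))))
    continuations[[length(continuations) + 1L]] <- enc$continuation
  }
  # the declaration section is contiguous: continuations all come last
  blocks <- c(blocks, continuations)

  metadata <- scene$metadata
  cm <- config$creator_metadata
  if (length(cm)) metadata[names(cm)] <- cm
  meta <- metadata_bytes(metadata)

  framed <- lapply(blocks, frame_block)
  extents <- vapply(framed, length, integer(1))
  header_extent <- 12L + pad4(24L) + pad4(length(meta))
  decl_size <- header_extent +
    sum(extents[!vapply(blocks, `[[`, logical(1), "continuation")])
  file_size <- header_extent + sum(extents)

  h <- bit_writer()
  bw_u32(h, c(0, 0))        # version, profile identifier
  bw_u32(h, decl_size)
  bw_u64(h, file_size)
  bw_u32(h, U3D_CHAR_ENCODING_UTF8)
  header <- u3d_block(U3D_BLOCK$file_header, bw_bytes(h), meta = meta)

  out <- bit_writer()
  bw_raw(out, frame_block(header))
  for (fb in framed) bw_raw(out, fb)
  bytes <- bw_bytes(out)
  if (!is.null(file)) {
    writeBin(bytes, file)
    return(invisible(bytes))
  }
  bytes
}
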