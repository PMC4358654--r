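# Block-type codes and codec context assignments for the emitted U3D subset.
#
# The file-level framing follows ECMA-363: a file is a sequence of 32-bit
# aligned blocks, each `type, data size, metadata size` (32-bit little-endian
# words) followed by the data and metadata payloads, zero-padded to 32-bit
# boundaries; declared sizes count unpadded bytes. The file-header type code
# spells 'U' '3' 'D' \0 in little-endian byte order.

U3D_BLOCK <- list(
  file_header       = 0x00443355,
  modifier_chain    = 0xFFFFFF14,
  priority_update   = 0xFFFFFF15,
  group_node        = 0xFFFFFF21,
  model_node        = 0xFFFFFF22,
  light_node        = 0xFFFFFF23,
  view_node         = 0xFFFFFF24,
  mesh_declaration  = 0xFFFFFF31,
  point_set_declaration = 0xFFFFFF36,
  line_set_declaration  = 0xFFFFFF37,
  base_mesh_continuation  = 0xFFFFFF3B,
  point_set_continuation  = 0xFFFFFF3E,
  line_set_continuation   = 0xFFFFFF3F,
  shading_modifier  = 0xFFFFFF45,
  light_resource    = 0xFFFFFF51,
  view_resource     = 0xFFFFFF52,
  lit_shader        = 0xFFFFFF53,
  material_resource = 0xFFFFFF54
)

u3d_block_kind <- function(type) {
  hit <- names(U3D_BLOCK)[vapply(U3D_BLOCK, identical, logical(1), type)]
  if (length(hit)) hit[[1]] else "unknown"
}

# modifier chain types
CHAIN_NODE <- 0
CHAIN_MODEL_RESOURCE <- 1

# dynamic compression contexts (per continuation block, state starts fresh)
CTX_POS_X <- 1   # zigzagged quantized x-coordinate differences
CTX_POS_Y <- 2
CTX_POS_Z <- 3
CTX_EDGE_A <- 4  # first / second edge endpoint (0-based position index)
CTX_EDGE_B <- 5

# static contexts: STATIC_CTX + n codes a value uniformly in [0, n)
STATIC_CTX <- 0x400
STATIC_MAX <- 0x3FFF  # largest uniform range; larger index sets fall back to u32

# mesh declaration attribute flags
MESH_ATTR_EXCLUDE_NORMALS <- 1

# shading modifier attribute flags (which renderer paths the modifier drives)
SHADING_MESH <- 1
SHADING_LINE <- 2
SHADING_POINT <- 4

# lit shader attribute flags
SHADER_LIGHTING <- 1
SHADER_ALPHA_BLEND <- 2

U3D_CHAR_ENCODING_UTF8 <- 106
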