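#' Bit-stream writer for the U3D codec
#'
#' Creates a stateful bit-level writer backing the U3D serializer. The writer
#' exposes two channels that share one bit stream: fixed-width little-endian
#' values (`u8`/`u16`/`u32`/`u64`/`f32`/`f64`/length-prefixed strings, bits
#' packed least-significant first) and context-compressed values coded by a
#' 16-bit adaptive arithmetic coder. Dynamic contexts (1 to 1023) maintain a
#' per-context symbol histogram with an escape mechanism: a value unseen in
#' its context is escaped to a raw 32-bit write and then enters the
#' histogram. Static contexts (`1024 + n`) code a value in `[0, n)` with a
#' uniform model and carry no state.
#'
#' Every write primitive has a matching read primitive on [bit_reader()] such
#' that reading back under the same call/context sequence recovers every
#' value exactly.
#'
#' @return An object of class `u3d_bit_writer`.
#' @seealso [bit_reader()]
#' @examples
#' w <- bit_writer()
#' bw_u32(w, 1)
#' bw_bytes(w)  # 01 00 00 00
#' @export
bit_writer <- function() {
  structure(list(ptr = cpp_bw_new()), class = "u3d_bit_writer")
}

#' Bit-stream reader for the U3D codec
#'
#' The decoding counterpart of [bit_writer()]. Reads must be issued in the
#' same order, with the same compression contexts, as the writes that
#' produced the stream; the adaptive histograms on both sides then evolve
#' identically and every value is recovered exactly.
#'
#' @param bytes Raw vector, as returned by [bw_bytes()].
#' @return An object of class `u3d_bit_reader`.
#' @export
bit_reader <- function(bytes) {
  stopifnot(is.raw(bytes))
  structure(list(ptr = cpp_br_new(bytes)), class = "u3d_bit_reader")
}

#' @rdname bit_writer
#' @param w A `u3d_bit_writer`.
#' @param x Numeric vector of whole numbers in the channel's range.
#' @export
bw_u8 <- function(w, x) { cpp_bw_u8(w$ptr, as.numeric(x)); invisible(w) }
#' @rdname bit_writer
#' @export
bw_u16 <- function(w, x) { cpp_bw_u16(w$ptr, as.numeric(x)); invisible(w) }
#' @rdname bit_writer
#' @export
bw_u32 <- function(w, x) { cpp_bw_u32(w$ptr, as.numeric(x)); invisible(w) }
#' @rdname bit_writer
#' @export
bw_u64 <- function(w, x) { cpp_bw_u64(w$ptr, as.numeric(x)); invisible(w) }
#' @rdname bit_writer
#' @export
bw_f32 <- function(w, x) { cpp_bw_f32(w$ptr, as.numeric(x)); invisible(w) }
#' @rdname bit_writer
#' @export
bw_f64 <- function(w, x) { cpp_bw_f64(w$ptr, as.numeric(x)); invisible(w) }
#' @rdname bit_writer
#' @param s A single character string (encoded as UTF-8 bytes with a 16-bit
#'   length prefix).
#' @export
bw_string <- function(w, s) {
  cpp_bw_string(w$ptr, enc2utf8(as.character(s)[1]))
  invisible(w)
}
#' @rdname bit_writer
#' @param context Compression context: 1-1023 dynamic, `1024 + n` static
#'   uniform over `[0, n)`.
#' @export
bw_compressed <- function(w, context, x) {
  cpp_bw_compressed(w$ptr, as.numeric(context), as.numeric(x))
  invisible(w)
}
#' @rdname bit_writer
#' @param bytes Raw vector appended verbatim (requires byte alignment).
#' @export
bw_raw <- function(w, bytes) { cpp_bw_raw(w$ptr, bytes); invisible(w) }
#' @rdname bit_writer
#' @export
bw_align4 <- function(w) { cpp_bw_align4(w$ptr); invisible(w) }
#' @rdname bit_writer
#' @export
bw_bytes <- function(w) cpp_bw_bytes(w$ptr)

#' @rdname bit_reader
#' @param r A `u3d_bit_reader`.
#' @param n Number of values to read.
#' @export
br_u8 <- function(r, n = 1) cpp_br_u8(r$ptr, as.integer(n))
#' @rdname bit_reader
#' @export
br_u16 <- function(r, n = 1) cpp_br_u16(r$ptr, as.integer(n))
#' @rdname bit_reader
#' @export
br_u32 <- function(r, n = 1) cpp_br_u32(r$ptr, as.integer(n))
#' @rdname bit_reader
#' @export
br_u64 <- function(r, n = 1) cpp_br_u64(r$ptr, as.integer(n))
#' @rdname bit_reader
#' @export
br_f32 <- function(r, n = 1) cpp_br_f32(r$ptr, as.integer(n))
#' @rdname bit_reader
#' @export
br_f64 <- function(r, n = 1) cpp_br_f64(r$ptr, as.integer(n))
#' @rdname bit_reader
#' @export
br_string <- function(r) cpp_br_string(r$ptr)
#' @rdname bit_reader
#' @param context Compression context, as for [bw_compressed()].
#' @export
br_compressed <- function(r, context, n = 1) {
  cpp_br_compressed(r$ptr, as.numeric(context), as.integer(n))
}
#' @rdname bit_reader
#' @export
br_align4 <- function(r) { cpp_br_align4(r$ptr); invisible(r) }
#' @rdname bit_reader
#' @export
br_pos <- function(r) cpp_br_pos(r$ptr)

#' Round a numeric vector to 32-bit float precision
#'
#' U3D stores mesh coordinates and all quality factors as IEEE-754 single
#' precision. `as_f32()` applies that rounding in R, which is useful when
#' asserting that decoded values are bit-exact.
#'
#' @param x Numeric vector.
#' @return Numeric vector, each element representable as a 32-bit float.
#' @export
as_f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}
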