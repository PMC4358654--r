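# Triangle-mesh interchange: a Wavefront OBJ subset (v / vn / f, ASCII) and
# ASCII PLY. Faces with more than three corners are fan-triangulated from
# their first corner. Both readers return a u3d_mesh with 1-based indices.

obj_tokens <- function(line) {
  strsplit(trimws(line), "[ \t]+")[[1]]
}

#' Read a Wavefront OBJ mesh (ASCII subset)
#'
#' Supports `v` (vertex position), `vn` (vertex normal) and `f` (face)
#' records plus `#` comments; any other record type is skipped and counted
#' in a single summary warning. OBJ's 1-based and negative (relative)
#' indices are resolved; polygonal faces are fan-triangulated from the
#' first corner. Face corners of the form `v/vt/vn` keep only the position
#' index. `vn` records are attached as per-vertex normals when exactly one
#' normal per vertex is present (normalized if needed), otherwise dropped.
#'
#' @param file Path or connection; ignored when `text` is given.
#' @param text Optional literal OBJ text.
#' @return A [u3d_mesh()].
#' @export
read_obj <- function(file, text = NULL) {
  lines <- if (!is.null(text))
    unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  else readLines(file, warn = FALSE)
  positions <- list(); normals <- list(); faces <- list()
  skipped <- character(0)
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[ln]])
    if (!nzchar(trimws(line))) next
    tok <- obj_tokens(line)
    key <- tok[[1]]
    if (key == "v") {
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (length(tok) < 4L || any(is.na(xyz)))
        stop(sprintf("line %d: malformed vertex record", ln), call. = FALSE)
      positions[[length(positions) + 1L]] <- xyz
    } else if (key == "vn") {
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (length(tok) < 4L || any(is.na(xyz)))
        stop(sprintf("line %d: malformed normal record", ln), call. = FALSE)
      normals[[length(normals) + 1L]] <- xyz
    } else if (key == "f") {
      if (length(tok) < 4L)
        stop(sprintf("line %d: face needs at least 3 corners", ln), call. = FALSE)
      nv <- length(positions)
      idx <- vapply(tok[-1], function(t) {
        i <- suppressWarnings(as.integer(strsplit(t, "/", fixed = TRUE)[[1]][1]))
        if (is.na(i) || i == 0L)
          stop(sprintf("line %d: malformed face index '%s'", ln, t),
               call. = FALSE)
        if (i < 0L) i <- nv + i + 1L  # -1 refers to the last vertex so far
        if (i < 1L || i > nv)
          stop(sprintf("line %d: face references nonexistent vertex %s", ln, t),
               call. = FALSE)
        i
      }, integer(1))
      for (k in seq_len(length(idx) - 2L))
        faces[[length(faces) + 1L]] <- c(idx[1], idx[k + 1L], idx[k + 2L])
    } else {
      skipped <- c(skipped, key)
    }
  }
  if (length(skipped))
    warning(sprintf("ignored %d unsupported OBJ record(s): %s",
                    length(skipped),
                    paste(sprintf("%s (%d)", names(table(skipped)),
                                  as.integer(table(skipped))), collapse = ", ")),
            call. = FALSE)
  pos <- do.call(rbind, positions)
  if (is.null(pos)) stop("OBJ input contains no vertices", call. = FALSE)
  fcs <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), ncol = 3)
  nrm <- NULL
  if (length(normals)) {
    if (length(normals) == nrow(pos)) {
      nrm <- do.call(rbind, normals)
      nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), .Machine$double.eps)
    } else {
      warning("OBJ normals do not map one-to-one onto vertices; dropped",
              call. = FALSE)
    }
  }
  u3d_mesh(pos, fcs, nrm)
}

#' Write a mesh as Wavefront OBJ
#'
#' Minimal OBJ writer (v / vn / f), primarily used to round-trip fixtures
#' through [read_obj()].
#'
#' @param mesh A [u3d_mesh()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_obj <- function(mesh, file) {
  stopifnot(inherits(mesh, "u3d_mesh"))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$positions[, 1],
                     mesh$positions[, 2], mesh$positions[, 3]), con)
  if (!is.null(mesh$normals))
    writeLines(sprintf("vn %.17g %.17g %.17g", mesh$normals[, 1],
                       mesh$normals[, 2], mesh$normals[, 3]), con)
  if (nrow(mesh$faces))
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  invisible(file)
}

#' Read an ASCII PLY mesh
#'
#' Parses the `ply` header, locates the `x`, `y`, `z` vertex properties and
#' the face `vertex_indices` list, and fan-triangulates polygonal faces.
#' Extra per-vertex properties are ignored. Binary PLY variants are
#' rejected with an error naming the detected format.
#'
#' @param file Path or connection; ignored when `text` is given.
#' @param text Optional literal PLY text.
#' @return A [u3d_mesh()].
#' @export
read_ply_ascii <- function(file, text = NULL) {
  lines <- if (!is.null(text))
    unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  else readLines(file, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[[1]]) != "ply")
    stop("not a PLY file (missing 'ply' magic)", call. = FALSE)

  elements <- list()  # name -> list(count, properties)
  current <- NULL
  body_start <- NA_integer_
  for (ln in 2:length(lines)) {
    tok <- obj_tokens(lines[[ln]])
    if (length(tok) == 0) next
    switch(tok[[1]],
      format = {
        if (!identical(tok[[2]], "ascii"))
          stop(sprintf("unsupported PLY format '%s' (only ascii is supported)",
                       tok[[2]]), call. = FALSE)
      },
      comment = NULL,
      element = {
        if (!is.null(current)) elements[[current$name]] <- current
        current <- list(name = tok[[2]], count = as.integer(tok[[3]]),
                        properties = character(0), list_props = character(0))
      },
      property = {
        if (is.null(current))
          stop("PLY property outside an element", call. = FALSE)
        if (identical(tok[[2]], "list")) {
          current$list_props <- c(current$list_props, tok[[length(tok)]])
          current$properties <- c(current$properties,
                                  paste0("list:", tok[[length(tok)]]))
        } else {
          current$properties <- c(current$properties, tok[[length(tok)]])
        }
      },
      end_header = {
        if (!is.null(current)) elements[[current$name]] <- current
        body_start <- ln + 1L
        break
      },
      ply = NULL,
      NULL)
  }
  if (is.na(body_start)) stop("PLY header missing end_header", call. = FALSE)
  if (is.null(elements$vertex)) stop("PLY file has no vertex element", call. = FALSE)

  body <- lines[seq(body_start, length.out = length(lines) - body_start + 1L)]
  body <- body[nzchar(trimws(body))]
  pos_at <- 1L
  pos <- NULL; fcs <- matrix(integer(0), ncol = 3)
  for (el in elements) {
    if (pos_at + el$count - 1L > length(body))
      stop(sprintf("PLY body truncated: element '%s' declares %d rows but only %d remain",
                   el$name, el$count, length(body) - pos_at + 1L), call. = FALSE)
    rows <- body[seq(pos_at, length.out = el$count)]
    pos_at <- pos_at + el$count
    if (el$name == "vertex") {
      ix <- match(c("x", "y", "z"), el$properties)
      if (any(is.na(ix)))
        stop("PLY vertex element lacks x/y/z properties", call. = FALSE)
      vals <- lapply(rows, function(r) suppressWarnings(as.numeric(obj_tokens(r))))
      bad <- which(vapply(vals, function(v) length(v) < max(ix) || any(is.na(v[ix])),
                          logical(1)))
      if (length(bad))
        stop(sprintf("PLY vertex row %d is malformed", bad[1]), call. = FALSE)
      pos <- t(vapply(vals, function(v) v[ix], numeric(3)))
    } else if (el$name == "face") {
      fl <- list()
      for (k in seq_along(rows)) {
        v <- suppressWarnings(as.integer(obj_tokens(rows[[k]])))
        if (length(v) < 1L || is.na(v[1]) || length(v) < 1L + v[1])
          stop(sprintf("PLY face row %d is malformed", k), call. = FALSE)
        idx <- v[2:(1L + v[1])] + 1L  # PLY indices are 0-based
        for (j in seq_len(length(idx) - 2L))
          fl[[length(fl) + 1L]] <- c(idx[1], idx[j + 1L], idx[j + 2L])
      }
      if (length(fl)) fcs <- do.call(rbind, fl)
    }
    # other elements: rows consumed and ignored
  }
  if (is.null(pos)) stop("PLY file has no vertex data", call. = FALSE)
  if (nrow(fcs) && max(fcs) > nrow(pos))
    stop("PLY face references nonexistent vertex", call. = FALSE)
  u3d_mesh(pos, fcs)
}
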