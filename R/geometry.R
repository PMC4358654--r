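# Geometry resources: point clouds, line sets, triangle meshes.
# Positions are n x 3 numeric matrices in model units (passed through
# unchanged; a right-handed coordinate system is assumed, matching U3D
# viewers). Edge and face indices are 1-based in R; they are converted to
# 0-based indices on the U3D byte stream and when reading 0-based text files.

as_position_matrix <- function(positions, what = "positions") {
  if (is.data.frame(positions)) positions <- as.matrix(positions)
  if (is.numeric(positions) && is.null(dim(positions)) &&
      length(positions) %% 3 == 0) {
    positions <- matrix(positions, ncol = 3, byrow = TRUE)
  }
  if (!is.matrix(positions) || !is.numeric(positions) || ncol(positions) != 3)
    stop(what, " must be an n x 3 numeric matrix", call. = FALSE)
  if (any(!is.finite(positions)))
    stop(what, " must be finite (no NA/NaN/Inf)", call. = FALSE)
  storage.mode(positions) <- "double"
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  positions
}

as_index_matrix <- function(idx, ncol, what) {
  if (is.data.frame(idx)) idx <- as.matrix(idx)
  if (is.numeric(idx) && is.null(dim(idx)) && length(idx) %% ncol == 0)
    idx <- matrix(idx, ncol = ncol, byrow = TRUE)
  if (!is.matrix(idx) || !is.numeric(idx) || ncol(idx) != ncol)
    stop(what, " must be an m x ", ncol, " index matrix", call. = FALSE)
  if (any(!is.finite(idx)) || any(idx != floor(idx)))
    stop(what, " indices must be whole numbers", call. = FALSE)
  storage.mode(idx) <- "integer"
  dimnames(idx) <- NULL
  idx
}

#' Create a point cloud geometry resource
#'
#' The simplest exportable geometry: a bare list of 3D point positions.
#'
#' @param positions An n x 3 numeric matrix (or a length-3k vector, taken
#'   row-wise) of finite point coordinates.
#' @return An object of class `u3d_point_cloud` / `u3d_geometry`.
#' @examples
#' u3d_point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)))
#' @export
u3d_point_cloud <- function(positions) {
  structure(list(positions = as_position_matrix(positions)),
            class = c("u3d_point_cloud", "u3d_geometry"))
}

#' Create a line set (polyline) geometry resource
#'
#' A line set consists of nodes connected by edges. When `edges` is omitted
#' the connections are derived automatically by joining each node to the
#' next one in the list (see [auto_connect()]), which is the natural layout
#' for trajectories such as vectorcardiograms or vessel centerlines.
#'
#' @param positions An n x 3 numeric matrix of node coordinates.
#' @param edges An m x 2 matrix of 1-based node indices, or `NULL` to
#'   connect consecutive nodes.
#' @return An object of class `u3d_line_set` / `u3d_geometry`.
#' @examples
#' helix <- cbind(cos(1:50 / 5), sin(1:50 / 5), 1:50 / 25)
#' u3d_line_set(helix)  # 49 chain edges
#' @export
u3d_line_set <- function(positions, edges = NULL) {
  positions <- as_position_matrix(positions)
  if (is.null(edges)) {
    edges <- auto_connect(nrow(positions))
  } else {
    edges <- as_index_matrix(edges, 2L, "edges")
  }
  structure(list(positions = positions, edges = edges),
            class = c("u3d_line_set", "u3d_geometry"))
}

#' Create a triangle mesh geometry resource
#'
#' @param positions An n x 3 numeric matrix of vertex coordinates.
#' @param faces An m x 3 matrix of 1-based vertex indices with
#'   counter-clockwise winding for outward-facing normals.
#' @param normals Optional n x 3 matrix of unit per-vertex normals; computed
#'   on export with [compute_vertex_normals()] when absent.
#' @return An object of class `u3d_mesh` / `u3d_geometry`.
#' @export
u3d_mesh <- function(positions, faces, normals = NULL) {
  positions <- as_position_matrix(positions)
  faces <- as_index_matrix(faces, 3L, "faces")
  if (!is.null(normals)) {
    normals <- as_position_matrix(normals, "normals")
    if (nrow(normals) != nrow(positions))
      stop("normals must have one row per vertex", call. = FALSE)
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("normals must have unit length (within 1e-6)", call. = FALSE)
  }
  structure(list(positions = positions, faces = faces, normals = normals),
            class = c("u3d_mesh", "u3d_geometry"))
}

u3d_geometry_kind <- function(geometry) {
  if (inherits(geometry, "u3d_point_cloud")) return("pointset")
  if (inherits(geometry, "u3d_line_set")) return("lineset")
  if (inherits(geometry, "u3d_mesh")) return("mesh")
  stop("not a u3d geometry resource", call. = FALSE)
}

#' Chain connections for an ordered node list
#'
#' Returns the edge list that joins each node to the next one:
#' `(1,2), (2,3), ..., (n-1, n)`. This is the rule applied when a line set
#' is supplied without an explicit connection list.
#'
#' @param n_positions Number of nodes (non-negative integer).
#' @return A `max(n-1, 0)` x 2 integer matrix of 1-based index pairs.
#' @examples
#' auto_connect(5)  # 4 edges
#' auto_connect(1)  # none
#' @export
auto_connect <- function(n_positions) {
  n <- as.integer(n_positions)
  if (is.na(n) || n < 0) stop("n_positions must be a non-negative integer")
  if (n <= 1L) return(matrix(integer(0), ncol = 2))
  cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L, deparse.level = 0)
}

#' Validate a geometry resource
#'
#' Checks the structural invariants of a geometry resource and reports every
#' violation found. Degenerate faces (a repeated vertex index) and
#' zero-length edges (identical endpoints) are reported as droppable: the
#' encoder removes them, with a warning, before export.
#'
#' @param resource A `u3d_geometry` object.
#' @return A data frame with columns `kind` (issue class), `index` (1-based
#'   element index), `droppable` and `message`; zero rows when all
#'   invariants hold.
#' @examples
#' m <- u3d_mesh(diag(3), matrix(c(1, 2, 2), 1))
#' validate_geometry(m)  # one degenerate face
#' @export
validate_geometry <- function(resource) {
  issues <- list()
  add <- function(kind, index, droppable, message) {
    issues[[length(issues) + 1L]] <<-
      data.frame(kind = kind, index = index, droppable = droppable,
                 message = message, stringsAsFactors = FALSE)
  }
  npos <- nrow(resource$positions)
  if (any(!is.finite(resource$positions)))
    add("non_finite_position", which(!is.finite(resource$positions))[1],
        FALSE, "position contains NA/NaN/Inf")
  if (inherits(resource, "u3d_line_set")) {
    e <- resource$edges
    if (nrow(e)) {
      bad <- which(e[, 1] < 1L | e[, 2] < 1L | e[, 1] > npos | e[, 2] > npos)
      for (i in bad)
        add("index_out_of_range", i, FALSE,
            sprintf("edge %d references a position outside 1..%d", i, npos))
      dg <- setdiff(which(e[, 1] == e[, 2]), bad)
      for (i in dg)
        add("zero_length_edge", i, TRUE,
            sprintf("edge %d joins a node to itself", i))
    }
  }
  if (inherits(resource, "u3d_mesh")) {
    f <- resource$faces
    if (nrow(f)) {
      bad <- which(apply(f, 1, function(r) any(r < 1L | r > npos)))
      for (i in bad)
        add("index_out_of_range", i, FALSE,
            sprintf("face %d references a vertex outside 1..%d", i, npos))
      dg <- setdiff(which(f[, 1] == f[, 2] | f[, 1] == f[, 3] |
                          f[, 2] == f[, 3]), bad)
      for (i in dg)
        add("degenerate_face", i, TRUE,
            sprintf("face %d repeats a vertex index", i))
    }
    if (!is.null(resource$normals)) {
      if (nrow(resource$normals) != npos)
        add("normal_count_mismatch", 1L, FALSE,
            "normals must have one row per vertex")
      len <- sqrt(rowSums(resource$normals^2))
      for (i in which(abs(len - 1) > 1e-6))
        add("non_unit_normal", i, FALSE,
            sprintf("normal %d has length %.8f", i, len[i]))
    }
  }
  if (length(issues) == 0)
    return(data.frame(kind = character(0), index = integer(0),
                      droppable = logical(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

# remove droppable defects (degenerate faces, zero-length edges), warning once
drop_degenerate <- function(resource) {
  issues <- validate_geometry(resource)
  fatal <- issues[!issues$droppable, , drop = FALSE]
  if (nrow(fatal))
    stop("invalid geometry: ", fatal$message[1], call. = FALSE)
  drop <- issues[issues$droppable, , drop = FALSE]
  if (nrow(drop) == 0) return(resource)
  warning(sprintf("dropping %d degenerate element(s) before export", nrow(drop)),
          call. = FALSE)
  if (inherits(resource, "u3d_mesh")) {
    keep <- setdiff(seq_len(nrow(resource$faces)),
                    drop$index[drop$kind == "degenerate_face"])
    resource$faces <- resource$faces[keep, , drop = FALSE]
  }
  if (inherits(resource, "u3d_line_set")) {
    keep <- setdiff(seq_len(nrow(resource$edges)),
                    drop$index[drop$kind == "zero_length_edge"])
    resource$edges <- resource$edges[keep, , drop = FALSE]
  }
  resource
}

#' Compute area-weighted per-vertex normals
#'
#' Fills in per-vertex unit normals as the normalized, area-weighted average
#' of the incident face normals; face normals follow the counter-clockwise
#' winding right-hand rule. A mesh that already carries normals is returned
#' untouched. A vertex whose incident faces all have zero area (or that has
#' no incident face) receives the fallback normal (0, 0, 1), with a warning.
#'
#' @param mesh A `u3d_mesh`.
#' @return The mesh with a `normals` matrix of unit vectors.
#' @examples
#' m <- u3d_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), matrix(1:3, 1))
#' compute_vertex_normals(m)$normals  # all (0, 0, 1)
#' @export
compute_vertex_normals <- function(mesh) {
  stopifnot(inherits(mesh, "u3d_mesh"))
  if (!is.null(mesh$normals)) return(mesh)
  issues <- validate_geometry(mesh)
  if (any(issues$kind == "index_out_of_range"))
    stop("mesh has out-of-range face indices", call. = FALSE)
  p <- mesh$positions
  f <- mesh$faces
  acc <- matrix(0, nrow(p), 3)
  if (nrow(f)) {
    a <- p[f[, 1], , drop = FALSE]
    e1 <- p[f[, 2], , drop = FALSE] - a
    e2 <- p[f[, 3], , drop = FALSE] - a
    # cross(e1, e2): magnitude 2 * face area, direction by right-hand rule
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    for (c in 1:3) {
      acc[, 1] <- acc[, 1] + tabulate2(f[, c], cr[, 1], nrow(p))
      acc[, 2] <- acc[, 2] + tabulate2(f[, c], cr[, 2], nrow(p))
      acc[, 3] <- acc[, 3] + tabulate2(f[, c], cr[, 3], nrow(p))
    }
  }
  len <- sqrt(rowSums(acc^2))
  flat <- len < .Machine$double.eps * 64
  if (any(flat)) {
    warning(sprintf(
      "%d vertices have no non-degenerate incident face; using fallback normal (0,0,1)",
      sum(flat)), call. = FALSE)
    acc[flat, ] <- rep(c(0, 0, 1), each = sum(flat))
    len[flat] <- 1
  }
  mesh$normals <- acc / len
  dimnames(mesh$normals) <- list(NULL, c("x", "y", "z"))
  mesh
}

# sum `values` into bins 1..nbins given by `index` (empty bins stay 0)
tabulate2 <- function(index, values, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.u3d_geometry <- function(x, ...) {
  kind <- u3d_geometry_kind(x)
  n <- nrow(x$positions)
  extra <- switch(kind,
    pointset = sprintf("%d points", n),
    lineset = sprintf("%d nodes, %d edges", n, nrow(x$edges)),
    mesh = sprintf("%d vertices, %d faces%s", n, nrow(x$faces),
                   if (is.null(x$normals)) "" else ", with normals"))
  cat(sprintf("<u3d %s: %s>\n", kind, extra))
  invisible(x)
}
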