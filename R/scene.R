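# In-memory scene model: a geometry resource table plus a hierarchical node
# tree (group nodes and model nodes). A geometry resource may be referenced
# by any number of model nodes, which is how the exporter keeps files small
# when the same shape appears in several colours or groups.

#' Surface material for a model node
#'
#' Colour channels are clamped to `[0, 1]`. An opacity below 1 makes the
#' encoder enable the alpha-blending path of the object's shader, so the
#' object renders transparent in the PDF viewer. When `ambient` is omitted
#' it defaults to one tenth of the diffuse colour, a common neutral choice;
#' the remaining defaults give a matte mid-gray.
#'
#' @param diffuse,specular,ambient,emissive Length-3 RGB vectors in `[0, 1]`.
#' @param reflectivity,opacity Scalars in `[0, 1]`.
#' @return An object of class `u3d_material`.
#' @export
u3d_material <- function(diffuse = c(0.65, 0.65, 0.65),
                         specular = c(0.3, 0.3, 0.3),
                         ambient = 0.1 * diffuse,
                         emissive = c(0, 0, 0),
                         reflectivity = 0,
                         opacity = 1) {
  chan <- function(x, what, len = 3L) {
    x <- as.numeric(x)
    if (length(x) == 1L && len == 3L) x <- rep(x, 3L)
    if (length(x) != len || any(!is.finite(x)))
      stop(what, " must be ", len, " finite number(s)", call. = FALSE)
    pmin(pmax(x, 0), 1)
  }
  structure(list(diffuse = chan(diffuse, "diffuse"),
                 specular = chan(specular, "specular"),
                 ambient = chan(ambient, "ambient"),
                 emissive = chan(emissive, "emissive"),
                 reflectivity = chan(reflectivity, "reflectivity", 1L),
                 opacity = chan(opacity, "opacity", 1L)),
            class = "u3d_material")
}

material_key <- function(m) {
  paste(sprintf("%.17g", c(m$diffuse, m$specular, m$ambient, m$emissive,
                           m$reflectivity, m$opacity)), collapse = ",")
}

new_group_node <- function(name) {
  list(kind = "group", name = name, children = list())
}

#' Create an empty U3D scene
#'
#' A scene holds a single root group, a table of named geometry resources
#' and ordered key/value metadata that ends up as annotations on the file
#' header.
#'
#' @param root_name Name of the root group node.
#' @param metadata Named character vector of file-level metadata pairs.
#' @return An object of class `u3d_scene`.
#' @examples
#' sc <- u3d_scene(metadata = c(Title = "Vectorcardiogram"))
#' sc <- u3d_add_resource(sc, "pts", u3d_point_cloud(diag(3)))
#' sc <- u3d_add_model(sc, "Markers", "pts", path = "Fiducials")
#' @export
u3d_scene <- function(root_name = "Scene", metadata = character()) {
  if (!is.character(root_name) || length(root_name) != 1L || !nzchar(root_name))
    stop("root_name must be a non-empty string")
  md <- as.character(metadata)
  names(md) <- names(metadata)
  if (length(md) && (is.null(names(md)) || any(!nzchar(names(md)))))
    stop("metadata must be a named character vector")
  structure(list(root = new_group_node(root_name),
                 resources = list(),
                 metadata = md),
            class = "u3d_scene")
}

#' Register a geometry resource in a scene
#'
#' Resources live in a flat, uniquely named table and may be referenced by
#' any number of model nodes; adding several models over one resource never
#' duplicates the geometry in the file.
#'
#' @param scene A `u3d_scene`.
#' @param id Unique resource identifier (non-empty string).
#' @param geometry A `u3d_geometry` object.
#' @return The modified scene.
#' @export
u3d_add_resource <- function(scene, id, geometry) {
  stopifnot(inherits(scene, "u3d_scene"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("resource id must be a non-empty string")
  if (!inherits(geometry, "u3d_geometry"))
    stop("geometry must be a u3d_geometry object")
  if (id %in% names(scene$resources))
    stop(sprintf("resource id '%s' already exists", id))
  scene$resources[[id]] <- geometry
  scene
}

split_group_path <- function(path) {
  if (!is.character(path) || length(path) != 1L || is.na(path))
    stop("path must be a single string", call. = FALSE)
  if (!nzchar(path))
    stop("group path must not be empty (use \"/\" for the root)", call. = FALSE)
  if (identical(path, "/")) return(character(0))
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  # a leading or trailing '/' is tolerated; interior empty names are not
  n <- length(parts)
  if (n && !nzchar(parts[1])) parts <- parts[-1]
  n <- length(parts)
  if (n && !nzchar(parts[n])) parts <- parts[-n]
  if (length(parts) == 0 || any(!nzchar(parts)))
    stop("group path must be '/'-separated non-empty names", call. = FALSE)
  parts
}

# descend/create groups along `parts`; errors if a part names a model node
descend_create <- function(node, parts) {
  if (length(parts) == 0) return(node)
  nm <- parts[[1]]
  idx <- which(vapply(node$children, function(ch) ch$name == nm, logical(1)))
  if (length(idx) == 0) {
    child <- new_group_node(nm)
    child <- descend_create(child, parts[-1])
    node$children[[length(node$children) + 1L]] <- child
  } else {
    child <- node$children[[idx[1]]]
    if (child$kind != "group")
      stop(sprintf("path component '%s' is a model node, not a group", nm),
           call. = FALSE)
    node$children[[idx[1]]] <- descend_create(child, parts[-1])
  }
  node
}

#' Ensure a group path exists in the scene tree
#'
#' Creates any missing intermediate groups along a '/'-separated path and
#' reuses existing ones, so the operation is idempotent. `"/"` denotes the
#' root group itself.
#'
#' @param scene A `u3d_scene`.
#' @param path '/'-separated sequence of non-empty group names.
#' @return The modified scene. Use [u3d_get_node()] to retrieve the group.
#' @export
u3d_add_group <- function(scene, path) {
  stopifnot(inherits(scene, "u3d_scene"))
  parts <- split_group_path(path)
  scene$root <- descend_create(scene$root, parts)
  scene
}

#' Fetch a node by its group path
#'
#' @param scene A `u3d_scene`.
#' @param path '/'-separated path, `"/"` for the root group.
#' @return The node (a list), or `NULL` if the path does not exist.
#' @export
u3d_get_node <- function(scene, path) {
  stopifnot(inherits(scene, "u3d_scene"))
  parts <- split_group_path(path)
  node <- scene$root
  for (nm in parts) {
    idx <- which(vapply(node$children, function(ch) ch$name == nm, logical(1)))
    if (length(idx) == 0) return(NULL)
    node <- node$children[[idx[1]]]
  }
  node
}

#' Attach a model node to the scene tree
#'
#' A model node binds a geometry resource to a position in the object tree
#' together with its material. `spec` may be a plain character name (with
#' material and placement given via the other arguments) or a
#' [u3d_object_spec()], in which case name, group path, colours and opacity
#' are taken from the spec.
#'
#' A sibling name collision is resolved by suffixing `_2`, `_3`, ... with a
#' warning, so an export never aborts over a cosmetic clash.
#'
#' @param scene A `u3d_scene`.
#' @param spec Model name (string) or a `u3d_object_spec`.
#' @param geometry_ref Id of a registered resource; defaults to the spec's
#'   `geometry_id`.
#' @param path Group path under which to attach (ignored when `spec` is an
#'   object spec carrying its own `group_path`).
#' @param material A [u3d_material()] (ignored for object specs, which carry
#'   their own colours).
#' @param transform 4 x 4 transform matrix; default identity.
#' @param ... Shortcut material arguments (`diffuse`, `specular`, `opacity`,
#'   ...) forwarded to [u3d_material()] when `material` is not supplied.
#' @return The modified scene.
#' @export
u3d_add_model <- function(scene, spec, geometry_ref = NULL, path = "/",
                          material = NULL, transform = NULL, ...) {
  stopifnot(inherits(scene, "u3d_scene"))
  if (is.null(material)) material <- u3d_material(...)
  if (inherits(spec, "u3d_object_spec")) {
    spec <- apply_spec_defaults(spec)
    name <- spec$name
    path <- spec$group_path
    if (is.null(geometry_ref)) geometry_ref <- as.character(spec$geometry_id)
    material <- u3d_material(diffuse = spec$diffuse, specular = spec$specular,
                             opacity = spec$opacity)
  } else {
    name <- spec
  }
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("model name must be a non-empty string")
  if (is.null(geometry_ref) || !geometry_ref %in% names(scene$resources))
    stop(sprintf("geometry_ref '%s' does not resolve to a registered resource",
                 if (is.null(geometry_ref)) "<missing>" else geometry_ref))
  if (is.null(transform)) transform <- diag(4)
  if (!is.matrix(transform) || !all(dim(transform) == c(4, 4)))
    stop("transform must be a 4 x 4 matrix")
  if (nrow(scene$resources[[geometry_ref]]$positions) == 0)
    stop("referenced geometry has no positions")

  parts <- split_group_path(path)
  scene$root <- descend_create(scene$root, parts)

  attach_model <- function(node, parts) {
    if (length(parts) == 0) {
      sibs <- vapply(node$children, `[[`, character(1), "name")
      final <- name
      if (final %in% sibs) {
        k <- 2L
        while (sprintf("%s_%d", name, k) %in% sibs) k <- k + 1L
        final <- sprintf("%s_%d", name, k)
        warning(sprintf("sibling name '%s' already used; renamed to '%s'",
                        name, final), call. = FALSE)
      }
      node$children[[length(node$children) + 1L]] <-
        list(kind = "model", name = final, geometry_ref = geometry_ref,
             material = material, transform = transform)
      return(node)
    }
    idx <- which(vapply(node$children, function(ch) ch$name == parts[[1]],
                        logical(1)))
    node$children[[idx[1]]] <- attach_model(node$children[[idx[1]]], parts[-1])
    node
  }
  scene$root <- attach_model(scene$root, parts)
  scene
}

# flatten the tree to a data-frame-ish list of records, preorder,
# parents before children
flatten_nodes <- function(scene) {
  out <- list()
  walk <- function(node, parent) {
    rec <- list(kind = node$kind, name = node$name, parent = parent,
                geometry_ref = node$geometry_ref %||% NA_character_,
                material = node$material,
                transform = node$transform %||% diag(4))
    out[[length(out) + 1L]] <<- rec
    if (node$kind == "group")
      for (ch in node$children) walk(ch, node$name)
  }
  walk(scene$root, "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scene_model_nodes <- function(scene) {
  Filter(function(n) n$kind == "model", flatten_nodes(scene))
}

#' @export
print.u3d_scene <- function(x, ...) {
  nodes <- flatten_nodes(x)
  kinds <- vapply(nodes, `[[`, character(1), "kind")
  cat(sprintf("<u3d scene '%s': %d group(s), %d model(s), %d resource(s), %d metadata pair(s)>\n",
              x$root$name, sum(kinds == "group"), sum(kinds == "model"),
              length(x$resources), length(x$metadata)))
  walk <- function(node, depth) {
    lab <- if (node$kind == "group") node$name
           else sprintf("%s  [%s -> %s]", node$name, node$kind, node$geometry_ref)
    cat(strrep("  ", depth), "- ", lab, "\n", sep = "")
    if (node$kind == "group") for (ch in node$children) walk(ch, depth + 1)
  }
  walk(x$root, 0)
  invisible(x)
}
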