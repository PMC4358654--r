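# The object-specification language: a small XML-like syntax declaring what
# to export. One <U3DObject> record per exported object, with child tags
#
#   <ObjectType>     pointset | lineset | mesh           (required)
#   <GeometryID>     resource name or 0-based input index (required)
#   <ObjectName>     display name; auto-named "<type>_<ordinal>" if omitted
#   <GroupPath>      '/'-separated tree placement, default "/"
#   <Color>          diffuse "r g b", each in [0,1]
#   <SpecularColor>  "r g b"
#   <Opacity>        scalar in [0,1]
#   <MetaData>       <Key>..</Key><Value>..</Value>, repeatable
#
# Tags are case-insensitive and whitespace-tolerant. The vocabulary is this
# package's own (versioned here); no compatibility with any other tool's
# specification strings is claimed.

SPEC_TYPES <- c("pointset", "lineset", "mesh")

#' Default values for omitted object-spec fields
#'
#' @return A named list with the default diffuse and specular colours, the
#'   default opacity and the default group path.
#' @export
u3d_spec_defaults <- function() {
  list(diffuse = c(0.65, 0.65, 0.65),
       specular = c(0.3, 0.3, 0.3),
       opacity = 1,
       group_path = "/")
}

check_channel <- function(x, what, len = 3L) {
  x <- suppressWarnings(as.numeric(x))
  if (length(x) != len || any(is.na(x)))
    stop(sprintf("%s must be %d number(s)", what, len), call. = FALSE)
  if (any(x < 0 | x > 1))
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  x
}

#' Declarative specification of one exported object
#'
#' An object spec names an object, states its geometry kind, references a
#' geometry resource (by id or by 0-based input index) and carries its
#' placement in the object tree, colours, opacity and per-object metadata.
#' Optional fields may be left `NULL` and are filled by
#' [apply_spec_defaults()] (which [u3d_add_model()] and the encoder call for
#' you).
#'
#' @param object_type One of `"pointset"`, `"lineset"`, `"mesh"`.
#' @param geometry_id Resource identifier (string) or 0-based input index.
#' @param name Object name; `NULL` for the automatic `"<type>_<ordinal>"`.
#' @param group_path '/'-separated placement, `NULL` for the root.
#' @param diffuse,specular Length-3 RGB in `[0, 1]`, or `NULL`.
#' @param opacity Scalar in `[0, 1]`, or `NULL`.
#' @param metadata Named character vector of per-object metadata.
#' @return An object of class `u3d_object_spec`.
#' @export
u3d_object_spec <- function(object_type, geometry_id, name = NULL,
                            group_path = NULL, diffuse = NULL,
                            specular = NULL, opacity = NULL,
                            metadata = NULL) {
  object_type <- tolower(as.character(object_type)[1])
  if (!object_type %in% SPEC_TYPES)
    stop("object_type must be one of: ", paste(SPEC_TYPES, collapse = ", "),
         call. = FALSE)
  if (missing(geometry_id) || is.null(geometry_id) ||
      !nzchar(as.character(geometry_id)[1]))
    stop("geometry_id is required", call. = FALSE)
  if (!is.null(name) && (!is.character(name) || !nzchar(name)))
    stop("name must be a non-empty string", call. = FALSE)
  if (!is.null(diffuse)) diffuse <- check_channel(diffuse, "Color")
  if (!is.null(specular)) specular <- check_channel(specular, "SpecularColor")
  if (!is.null(opacity)) opacity <- check_channel(opacity, "Opacity", 1L)
  if (!is.null(metadata)) {
    nms <- names(metadata)
    metadata <- as.character(metadata)
    names(metadata) <- nms
    if (length(metadata) && (is.null(nms) || any(!nzchar(nms))))
      stop("metadata must be a named character vector", call. = FALSE)
  }
  structure(list(name = name, object_type = object_type,
                 geometry_id = as.character(geometry_id)[1],
                 group_path = group_path, diffuse = diffuse,
                 specular = specular, opacity = opacity,
                 metadata = metadata),
            class = "u3d_object_spec")
}

#' Fill omitted object-spec fields from the default table
#'
#' @param spec A (possibly partial) `u3d_object_spec`.
#' @param ordinal 1-based position of the spec in its list, used for the
#'   automatic object name `"<type>_<ordinal>"`.
#' @param defaults Default table, see [u3d_spec_defaults()].
#' @return The completed spec.
#' @export
apply_spec_defaults <- function(spec, ordinal = 1L,
                                defaults = u3d_spec_defaults()) {
  stopifnot(inherits(spec, "u3d_object_spec"))
  if (is.null(spec$name))
    spec$name <- sprintf("%s_%d", spec$object_type, as.integer(ordinal))
  if (is.null(spec$group_path)) spec$group_path <- defaults$group_path
  if (is.null(spec$diffuse)) spec$diffuse <- defaults$diffuse
  if (is.null(spec$specular)) spec$specular <- defaults$specular
  if (is.null(spec$opacity)) spec$opacity <- defaults$opacity
  if (is.null(spec$metadata)) spec$metadata <- setNames(character(0), character(0))
  spec
}

KNOWN_TAGS <- c("objecttype", "objectname", "grouppath", "geometryid",
                "color", "specularcolor", "opacity", "metadata")

#' Parse object-specification text
#'
#' Parses a sequence of `<U3DObject>` records (see the package vignette for
#' the tag vocabulary) into a list of [u3d_object_spec()] objects, in record
#' order, with defaults applied to omitted tags. Unknown tags are rejected
#' with an error naming the tag and the record index -- a misspelled tag is
#' never silently ignored.
#'
#' @param text The specification text (a single string or a character
#'   vector of lines).
#' @return A list of `u3d_object_spec` objects.
#' @examples
#' parse_object_specs('<U3DObject>
#'   <ObjectType>pointset</ObjectType><GeometryID>0</GeometryID>
#' </U3DObject>')
#' @export
parse_object_specs <- function(text) {
  text <- paste(text, collapse = "\n")
  doc <- tryCatch(
    xml2::read_xml(paste0("<u3dspeclist>", text, "</u3dspeclist>")),
    error = function(e) stop("specification text is not well-formed: ",
                             conditionMessage(e), call. = FALSE))
  records <- xml2::xml_children(doc)
  specs <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (tolower(xml2::xml_name(rec)) != "u3dobject")
      stop(sprintf("record %d: expected <U3DObject>, found <%s>",
                   i, xml2::xml_name(rec)), call. = FALSE)
    fields <- list(metadata = character(0))
    for (child in xml2::xml_children(rec)) {
      tag <- tolower(xml2::xml_name(child))
      if (!tag %in% KNOWN_TAGS)
        stop(sprintf("record %d: unknown tag <%s>", i, xml2::xml_name(child)),
             call. = FALSE)
      val <- trimws(xml2::xml_text(child))
      if (tag == "metadata") {
        kids <- xml2::xml_children(child)
        nms <- tolower(vapply(kids, xml2::xml_name, character(1)))
        if (!identical(sort(nms), c("key", "value")))
          stop(sprintf("record %d: <MetaData> needs exactly <Key> and <Value>", i),
               call. = FALSE)
        key <- trimws(xml2::xml_text(kids[[which(nms == "key")]]))
        value <- xml2::xml_text(kids[[which(nms == "value")]])
        md <- fields$metadata
        md[key] <- value
        fields$metadata <- md
      } else {
        fields[[tag]] <- val
      }
    }
    if (is.null(fields$objecttype))
      stop(sprintf("record %d: missing required tag <ObjectType>", i),
           call. = FALSE)
    if (is.null(fields$geometryid))
      stop(sprintf("record %d: missing required tag <GeometryID>", i),
           call. = FALSE)
    parse_color <- function(s, what) {
      if (is.null(s)) return(NULL)
      check_channel(strsplit(trimws(s), "[[:space:]]+")[[1]], what)
    }
    spec <- tryCatch(
      u3d_object_spec(
        object_type = fields$objecttype,
        geometry_id = fields$geometryid,
        name = fields$objectname,
        group_path = fields$grouppath,
        diffuse = parse_color(fields$color, "Color"),
        specular = parse_color(fields$specularcolor, "SpecularColor"),
        opacity = if (!is.null(fields$opacity))
          check_channel(fields$opacity, "Opacity", 1L),
        metadata = if (length(fields$metadata)) fields$metadata),
      error = function(e) stop(sprintf("record %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
    specs[[i]] <- apply_spec_defaults(spec, ordinal = i)
  }
  specs
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

# shortest decimal form that parses back to exactly the same double
num_fmt <- function(x) {
  paste(vapply(x, function(v) {
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1)), collapse = " ")
}

#' Generate specification text for object specs
#'
#' Emits `<U3DObject>` records that [parse_object_specs()] inverts exactly
#' (field for field, after defaults). With `compact = TRUE`, optional fields
#' that equal their defaults are omitted.
#'
#' @param specs A `u3d_object_spec` or a list of them.
#' @param compact Omit default-valued optional fields.
#' @return A single string of specification text.
#' @export
generate_object_specs <- function(specs, compact = FALSE) {
  if (inherits(specs, "u3d_object_spec")) specs <- list(specs)
  out <- character(0)
  defaults <- u3d_spec_defaults()
  for (i in seq_along(specs)) {
    s <- apply_spec_defaults(specs[[i]], ordinal = i)
    line <- function(tag, value) sprintf("  <%s>%s</%s>", tag,
                                         xml_escape(value), tag)
    rec <- c("<U3DObject>",
             line("ObjectType", s$object_type),
             line("ObjectName", s$name),
             line("GeometryID", s$geometry_id))
    if (!compact || !identical(s$group_path, defaults$group_path))
      rec <- c(rec, line("GroupPath", s$group_path))
    if (!compact || !identical(s$diffuse, defaults$diffuse))
      rec <- c(rec, line("Color", num_fmt(s$diffuse)))
    if (!compact || !identical(s$specular, defaults$specular))
      rec <- c(rec, line("SpecularColor", num_fmt(s$specular)))
    if (!compact || !identical(s$opacity, defaults$opacity))
      rec <- c(rec, line("Opacity", num_fmt(s$opacity)))
    for (k in names(s$metadata))
      rec <- c(rec, sprintf("  <MetaData><Key>%s</Key><Value>%s</Value></MetaData>",
                            xml_escape(k), xml_escape(s$metadata[[k]])))
    out <- c(out, rec, "</U3DObject>")
  }
  paste(out, collapse = "\n")
}

#' @export
print.u3d_object_spec <- function(x, ...) {
  cat(sprintf("<u3d object spec: %s '%s' -> geometry '%s'>\n",
              x$object_type, x$name %||% "(auto)", x$geometry_id))
  invisible(x)
}
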