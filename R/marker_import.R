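# Tabular marker-list import: CSV-like text files of point positions and
# edge connection lists, with configurable value delimiter, decimal
# separator, comment prefix and row filtering.

#' Row filter for tabular imports
#'
#' Selects a subset of the data rows (rows that are neither empty nor
#' comments), by 0-based data-row index `i`: a row is kept when
#' `i >= start_row`, `(i - start_row) %% stride == 0` and, if a match is
#' configured, its `match_column`-th field (0-based) equals `match_value`.
#' The result is then truncated to at most `max_rows` rows.
#'
#' @param start_row First data row to keep (0-based).
#' @param max_rows Maximum number of rows returned, `NULL` for no limit.
#' @param stride Keep every `stride`-th row.
#' @param match_column,match_value Optional: keep only rows whose given
#'   0-based column equals the given text (compared after trimming).
#' @return An object of class `u3d_row_filter`.
#' @export
u3d_row_filter <- function(start_row = 0L, max_rows = NULL, stride = 1L,
                           match_column = NULL, match_value = NULL) {
  start_row <- as.integer(start_row)
  stride <- as.integer(stride)
  if (is.na(start_row) || start_row < 0L) stop("start_row must be >= 0")
  if (is.na(stride) || stride < 1L) stop("stride must be >= 1")
  if (!is.null(max_rows)) {
    max_rows <- as.integer(max_rows)
    if (is.na(max_rows) || max_rows < 1L) stop("max_rows must be >= 1")
  }
  if (xor(is.null(match_column), is.null(match_value)))
    stop("match_column and match_value must be given together")
  structure(list(start_row = start_row, max_rows = max_rows, stride = stride,
                 match_column = if (!is.null(match_column)) as.integer(match_column),
                 match_value = if (!is.null(match_value)) as.character(match_value)),
            class = "u3d_row_filter")
}

#' Options for tabular imports
#'
#' @param delimiter Single character separating the values of a row. When
#'   set to a space, any run of spaces/tabs counts as one delimiter.
#' @param decimal_separator Single character used as the decimal mark
#'   (substituted with `.` before numeric parsing); must differ from the
#'   delimiter.
#' @param comment_prefix Rows starting with this text are skipped.
#' @param filter A [u3d_row_filter()].
#' @return An object of class `u3d_read_options`.
#' @export
u3d_read_options <- function(delimiter = ",", decimal_separator = ".",
                             comment_prefix = "#",
                             filter = u3d_row_filter()) {
  if (!is.character(delimiter) || nchar(delimiter) != 1L)
    stop("delimiter must be a single character")
  if (!is.character(decimal_separator) || nchar(decimal_separator) != 1L)
    stop("decimal_separator must be a single character")
  if (identical(delimiter, decimal_separator))
    stop("delimiter and decimal_separator must differ")
  stopifnot(inherits(filter, "u3d_row_filter"))
  structure(list(delimiter = delimiter,
                 decimal_separator = decimal_separator,
                 comment_prefix = comment_prefix,
                 filter = filter),
            class = "u3d_read_options")
}

# read lines from a path, connection or `text =` and return the surviving
# data rows as a list of character field vectors, with original line numbers
read_table_rows <- function(file, options, text = NULL) {
  stopifnot(inherits(options, "u3d_read_options"))
  lines <- if (!is.null(text)) {
    unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  } else {
    if (is.character(file) && !file.exists(file))
      stop(sprintf("file '%s' does not exist", file), call. = FALSE)
    readLines(file, warn = FALSE)
  }
  trimmed <- trimws(lines)
  is_data <- nzchar(trimmed) &
    !startsWith(trimmed, options$comment_prefix)
  data_idx <- which(is_data)

  flt <- options$filter
  i0 <- seq_along(data_idx) - 1L  # 0-based data-row index
  keep <- i0 >= flt$start_row & (i0 - flt$start_row) %% flt$stride == 0L

  fields_of <- function(line) {
    if (options$delimiter == " ") {
      strsplit(trimws(line), "[ \t]+")[[1]]
    } else {
      trimws(strsplit(line, options$delimiter, fixed = TRUE)[[1]])
    }
  }
  rows <- lapply(data_idx, function(j) fields_of(lines[j]))

  if (!is.null(flt$match_column)) {
    keep <- keep & vapply(rows, function(f) {
      flt$match_column < length(f) &&
        identical(f[[flt$match_column + 1L]], flt$match_value)
    }, logical(1))
  }
  sel <- which(keep)
  if (!is.null(flt$max_rows)) sel <- head(sel, flt$max_rows)
  list(rows = rows[sel], line_numbers = data_idx[sel])
}

#' Import a marker list (point positions) from character-separated text
#'
#' Reads a plain text table of 3D positions: one point per surviving row,
#' first three fields as x, y, z; extra fields (labels, timestamps) are
#' ignored. The decimal separator is substituted before numeric parsing, so
#' e.g. `1,5;2,5;3,75` with `;` as delimiter and `,` as decimal mark parses
#' to `(1.5, 2.5, 3.75)`.
#'
#' @param file Path or connection; ignored when `text` is given.
#' @param options A [u3d_read_options()].
#' @param text Optional literal text (instead of a file).
#' @return An n x 3 numeric matrix of positions, in file order.
#' @examples
#' read_marker_list(text = "0,0,0\n1,0,0")
#' @export
read_marker_list <- function(file, options = u3d_read_options(), text = NULL) {
  tab <- read_table_rows(file, options, text = text)
  n <- length(tab$rows)
  out <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (k in seq_len(n)) {
    f <- tab$rows[[k]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop(sprintf("row %d: expected at least 3 numeric fields, found %d",
                   tab$line_numbers[k], length(f)), call. = FALSE)
    for (c in 1:3) {
      v <- suppressWarnings(as.numeric(
        gsub(options$decimal_separator, ".", f[[c]], fixed = TRUE)))
      if (is.na(v))
        stop(sprintf("row %d, column %d: '%s' is not numeric",
                     tab$line_numbers[k], c, f[[c]]), call. = FALSE)
      out[k, c] <- v
    }
  }
  out
}

#' Import an edge connection list from character-separated text
#'
#' Reads the edge list of a line set: each surviving row carries two
#' non-negative 0-based node indices (the convention of the text format);
#' they are converted to R's 1-based indexing on return.
#'
#' @inheritParams read_marker_list
#' @return An m x 2 integer matrix of 1-based index pairs, in file order.
#' @examples
#' read_connections(text = "0,1\n1,2")  # rows (1,2) and (2,3)
#' @export
read_connections <- function(file, options = u3d_read_options(), text = NULL) {
  tab <- read_table_rows(file, options, text = text)
  n <- length(tab$rows)
  out <- matrix(integer(0), ncol = 2)
  if (n == 0) return(out)
  out <- matrix(0L, n, 2)
  for (k in seq_len(n)) {
    f <- tab$rows[[k]]
    f <- f[nzchar(f)]
    if (length(f) < 2L)
      stop(sprintf("row %d: expected at least 2 index fields, found %d",
                   tab$line_numbers[k], length(f)), call. = FALSE)
    for (c in 1:2) {
      if (!grepl("^[0-9]+$", f[[c]]))
        stop(sprintf("row %d: '%s' is not a non-negative integer index",
                     tab$line_numbers[k], f[[c]]), call. = FALSE)
      out[k, c] <- as.integer(f[[c]]) + 1L
    }
  }
  out
}
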