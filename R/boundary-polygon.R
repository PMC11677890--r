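#' Boundary polygon of a single petal
#'
#' A `boundary_polygon` stores the ordered planar outline of one petal in
#' physical units (cm by convention). The outline is held open (the closing
#' edge from the last to the first vertex is implicit), oriented
#' counter-clockwise, with consecutive duplicate vertices collapsed.
#'
#' @param x,y Numeric vertex coordinates (equal length, >= 3 distinct
#'   vertices after collapsing consecutive duplicates).
#' @param label Object label, e.g. the component id assigned by the tracer
#'   or the `object_id` of a boundary file.
#' @param touches_border Logical flag set by [trace_boundaries()] when the
#'   traced component touched the image border (the outline may be clipped).
#'
#' @return An object of class `boundary_polygon`: a list with fields `x`,
#'   `y`, `label` and `touches_border`.
#' @export
#' @examples
#' tri <- boundary_polygon(c(0, 1, 0), c(0, 0, 1), label = "t")
#' polygon_area(tri)
boundary_polygon <- function(x, y, label = "1", touches_border = FALSE) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("vertex coordinates contain NA", call. = FALSE)

  # drop explicit closure and consecutive duplicates
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  x <- x[keep]; y <- y[keep]

  if (length(x) < 3) {
    stop("polygon '", label, "' has fewer than 3 distinct vertices",
         call. = FALSE)
  }
  a <- signed_area(x, y)
  if (abs(a) < .Machine$double.eps * max(1, max(abs(x)), max(abs(y)))^2) {
    stop("polygon '", label, "' has zero area (collinear vertices)",
         call. = FALSE)
  }
  if (a < 0) { # enforce counter-clockwise orientation
    x <- rev(x); y <- rev(y)
  }
  structure(
    list(x = x, y = y, label = as.character(label),
         touches_border = isTRUE(touches_border)),
    class = "boundary_polygon"
  )
}

#' @export
print.boundary_polygon <- function(x, ...) {
  cat(sprintf(
    "<boundary_polygon '%s': %d vertices, area %.4g%s>\n",
    x$label, length(x$x), polygon_area(x),
    if (x$touches_border) ", touches image border" else ""
  ))
  invisible(x)
}

# shoelace signed area of an implicitly closed vertex list (positive = CCW)
signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Read petal boundary polygons from a delimited text file
#'
#' The file must be comma- or tab-delimited with a mandatory header row and
#' columns `object_id`, `x`, `y`; vertices of each object are taken in file
#' order. Consecutive duplicate vertices are collapsed; an explicit closing
#' vertex (first repeated last) is accepted and removed.
#'
#' @param path Path to the boundary file.
#' @return A list of [boundary_polygon()] objects, one per `object_id`, in
#'   order of first appearance.
#' @seealso [write_boundary_file()] for the inverse operation.
#' @export
read_boundary_file <- function(path) {
  df <- readr::read_delim(path, col_types = readr::cols(
    object_id = readr::col_character(),
    x = readr::col_double(),
    y = readr::col_double()
  ), comment = "#", progress = FALSE, show_col_types = FALSE)
  need <- c("object_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("boundary file must have columns object_id, x, y", call. = FALSE)
  }
  ids <- unique(df$object_id)
  lapply(ids, function(id) {
    sub <- df[df$object_id == id, ]
    if (nrow(sub) < 3) {
      stop("object '", id, "' has fewer than 3 vertices", call. = FALSE)
    }
    boundary_polygon(sub$x, sub$y, label = id)
  })
}

#' Write boundary polygons to a delimited text file
#'
#' Writes CSV with columns `object_id,x,y` and a comment header recording
#' the unit and the y-up coordinate convention, readable by
#' [read_boundary_file()].
#'
#' @param polygons A single [boundary_polygon()] or a list of them.
#' @param path Output path.
#' @param unit Unit recorded in the header comment (default `"cm"`).
#' @return `path`, invisibly.
#' @export
write_boundary_file <- function(polygons, path, unit = "cm") {
  if (inherits(polygons, "boundary_polygon")) polygons <- list(polygons)
  df <- dplyr::bind_rows(lapply(polygons, function(p) {
    tibble::tibble(object_id = p$label, x = p$x, y = p$y)
  }))
  header <- sprintf(
    "# petal boundary coordinates; unit = %s; y increases upward", unit)
  writeLines(c(header, "object_id,x,y"), path)
  readr::write_csv(df, path, append = TRUE, col_names = FALSE)
  invisible(path)
}
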