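#' Binary silhouette image
#'
#' Wraps a foreground/background pixel grid together with its scan
#' resolution. Any nonzero pixel is foreground. Row 1 is the top of the
#' image; [trace_boundaries()] converts to a y-up physical frame.
#'
#' @param pixels Numeric or logical matrix; nonzero/`TRUE` = foreground.
#' @param dpi Scan resolution in dots per inch (default 600). One pixel
#'   spans `2.54 / dpi` cm.
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(pixels, dpi = 600) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  if (!is.numeric(dpi) || length(dpi) != 1 || is.na(dpi) || dpi <= 0) {
    stop("dpi must be a single positive number", call. = FALSE)
  }
  structure(list(pixels = (pixels != 0) * 1L, dpi = dpi),
            class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image %d x %d px, %g dpi, %d foreground px>\n",
              nrow(x$pixels), ncol(x$pixels), x$dpi, sum(x$pixels)))
  invisible(x)
}

#' Read a binary silhouette image from PNG or TIFF
#'
#' Pixels darker than mid-grey are treated as foreground (silhouettes are
#' conventionally black on white); set `invert = FALSE` for white-on-black
#' scans.
#'
#' @param path PNG or TIFF file path.
#' @param dpi Resolution in dots per inch; taken from file metadata when
#'   available, else this value (default 600).
#' @param invert If `TRUE` (default) dark pixels are foreground.
#' @return A [binary_image()].
#' @export
read_binary_image <- function(path, dpi = 600, invert = TRUE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path, info = TRUE),
    tif = ,
    tiff = tiff::readTIFF(path, info = TRUE),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  info <- attr(img, "info")
  if (!is.null(info$dpi) && all(is.finite(info$dpi)) && all(info$dpi > 0)) {
    dpi <- mean(info$dpi)
  }
  if (length(dim(img)) == 3) img <- img[, , 1] # first channel of RGB(A)
  fg <- if (invert) img < 0.5 else img >= 0.5
  binary_image(fg * 1L, dpi = dpi)
}

#' Trace petal boundaries in a binary image
#'
#' Labels 8-connected foreground components, drops components smaller than
#' `min_pixels`, and extracts each retained component's outer contour by
#' marching-squares contouring of the 0/1 grid at level 0.5, which places
#' vertices sub-pixel at the midpoints between foreground and background
#' pixel centres. Holes inside a component are ignored: only the outer
#' contour is returned. Coordinates are converted to cm with one pixel =
#' `2.54 / dpi` cm, x increasing with image column and y increasing upward
#' (`y = (image height - row) * scale`). All polygons are returned
#' counter-clockwise.
#'
#' @param image A [binary_image()].
#' @param min_pixels Minimum component size in pixels; smaller components
#'   are dropped with a message (default 100).
#' @return List of [boundary_polygon()]s, labelled `"1"`, `"2"`, ... in
#'   labelling order. Components touching the image border are returned
#'   with `touches_border = TRUE` and a warning.
#' @export
#' @examples
#' px <- matrix(0L, 60, 60); px[20:39, 15:44] <- 1L
#' trace_boundaries(binary_image(px, dpi = 600), min_pixels = 10)
trace_boundaries <- function(image, min_pixels = 100) {
  stopifnot(inherits(image, "binary_image"))
  px <- image$pixels
  if (sum(px) == 0) stop("no objects found: image has no foreground pixels",
                         call. = FALSE)

  lab <- label_components(px)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_pixels)
  if (length(keep) == 0) {
    stop("no objects found: all ", length(sizes),
         " component(s) are below min_pixels = ", min_pixels, call. = FALSE)
  }
  if (length(keep) < length(sizes)) {
    message(length(sizes) - length(keep), " component(s) below ",
            min_pixels, " px dropped")
  }

  nr <- nrow(px); nc <- ncol(px)
  scale <- 2.54 / image$dpi
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    id <- keep[i]
    mask <- (lab == id)
    border <- any(mask[1, ]) || any(mask[nr, ]) ||
      any(mask[, 1]) || any(mask[, nc])
    if (border) {
      warning("component ", id, " touches the image border; ",
              "its outline may be clipped", call. = FALSE)
    }
    # zero ring so every contour closes inside the grid
    z <- matrix(0, nr + 2L, nc + 2L)
    z[2:(nr + 1L), 2:(nc + 1L)] <- mask
    cl <- grDevices::contourLines(x = seq_len(nr + 2L), y = seq_len(nc + 2L),
                                  z = z, levels = 0.5)
    # outer contour = the one enclosing the largest area (holes are smaller)
    areas <- vapply(cl, function(cc) abs(signed_area(cc$x, cc$y)), 0)
    cc <- cl[[which.max(areas)]]
    row <- cc$x - 1 # un-pad: contour x follows the row index
    col <- cc$y - 1
    out[[i]] <- boundary_polygon(
      x = col * scale, y = (nr - row) * scale,
      label = as.character(i), touches_border = border
    )
  }
  out
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# labels that touch diagonally are merged afterwards with union-find.
label_components <- function(px) {
  lab <- EBImage::imageData(EBImage::bwlabel(px))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), if (shift[2] == 1L) seq_len(nc - 1L) else 2:nc]
    b <- lab[2:nr, if (shift[2] == 1L) 2:nc else seq_len(nc - 1L)]
    hit <- which(a > 0 & b > 0 & a != b)
    for (k in hit) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, 0L)
  # compact to consecutive ids in order of first appearance
  remap <- match(root, unique(root))
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}
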