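#' Area enclosed by a boundary polygon
#'
#' Absolute shoelace (Gauss) area of the implicitly closed outline.
#'
#' @param polygon A [boundary_polygon()].
#' @return Enclosed area, in the square of the coordinate unit (cm^2 for
#'   traced petals).
#' @export
#' @examples
#' polygon_area(boundary_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))) # 1
polygon_area <- function(polygon) {
  stopifnot(inherits(polygon, "boundary_polygon"))
  abs(signed_area(polygon$x, polygon$y))
}

#' Length-axis specification for petal measurement
#'
#' Fixes the convention along which petal length is measured. In
#' `"principal"` mode (default) the length axis is the major principal axis
#' of the outline's second area moments; in `"landmarks"` mode it is the
#' line from a base landmark to an apex landmark (useful for bilaterally
#' symmetric petals whose symmetry axis is known).
#'
#' @param mode `"principal"` or `"landmarks"`.
#' @param base,apex Numeric length-2 points (cm), required for
#'   `"landmarks"`; both must lie within the polygon's bounding box at
#'   measurement time.
#' @return An object of class `axis_spec`.
#' @export
axis_spec <- function(mode = c("principal", "landmarks"),
                      base = NULL, apex = NULL) {
  mode <- match.arg(mode)
  if (mode == "landmarks") {
    if (is.null(base) || is.null(apex)) {
      stop("landmarks mode requires both base and apex points", call. = FALSE)
    }
    base <- as.numeric(base); apex <- as.numeric(apex)
    stopifnot(length(base) == 2, length(apex) == 2)
    if (all(base == apex)) stop("base and apex landmarks coincide",
                                call. = FALSE)
  }
  structure(list(mode = mode, base = base, apex = apex), class = "axis_spec")
}

#' Measure one petal: area, length and width
#'
#' Length `L` is the extent of the outline projected onto the length axis
#' (see [axis_spec()]); width `W` is the maximum extent perpendicular to
#' that axis (maximum perpendicular caliper); area `A` is the shoelace
#' area. Because `L` and `W` are extents of the same outline along
#' orthogonal directions, every petal satisfies `A <= L * W`, so the
#' per-petal Montgomery ratio `A/(LW)` lies in (0, 1].
#'
#' For a notched (apex-concave) petal the length axis still runs through
#' the notch, so the axis extent understates the envelope rectangle and the
#' ratio `A/(LW)` comes out larger than for an unnotched outline of the
#' same shape family — no correction is applied.
#'
#' @param polygon A [boundary_polygon()].
#' @param axis An [axis_spec()]; default principal-axis mode.
#' @param species,flower_id,petal_id Identifier labels copied into the
#'   returned record.
#' @return A one-row tibble (a `PetalRecord`) with columns `species`,
#'   `flower_id`, `petal_id`, `A`, `L`, `W`.
#' @export
#' @examples
#' rect <- boundary_polygon(c(0, 3, 3, 0), c(0, 0, 1, 1))
#' measure_petal(rect) # L = 3, W = 1, A = 3
measure_petal <- function(polygon, axis = axis_spec("principal"),
                          species = "sp", flower_id = "f1", petal_id = "p1") {
  stopifnot(inherits(polygon, "boundary_polygon"),
            inherits(axis, "axis_spec"))
  A <- polygon_area(polygon)
  u <- length_axis_direction(polygon, axis)
  # project vertices on the axis and its normal
  t_along <- polygon$x * u[1] + polygon$y * u[2]
  t_perp <- -polygon$x * u[2] + polygon$y * u[1]
  L <- diff(range(t_along))
  W <- diff(range(t_perp))
  if (W > L) { # major axis by construction, but guard ties/symmetry
    tmp <- L; L <- W; W <- tmp
  }
  tibble::tibble(
    species = species, flower_id = flower_id, petal_id = petal_id,
    A = A, L = L, W = W
  )
}

# unit direction of the length axis under an axis_spec
length_axis_direction <- function(polygon, axis) {
  if (axis$mode == "landmarks") {
    bb <- list(x = range(polygon$x), y = range(polygon$y))
    for (p in list(axis$base, axis$apex)) {
      if (p[1] < bb$x[1] || p[1] > bb$x[2] || p[2] < bb$y[1] ||
          p[2] > bb$y[2]) {
        stop("landmark (", p[1], ", ", p[2],
             ") lies outside the polygon's bounding box", call. = FALSE)
      }
    }
    v <- axis$apex - axis$base
    return(v / sqrt(sum(v^2)))
  }
  m <- polygon_moments(polygon)
  # principal directions of the central second area moments
  d <- m$Ixx - m$Iyy
  if (abs(d) < 1e-12 * (m$Ixx + m$Iyy) && abs(m$Ixy) < 1e-12 * (m$Ixx + m$Iyy)) {
    warning("isotropic second moments; falling back to longest-diameter axis",
            call. = FALSE)
    return(longest_diameter_direction(polygon))
  }
  theta <- 0.5 * atan2(2 * m$Ixy, d)
  # theta gives one principal direction; pick the one with the larger moment
  u1 <- c(cos(theta), sin(theta))
  u2 <- c(-u1[2], u1[1])
  i1 <- m$Ixx * u1[1]^2 + 2 * m$Ixy * u1[1] * u1[2] + m$Iyy * u1[2]^2
  i2 <- m$Ixx * u2[1]^2 + 2 * m$Ixy * u2[1] * u2[2] + m$Iyy * u2[2]^2
  if (i1 >= i2) u1 else u2
}

# central second area moments of a polygon (shoelace-based closed forms);
# Ixx = integral of x'^2 dA etc., about the area centroid
polygon_moments <- function(polygon) {
  x <- polygon$x; y <- polygon$y
  n <- length(x)
  j <- c(2:n, 1L)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  cx <- sum((x + x[j]) * cross) / (6 * a)
  cy <- sum((y + y[j]) * cross) / (6 * a)
  x0 <- x - cx; y0 <- y - cy
  xj <- x0[j]; yj <- y0[j]
  cr <- x0 * yj - xj * y0
  Ixx <- sum(cr * (x0^2 + x0 * xj + xj^2)) / 12
  Iyy <- sum(cr * (y0^2 + y0 * yj + yj^2)) / 12
  Ixy <- sum(cr * (x0 * yj + 2 * x0 * y0 + 2 * xj * yj + xj * y0)) / 24
  if (a < 0) { Ixx <- -Ixx; Iyy <- -Iyy; Ixy <- -Ixy }
  list(area = abs(a), centroid = c(cx, cy), Ixx = Ixx, Iyy = Iyy, Ixy = Ixy)
}

# direction of the longest chord between hull vertices
longest_diameter_direction <- function(polygon) {
  h <- grDevices::chull(polygon$x, polygon$y)
  hx <- polygon$x[h]; hy <- polygon$y[h]
  d2 <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  v <- c(hx[ij[2]] - hx[ij[1]], hy[ij[2]] - hy[ij[1]])
  v / sqrt(sum(v^2))
}

#' Measure a list of petal boundary polygons
#'
#' Convenience wrapper applying [measure_petal()] to each polygon of one
#' flower (or of a whole traced image).
#'
#' @param polygons List of [boundary_polygon()]s.
#' @param axis An [axis_spec()].
#' @param species,flower_id Labels for all records; petal ids are taken
#'   from the polygon labels.
#' @return A tibble of petal records, one row per polygon.
#' @export
measure_petals <- function(polygons, axis = axis_spec("principal"),
                           species = "sp", flower_id = "f1") {
  dplyr::bind_rows(lapply(polygons, function(p) {
    measure_petal(p, axis, species = species, flower_id = flower_id,
                  petal_id = p$label)
  }))
}
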