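# shared fixtures: all synthetic, built in code at test time

# n-vertex polygon approximating an axis-aligned ellipse
ellipse_polygon <- function(a, b, n = 100, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  boundary_polygon(cx + a * cos(th), cy + b * sin(th), label = "ellipse")
}

# pixel grid whose centres fall inside an ellipse with semi-axes in px
raster_ellipse <- function(a_px, b_px, pad = 5) {
  nc <- 2 * ceiling(a_px) + 2 * pad
  nr <- 2 * ceiling(b_px) + 2 * pad
  cx <- nc / 2; cy <- nr / 2
  col <- matrix(seq_len(nc) - 0.5, nr, nc, byrow = TRUE)
  row <- matrix(seq_len(nr) - 0.5, nr, nc)
  ((col - cx)^2 / a_px^2 + (row - cy)^2 / b_px^2 <= 1) * 1L
}

# random petal-like outline with moderate tip exponents
random_outline <- function() {
  L <- runif(1, 1.5, 3.5)
  wl <- runif(1, 0.4, 0.9)
  p1 <- runif(1, 0.8, 1.4)
  p2 <- runif(1, 0.8, 1.4)
  notch <- sample(c(0, runif(1, 0.02, 0.1)), 1)
  make_outline(L, L * wl, p1, p2, notch)
}

# rotate + translate a polygon (for invariance checks)
transform_polygon <- function(p, theta = 0, dx = 0, dy = 0) {
  boundary_polygon(
    p$x * cos(theta) - p$y * sin(theta) + dx,
    p$x * sin(theta) + p$y * cos(theta) + dy,
    label = p$label
  )
}

# Monte-Carlo polygon area oracle (point-in-polygon via mgcv::in.out)
mc_polygon_area <- function(p, n = 1e6, seed = 1) {
  withr::with_seed(seed, {
    xr <- range(p$x); yr <- range(p$y)
    px <- runif(n, xr[1], xr[2])
    py <- runif(n, yr[1], yr[2])
    bnd <- cbind(c(p$x, p$x[1]), c(p$y, p$y[1]))
    inside <- mgcv::in.out(bnd, cbind(px, py))
    mean(inside) * diff(xr) * diff(yr)
  })
}

# quadrature oracle for make_outline's enclosed area
quadrature_outline_area <- function(L, W, p1, p2, notch_depth) {
  t_star <- p1 / (p1 + p2)
  t_max <- 1 - notch_depth
  f <- function(t) (t^p1 * (1 - t)^p2) / (t_star^p1 * (1 - t_star)^p2)
  smooth <- W * (L / t_max) * stats::integrate(f, 0, t_max,
                                               rel.tol = 1e-10)$value
  wedge <- if (notch_depth > 0) {
    (W / 2) * f(t_max) * notch_depth * L # (1/2) * 2*y_tip * d*L
  } else 0
  smooth - wedge
}
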