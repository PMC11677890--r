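test_that("make_outline hits its construction length and width exactly", {
  o <- make_outline(3, 1.5, 1, 1, 0) # lens
  expect_equal(diff(range(o$x)), 3, tolerance = 1e-12)
  expect_equal(diff(range(o$y)), 1.5, tolerance = 1e-12)
  on <- make_outline(2, 1.8, 0.9, 0.9, 0.1) # notched
  expect_equal(diff(range(on$x)), 2, tolerance = 1e-12)
  expect_equal(diff(range(on$y)), 1.8, tolerance = 1e-12)

  expect_error(make_outline(-1, 1, 1, 1), "positive")
  expect_error(make_outline(1, 1, 0, 1), "positive")
  expect_error(make_outline(1, 1, 1, 1, 0.4), "notch_depth")
  expect_error(make_outline(1, 1, 1, 1, n_vertices = 8), "n_vertices")
  expect_error(make_outline(1, 1, 9, 0.5, 0.2), "widest station")
})

test_that("outline area matches adaptive quadrature within 0.5% at 512 vertices", {
  cases <- list(c(3, 1.5, 1, 1, 0), c(2.5, 1.2, 1.4, 0.8, 0),
                c(2, 1.8, 0.9, 0.9, 0.05), c(1.5, 1.3, 1.2, 1.1, 0.2))
  for (cc in cases) {
    o <- make_outline(cc[1], cc[2], cc[3], cc[4], cc[5], n_vertices = 512)
    expect_equal(polygon_area(o),
                 quadrature_outline_area(cc[1], cc[2], cc[3], cc[4], cc[5]),
                 tolerance = 0.005)
  }
})

test_that("an apex notch keeps L but carves a wedge out of the enclosed area", {
  plain <- make_outline(2, 1.6, 0.9, 0.9, 0, n_vertices = 512)
  notched <- make_outline(2, 1.6, 0.9, 0.9, 0.1, n_vertices = 512)
  m0 <- measure_petal(plain); m1 <- measure_petal(notched)
  expect_equal(m1$L, m0$L, tolerance = 1e-9) # axis extent unchanged
  expect_equal(m1$L * m1$W, m0$L * m0$W, tolerance = 1e-9) # same envelope
  # the enclosed area sits exactly one wedge below the closed smooth profile
  t_max <- 0.9
  f <- function(t) (t^0.9 * (1 - t)^0.9) / (0.5^0.9 * 0.5^0.9)
  smooth <- 1.6 * (2 / t_max) * stats::integrate(f, 0, t_max)$value
  wedge <- (1.6 / 2) * f(t_max) * 0.1 * 2
  expect_lt(polygon_area(notched), smooth)
  expect_equal(polygon_area(notched), smooth - wedge, tolerance = 0.005)
})

test_that("generated W/L ratios match the configured target in the mean", {
  cfg <- species_config("x", n_flowers = 1000, petal_count = c(10, 10),
                        length_meanlog = log(1.5), length_sdlog = 0.1,
                        wl_mean = 0.62, wl_sd = 0.05, p1 = 1.2, p2 = 0.9)
  sim <- generate_dataset(list(cfg), seed = 17, n_vertices = 32)
  ratio <- sim$petals$W / sim$petals$L
  se <- sd(ratio) / sqrt(length(ratio))
  expect_gte(length(ratio), 1e4)
  expect_lt(abs(mean(ratio) - 0.62), 2 * se + 1e-4)
})

test_that("the generator is seed-reproducible and refuses to run unseeded", {
  s1 <- generate_dataset(seed = 23)
  s2 <- generate_dataset(seed = 23)
  s3 <- generate_dataset(seed = 24)
  expect_identical(s1$petals, s2$petals)
  expect_false(identical(s1$petals$A, s3$petals$A))
  expect_error(generate_dataset(), "seed")
  expect_error(simulate_flower_summaries(10, 0.8, 0.05), "seed")
})

test_that("petal counts and flower numbers follow the configuration", {
  sim <- generate_dataset(seed = 29)
  per_flower <- dplyr::count(sim$petals, species, flower_id)
  ob <- per_flower$n[per_flower$species == "obovate"]
  no <- per_flower$n[per_flower$species == "notched"]
  expect_true(all(ob %in% 11:12))
  expect_true(all(no == 5))
  expect_equal(length(ob), 60)
  expect_equal(length(no), 63)
})

test_that("zero-noise data return the shape-determined k exactly", {
  cfg <- species_config("exact", n_flowers = 10, petal_count = c(6, 8),
                        length_meanlog = log(2), length_sdlog = 0.1,
                        wl_mean = 0.6, wl_sd = 0.04, p1 = 1.3, p2 = 0.9,
                        sigma = 0)
  sim <- generate_dataset(list(cfg), seed = 31)
  fit <- fit_montgomery(sim$petals)
  expect_equal(fit$k_hat, sim$truth$k, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-6)
})

test_that("a unit square rasterizes to the expected foreground block", {
  sq <- boundary_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))
  img <- rasterize(sq, dpi = 600)
  side <- 600 / 2.54 # pixels per cm at 600 dpi
  expect_lt(abs(sum(img$pixels) - side^2) / side^2, 0.01)
  expect_error(rasterize(sq, dpi = 600, max_pixels = 1000), "maximum canvas")
})

test_that("round-trip error shrinks as resolution grows", {
  o <- make_outline(2.5, 1.4, 1.1, 0.9, 0.05)
  err <- vapply(c(20, 100, 600), function(dpi) {
    m <- measure_petal(trace_boundaries(rasterize(o, dpi),
                                        min_pixels = 5)[[1]])
    abs(m$A / polygon_area(o) - 1)
  }, 0)
  expect_gt(err[1], err[2])
  expect_gt(err[2], err[3])
  expect_lt(err[3], 0.01)
})
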