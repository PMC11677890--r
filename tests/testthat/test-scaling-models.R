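noisefree_petals <- function(k = 0.7, n = 40, seed = 1) {
  withr::with_seed(seed, {
    L <- runif(n, 1, 4)
    W <- L * runif(n, 0.4, 0.9)
    tibble::tibble(species = "s", flower_id = "f",
                   petal_id = as.character(seq_len(n)),
                   A = k * L * W, L = L, W = W)
  })
}

noisefree_flowers <- function(k = 0.8, n = 30, seed = 1, sigma = 0) {
  simulate_flower_summaries(n, k, sigma, seed = seed)
}

test_that("the Montgomery fit recovers exact proportionality with zero residual", {
  fit <- fit_montgomery(noisefree_petals(0.7))
  expect_equal(fit$k_hat, 0.7, tolerance = 1e-10)
  expect_equal(fit$slope, 1)
  expect_lt(fit$rmse, 1e-10)
  expect_equal(fit$n, 40L)
})

test_that("hand-computed residuals give a = ln 0.6 and rmse = sqrt(0.02)", {
  res <- c(0.1, -0.1, 0, 0.2, -0.2)
  L <- c(2, 2.5, 3, 3.5, 4); W <- c(1, 1.1, 1.3, 1.5, 1.6)
  petals <- tibble::tibble(species = "s", flower_id = "f",
                           petal_id = as.character(1:5),
                           A = 0.6 * L * W * exp(res), L = L, W = W)
  fit <- fit_montgomery(petals)
  expect_equal(fit$intercept, log(0.6), tolerance = 1e-12)
  expect_equal(fit$rmse, sqrt(0.02), tolerance = 1e-12)
})

test_that("nonpositive measurements are rejected before transformation", {
  bad <- noisefree_petals()
  bad$A[3] <- -1
  expect_error(fit_montgomery(bad), "positive")
  bad2 <- noisefree_petals()
  bad2$W[1] <- 0
  expect_error(fit_montgomery(bad2), "positive")
})

test_that("predict_area is k*LW for ME fits only, exact on zero-noise data", {
  petals <- noisefree_petals(0.5)
  fit <- fit_montgomery(petals)
  expect_equal(predict_area(fit, 2, 1), 1.0, tolerance = 1e-10)
  expect_equal(predict_area(fit, petals$L, petals$W), petals$A,
               tolerance = 1e-10)
  mkse <- fit_total_area_model(noisefree_flowers(), "MKSE")
  expect_error(predict_area(mkse, 2, 1), "ME fit")
  expect_equal(predict_total_area(mkse, 3, 2), 0.8 * 6, tolerance = 1e-10)
})

test_that("MKSE and PLE agree on exactly proportional flower data", {
  fl <- noisefree_flowers(k = 0.8)
  mkse <- fit_total_area_model(fl, "MKSE")
  ple <- fit_total_area_model(fl, "PLE")
  expect_equal(mkse$k_hat, 0.8, tolerance = 1e-10)
  expect_lt(mkse$rmse, 1e-10)
  expect_equal(ple$slope, 1, tolerance = 1e-8)
  expect_error(fit_total_area_model(fl[1:2, ], "PLE"), "at least 3")
})

test_that("PLE recovers a known scaling exponent across 200 simulations", {
  alpha <- 0.85; gamma <- -0.3; sigma <- 0.03; n <- 60
  hits <- 0
  alphas <- numeric(200)
  for (s in 1:200) {
    fl <- withr::with_seed(1000 + s, {
      lx <- log(stats::rlnorm(n, log(7), 0.25) *
                  stats::rlnorm(n, log(2), 0.15))
      tibble::tibble(species = "s", flower_id = as.character(1:n),
                     A_T = exp(gamma + alpha * lx + rnorm(n, 0, sigma)),
                     L_KS = exp(lx), W_KS = 1)
    })
    fit <- fit_total_area_model(fl, "PLE")
    lx <- log(fl$L_KS * fl$W_KS)
    se <- sigma / (stats::sd(lx) * sqrt(n)) # closed-form OLS slope se
    alphas[s] <- fit$slope
    if (abs(fit$slope - alpha) <= 3 * se) hits <- hits + 1
  }
  expect_gte(hits, 195) # ~99.7% expected within 3 SE
  expect_lt(abs(mean(alphas) - alpha), 0.01)
})

test_that("rmse and aic reproduce closed forms and the stats oracle", {
  expect_equal(compute_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_rmse(c(0.3, -0.4), c(0, 0)), sqrt(0.125))
  expect_error(compute_rmse(1:3, 1:2), "length")
  expect_error(compute_rmse(numeric(), numeric()), "empty")

  # logL-zero construction: rss/n = 1/(2*pi*e) makes logL = 0, AIC = 2p
  n <- 10
  expect_equal(compute_aic(n, n / (2 * pi * exp(1)), 1), 4, tolerance = 1e-12)
  expect_error(compute_aic(10, 0, 1), "degenerate")

  # independent oracle: stats::AIC on the same Gaussian likelihood
  withr::with_seed(8, {
    x <- rnorm(40); y <- 1 + 0.5 * x + rnorm(40, 0, 0.2)
    lmfit <- lm(y ~ x)
    rss <- sum(residuals(lmfit)^2)
    expect_equal(compute_aic(40, rss, 2), AIC(lmfit), tolerance = 1e-8)
  })
})

test_that("percent error follows its definition and guards rmse_1 = 0", {
  expect_equal(percent_error(0.5, 0.5), 0)
  expect_equal(percent_error(0.5, 0), 100)
  expect_error(percent_error(0, 0.1), "positive")
})

test_that("model selection prefers PLE only above the PE threshold", {
  fl <- simulate_flower_summaries(60, 0.8, 0.05, seed = 3)
  mkse <- fit_total_area_model(fl, "MKSE")
  ple <- fit_total_area_model(fl, "PLE", bootstrap = 200, seed = 4)
  cmp <- select_model(mkse, ple)
  expect_equal(cmp$pe, percent_error(mkse$rmse, ple$rmse))
  expect_match(cmp$rule_trace, "slope 95% CI", fixed = TRUE)
  # ties go to the simpler model
  tie <- select_model(mkse, ple, threshold = cmp$pe)
  expect_equal(tie$preferred, "MKSE")
  # mismatched data are refused
  other <- fit_total_area_model(simulate_flower_summaries(30, 0.8, 0.05,
                                                          seed = 5), "PLE")
  expect_error(select_model(mkse, other), "different data")
})

test_that("PLE never fits worse than the nested MKSE", {
  for (s in 1:100) {
    fl <- simulate_flower_summaries(
      n_flowers = withr::with_seed(s, sample(10:80, 1)),
      k_KS = withr::with_seed(s, runif(1, 0.5, 0.95)),
      sigma = withr::with_seed(s, runif(1, 0.01, 0.2)),
      seed = 2000 + s
    )
    mkse <- fit_total_area_model(fl, "MKSE")
    ple <- fit_total_area_model(fl, "PLE")
    expect_lte(ple$rmse, mkse$rmse + 1e-12)
    expect_gte(percent_error(mkse$rmse, ple$rmse), -1e-9)
  }
})

test_that("k_hat is invariant to a joint change of measurement unit", {
  sim <- generate_dataset(seed = 9)
  petals_cm <- sim$petals
  petals_mm <- dplyr::mutate(petals_cm, A = A * 100, L = L * 10, W = W * 10)
  expect_equal(fit_montgomery(petals_mm)$k_hat,
               fit_montgomery(petals_cm)$k_hat, tolerance = 1e-12)
  fl_cm <- sim$flowers
  fl_mm <- dplyr::mutate(fl_cm, A_T = A_T * 100, L_KS = L_KS * 10,
                         W_KS = W_KS * 10)
  expect_equal(fit_total_area_model(fl_mm, "MKSE")$k_hat,
               fit_total_area_model(fl_cm, "MKSE")$k_hat, tolerance = 1e-12)
})

test_that("bootstrap intervals are seeded, deterministic, and collapse at zero noise", {
  fl <- simulate_flower_summaries(40, 0.75, 0.06, seed = 12)
  ci1 <- bootstrap_ci(fl, "MKSE", B = 100, seed = 42)
  ci2 <- bootstrap_ci(fl, "MKSE", B = 100, seed = 42)
  expect_identical(ci1$k, ci2$k)
  expect_error(bootstrap_ci(fl, "MKSE", B = 100), "seed")

  exact <- noisefree_flowers(k = 0.8)
  ci0 <- bootstrap_ci(exact, "MKSE", B = 100, seed = 1)
  expect_equal(diff(ci0$k), 0, tolerance = 1e-12)
  expect_equal(ci0$k[1], 0.8, tolerance = 1e-10)

  # the bootstrap must not disturb the caller's RNG stream
  withr::with_seed(5, {
    before <- runif(1)
  })
  withr::with_seed(5, {
    invisible(bootstrap_ci(fl, "PLE", B = 50, seed = 9))
    after <- runif(1)
  })
  expect_identical(before, after)
})
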