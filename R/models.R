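#' @title Log-scale scaling models for petal and corolla area
#'
#' @description
#' Three models relate planar area to one-dimensional size measures, all
#' fitted by ordinary least squares after natural-log transformation
#' (log-transforming stabilises the multiplicative variance of area):
#'
#' * **ME** (Montgomery equation), per petal: `A = k * L * W`, fitted as
#'   `ln A = a + ln(LW)` with the slope fixed at 1, so the only parameter
#'   is the intercept `a = ln k`. The intercept-only OLS solution is
#'   `a_hat = mean(ln A - ln LW)`.
#' * **MKSE** (Montgomery-Koyama-Smith equation), per flower:
#'   `A_T = k_KS * L_KS * W_KS`, fitted the same way on flower summaries.
#' * **PLE** (power-law equation), per flower:
#'   `A_T = beta * (L_KS W_KS)^alpha`, fitted as the simple linear
#'   regression `ln A_T = gamma + alpha * ln(L_KS W_KS)`; `alpha = 1`
#'   recovers the MKSE structure, so the PLE nests the MKSE and its RMSE
#'   can never exceed the MKSE's on the same data.
#'
#' The proportionality coefficient is back-transformed directly,
#' `k_hat = exp(intercept)`, with no smearing correction.
#'
#' @name scaling-models
NULL

new_model_fit <- function(model, intercept, slope, n, rss, r,
                          ci = NULL, B = 0L, seed = NULL) {
  n_params <- if (model == "PLE") 2L else 1L
  rmse <- sqrt(rss / n)
  aic <- if (rss > 0) compute_aic(n, rss, n_params) else NA_real_
  structure(
    list(model = model, intercept = intercept, slope = slope,
         k_hat = exp(intercept), n = n, rss = rss, rmse = rmse,
         aic = aic, r = r, n_params = n_params,
         ci = ci, B = B, seed = seed),
    class = "petal_model_fit"
  )
}

#' @export
print.petal_model_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<%s fit, n = %d>\n", x$model, x$n))
  cat(sprintf("  intercept (ln k) = %.*g   slope = %.*g   k_hat = %.*g\n",
              digits, x$intercept, digits, x$slope, digits, x$k_hat))
  cat(sprintf("  rmse (ln scale) = %.*g   aic = %.*g   r = %.*g\n",
              digits, x$rmse, digits, x$aic, digits, x$r))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI k: [%.*g, %.*g]  (B = %d bootstrap reps)\n",
                digits, x$ci$k[1], digits, x$ci$k[2], x$B))
    if (x$model == "PLE") {
      cat(sprintf("  95%% CI slope: [%.*g, %.*g]\n",
                  digits, x$ci$slope[1], digits, x$ci$slope[2]))
    }
  }
  invisible(x)
}

#' Fit the Montgomery equation to per-petal measurements
#'
#' Intercept-only OLS of `ln A` on the offset `ln(LW)`:
#' `a_hat = mean(ln A - ln LW)`, `k_hat = exp(a_hat)`. The reported RMSE
#' is on the natural-log scale with divisor `n` (the petal count), and `r`
#' is the Pearson correlation of `ln(LW)` with `ln A`.
#'
#' @param petals Tibble of petal records with positive `A`, `L`, `W`
#'   (>= 2 rows).
#' @param bootstrap Number of bootstrap replicates for 95 percent
#'   percentile confidence intervals (0 = none).
#' @param seed RNG seed, required when `bootstrap > 0`.
#' @return A `petal_model_fit` (model `"ME"`).
#' @export
#' @examples
#' petals <- tibble::tibble(
#'   species = "s", flower_id = "f", petal_id = as.character(1:4),
#'   L = c(2, 2.5, 3, 3.5), W = c(1, 1.2, 1.4, 1.6)
#' )
#' petals$A <- 0.7 * petals$L * petals$W
#' fit_montgomery(petals)$k_hat # 0.7 exactly
fit_montgomery <- function(petals, bootstrap = 0, seed = NULL) {
  check_positive(petals, c("A", "L", "W"))
  if (nrow(petals) < 2) stop("need at least 2 petals", call. = FALSE)
  lx <- log(petals$L * petals$W)
  ly <- log(petals$A)
  fit <- ols_offset(lx, ly)
  ci <- if (bootstrap > 0) {
    boot_intervals(lx, ly, slope_free = FALSE, B = bootstrap, seed = seed)
  }
  new_model_fit("ME", fit$intercept, 1, length(ly), fit$rss,
                stats::cor(lx, ly), ci = ci, B = as.integer(bootstrap),
                seed = seed)
}

#' Fit the MKSE or the power-law equation to per-flower summaries
#'
#' `model = "MKSE"` fits `ln A_T = c + ln(L_KS W_KS)` (intercept only,
#' slope fixed at 1); `model = "PLE"` fits
#' `ln A_T = gamma + alpha * ln(L_KS W_KS)` with the slope free. RMSE uses
#' divisor `n` (the flower count); AIC uses the Gaussian maximum
#' likelihood (see [compute_aic()]) with parameter counts 1 (MKSE) and 2
#' (PLE) plus one for the error variance.
#'
#' @param flowers Tibble of flower summaries with positive `A_T`, `L_KS`,
#'   `W_KS` (see [aggregate_flowers()]).
#' @param model `"MKSE"` or `"PLE"`.
#' @inheritParams fit_montgomery
#' @return A `petal_model_fit`.
#' @export
fit_total_area_model <- function(flowers, model = c("MKSE", "PLE"),
                                 bootstrap = 0, seed = NULL) {
  model <- match.arg(model)
  check_positive(flowers, c("A_T", "L_KS", "W_KS"))
  n <- nrow(flowers)
  if (n < 3) stop("need at least 3 flowers", call. = FALSE)
  lx <- log(flowers$L_KS * flowers$W_KS)
  ly <- log(flowers$A_T)
  if (model == "MKSE") {
    fit <- ols_offset(lx, ly)
    slope <- 1
  } else {
    fit <- ols_simple(lx, ly)
    slope <- fit$slope
  }
  ci <- if (bootstrap > 0) {
    boot_intervals(lx, ly, slope_free = (model == "PLE"), B = bootstrap,
                   seed = seed)
  }
  new_model_fit(model, fit$intercept, slope, n, fit$rss,
                stats::cor(lx, ly), ci = ci, B = as.integer(bootstrap),
                seed = seed)
}

# intercept-only OLS of ly on offset lx
ols_offset <- function(lx, ly) {
  a <- mean(ly - lx)
  list(intercept = a, rss = sum((ly - lx - a)^2))
}

# simple linear OLS (closed form)
ols_simple <- function(lx, ly) {
  mx <- mean(lx); my <- mean(ly)
  sxx <- sum((lx - mx)^2)
  if (sxx == 0) stop("predictor has no variation; slope underdetermined",
                     call. = FALSE)
  b <- sum((lx - mx) * (ly - my)) / sxx
  a <- my - b * mx
  list(intercept = a, slope = b, rss = sum((ly - a - b * lx)^2))
}

#' Predict individual petal area from the fitted Montgomery equation
#'
#' @param fit A `petal_model_fit` with model `"ME"`.
#' @param L,W Petal length and width (cm), vectorised.
#' @return Predicted area(s) `k_hat * L * W` in cm^2.
#' @export
predict_area <- function(fit, L, W) {
  stopifnot(inherits(fit, "petal_model_fit"))
  if (fit$model != "ME") {
    stop("predict_area() requires an ME fit; use predict_total_area() for ",
         fit$model, call. = FALSE)
  }
  fit$k_hat * L * W
}

#' Predict total petal area per flower from an MKSE or PLE fit
#'
#' @param fit A `petal_model_fit` with model `"MKSE"` or `"PLE"`.
#' @param L_KS,W_KS Sum of petal widths and maximum petal length (cm).
#' @return Predicted corolla area(s) in cm^2.
#' @export
predict_total_area <- function(fit, L_KS, W_KS) {
  stopifnot(inherits(fit, "petal_model_fit"))
  if (!fit$model %in% c("MKSE", "PLE")) {
    stop("predict_total_area() requires an MKSE or PLE fit", call. = FALSE)
  }
  exp(fit$intercept) * (L_KS * W_KS)^fit$slope
}

#' Root-mean-square error of log-scale predictions
#'
#' `sqrt(mean((obs_log - pred_log)^2))`; the divisor is the number of
#' observations `n`, not `n - p`.
#'
#' @param obs_log,pred_log Equal-length numeric vectors of natural-log
#'   observed and predicted values.
#' @return The RMSE (nonnegative scalar).
#' @export
compute_rmse <- function(obs_log, pred_log) {
  if (length(obs_log) == 0) stop("empty vectors", call. = FALSE)
  if (length(obs_log) != length(pred_log)) {
    stop("obs_log and pred_log differ in length", call. = FALSE)
  }
  sqrt(mean((obs_log - pred_log)^2))
}

#' Akaike information criterion from a Gaussian log-likelihood
#'
#' `AIC = 2p - 2 logL` where `p = n_params + 1` counts the regression
#' parameters plus one for the error variance, and `logL` is the Gaussian
#' maximum with the ML variance `rss / n`:
#' `logL = -(n/2) (ln 2*pi + ln(rss/n) + 1)`.
#'
#' @param n Number of observations.
#' @param rss Sum of squared log-scale residuals (> 0).
#' @param n_params Number of regression parameters (1 for ME/MKSE, 2 for
#'   PLE).
#' @return The AIC value.
#' @export
compute_aic <- function(n, rss, n_params) {
  stopifnot(n >= 1, n_params >= 1)
  if (rss <= 0) {
    stop("degenerate likelihood: rss = 0 has no finite AIC", call. = FALSE)
  }
  p <- n_params + 1
  logL <- -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
  2 * p - 2 * logL
}

#' Percent error between a simpler and a more complex model's RMSE
#'
#' `PE = (rmse_1 - rmse_2) / rmse_1 * 100`, with subscript 1 the simpler
#' model (MKSE) and 2 the complex one (PLE). When the complex model nests
#' the simple one and both are least-squares fits on the same data, PE is
#' nonnegative.
#'
#' @param rmse_1 RMSE of the simpler model (> 0).
#' @param rmse_2 RMSE of the complex model.
#' @return PE in percent.
#' @export
percent_error <- function(rmse_1, rmse_2) {
  if (rmse_1 <= 0) stop("rmse_1 must be positive", call. = FALSE)
  (rmse_1 - rmse_2) / rmse_1 * 100
}

#' Choose between the MKSE and the PLE by percent error
#'
#' The extra PLE parameter is judged worthwhile when the percent error
#' exceeds the threshold (default 5 percent); at or below the threshold
#' the simpler MKSE is preferred. The decision trace also records both
#' AICs and, when the PLE fit carries a bootstrap CI, whether the slope CI
#' contains 1 (a slope CI excluding 1 corroborates a non-isometric
#' scaling).
#'
#' @param fit_mkse,fit_ple `petal_model_fit`s of both models on the same
#'   data (equal `n`).
#' @param threshold PE threshold in percent (default 5).
#' @return A list of class `model_comparison`: `rmse_1`, `rmse_2`, `pe`,
#'   `aic_1`, `aic_2`, `preferred`, `rule_trace`.
#' @export
select_model <- function(fit_mkse, fit_ple, threshold = 5) {
  stopifnot(inherits(fit_mkse, "petal_model_fit"),
            inherits(fit_ple, "petal_model_fit"))
  if (fit_mkse$model != "MKSE" || fit_ple$model != "PLE") {
    stop("arguments must be an MKSE fit and a PLE fit, in that order",
         call. = FALSE)
  }
  if (fit_mkse$n != fit_ple$n) {
    stop("fits were made on different data (n = ", fit_mkse$n, " vs ",
         fit_ple$n, ")", call. = FALSE)
  }
  pe <- percent_error(fit_mkse$rmse, fit_ple$rmse)
  preferred <- if (pe > threshold) "PLE" else "MKSE"
  trace <- sprintf(
    "PE = %.4g%% vs threshold %g%% -> %s preferred; AIC MKSE = %.6g, AIC PLE = %.6g",
    pe, threshold, preferred, fit_mkse$aic, fit_ple$aic)
  if (pe < 0) {
    trace <- paste0(trace, "; note PE < 0 (complex model fit worse)")
  }
  if (!is.null(fit_ple$ci)) {
    inside <- fit_ple$ci$slope[1] <= 1 && 1 <= fit_ple$ci$slope[2]
    trace <- paste0(trace, sprintf(
      "; PLE slope 95%% CI [%.4g, %.4g] %s 1",
      fit_ple$ci$slope[1], fit_ple$ci$slope[2],
      if (inside) "contains" else "excludes"))
  }
  structure(
    list(rmse_1 = fit_mkse$rmse, rmse_2 = fit_ple$rmse, pe = pe,
         aic_1 = fit_mkse$aic, aic_2 = fit_ple$aic,
         preferred = preferred, rule_trace = trace),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model comparison>\n  ", x$rule_trace, "\n", sep = "")
  invisible(x)
}

#' Bootstrap confidence intervals for a scaling-model fit
#'
#' Nonparametric case resampling: observation pairs are resampled with
#' replacement `B` times, the model is refitted to each resample, and 95
#' percent percentile (2.5/97.5 percent) bounds are taken. Reproducible
#' given `seed`.
#'
#' @param data Petal table (for `model = "ME"`) or flower summary table
#'   (for `"MKSE"`/`"PLE"`).
#' @param model `"ME"`, `"MKSE"` or `"PLE"`.
#' @param B Number of bootstrap replicates (default 3000).
#' @param seed RNG seed (mandatory).
#' @return List with elements `intercept`, `slope`, `k` (each a length-2
#'   interval), plus `B` and `seed`.
#' @export
bootstrap_ci <- function(data, model = c("ME", "MKSE", "PLE"), B = 3000,
                         seed) {
  model <- match.arg(model)
  if (missing(seed) || is.null(seed)) {
    stop("seed is required for a reproducible bootstrap", call. = FALSE)
  }
  stopifnot(B >= 1)
  if (model == "ME") {
    check_positive(data, c("A", "L", "W"))
    lx <- log(data$L * data$W); ly <- log(data$A)
  } else {
    check_positive(data, c("A_T", "L_KS", "W_KS"))
    lx <- log(data$L_KS * data$W_KS); ly <- log(data$A_T)
  }
  ci <- boot_intervals(lx, ly, slope_free = (model == "PLE"), B = B,
                       seed = seed)
  c(ci, list(B = as.integer(B), seed = seed))
}

# vectorised case-resampling bootstrap on the log scale
boot_intervals <- function(lx, ly, slope_free, B, seed) {
  if (is.null(seed)) {
    stop("seed is required for a reproducible bootstrap", call. = FALSE)
  }
  n <- length(lx)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  if (!slope_free) {
    r <- ly - lx
    a <- colMeans(matrix(r[idx], nrow = n))
    b <- rep(1, B)
  } else {
    X <- matrix(lx[idx], nrow = n)
    Y <- matrix(ly[idx], nrow = n)
    mx <- colMeans(X); my <- colMeans(Y)
    sxy <- colMeans(X * Y) - mx * my
    sxx <- colMeans(X * X) - mx^2
    ok <- sxx > 0 # drop degenerate resamples (all identical x)
    b <- (sxy / sxx)[ok]
    a <- (my - (sxy / sxx) * mx)[ok]
  }
  q <- function(v) unname(stats::quantile(v, c(0.025, 0.975)))
  list(intercept = q(a), slope = q(b), k = exp(q(a)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

check_positive <- function(df, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cl in cols) {
    v <- df[[cl]]
    if (anyNA(v) || any(v <= 0)) {
      stop("column ", cl, " must be positive and non-missing", call. = FALSE)
    }
  }
  invisible(df)
}
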