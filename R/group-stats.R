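#' Tukey HSD comparison of a trait between groups
#'
#' Pairwise studentized-range (Tukey-Kramer) tests on a one-way layout:
#' for groups i, j with means `m`, sizes `n` and the pooled within-group
#' mean square `MSE` on `N - k` degrees of freedom,
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, with p-values from
#' the studentized range distribution on `k` means. With exactly two
#' groups this reduces to the pooled-variance two-sample t-test
#' (`q = sqrt(2) |t|`). Group means are summarised by a compact letter
#' display assigned in order of descending mean: groups sharing a letter
#' do not differ at level `alpha`.
#'
#' Observations are treated as independent; when petals from the same
#' flower are pooled, flower-level correlation is ignored (a documented
#' caveat, not a modelling choice).
#'
#' @param values Numeric trait values.
#' @param group Group labels (same length as `values`); each group needs
#'   >= 2 observations.
#' @param alpha Significance level (default 0.05).
#' @param trait Trait name carried into the output.
#' @return A list of class `group_comparison`: `trait`, `alpha`, `means`
#'   (tibble of group, n, mean, letters) and `pairs` (tibble of pairwise
#'   diff, q, p).
#' @export
#' @examples
#' set.seed(1)
#' tukey_hsd(c(rnorm(20), rnorm(20, 3)), rep(c("a", "b"), each = 20))
tukey_hsd <- function(values, group, alpha = 0.05, trait = "trait") {
  if (length(values) != length(group)) {
    stop("values and group must have equal length", call. = FALSE)
  }
  group <- as.character(group)
  ok <- stats::complete.cases(values, group)
  values <- values[ok]; group <- group[ok]
  sizes <- table(group)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }

  k <- length(sizes)
  N <- length(values)
  means <- tapply(values, group, mean)
  mse <- sum(tapply(values, group, function(v) sum((v - mean(v))^2))) / (N - k)
  df <- N - k

  gnames <- names(means)
  pair <- utils::combn(gnames, 2)
  di <- means[pair[1, ]] - means[pair[2, ]]
  se <- sqrt(mse / 2 * (1 / sizes[pair[1, ]] + 1 / sizes[pair[2, ]]))
  qstat <- abs(di) / se
  pval <- stats::ptukey(qstat, nmeans = k, df = df, lower.tail = FALSE)
  pairs <- tibble::tibble(
    group_1 = pair[1, ], group_2 = pair[2, ],
    diff = as.numeric(di), q = as.numeric(qstat), p = as.numeric(pval)
  )

  letters_by_group <- cld_letters(gnames, means, pairs, alpha)
  ord <- order(-means)
  means_tbl <- tibble::tibble(
    group = gnames[ord],
    n = as.integer(sizes[ord]),
    mean = as.numeric(means[ord]),
    letters = letters_by_group[ord]
  )
  structure(
    list(trait = trait, alpha = alpha, means = means_tbl, pairs = pairs),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<Tukey HSD, trait '%s', alpha = %g>\n", x$trait, x$alpha))
  print(as.data.frame(x$means), row.names = FALSE)
  invisible(x)
}

# compact letter display: groups are visited in descending mean order and
# join every letter class whose members they do not differ from; a group
# compatible with no existing class opens a new letter
cld_letters <- function(gnames, means, pairs, alpha) {
  signif_pair <- function(a, b) {
    hit <- (pairs$group_1 == a & pairs$group_2 == b) |
      (pairs$group_1 == b & pairs$group_2 == a)
    pairs$p[hit] < alpha
  }
  ord <- gnames[order(-means)]
  classes <- list()
  for (g in ord) {
    placed <- FALSE
    for (i in seq_along(classes)) {
      if (!any(vapply(classes[[i]], signif_pair, logical(1), b = g))) {
        classes[[i]] <- c(classes[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) classes[[length(classes) + 1]] <- g
  }
  vapply(gnames, function(g) {
    paste(letters[which(vapply(classes, function(cl) g %in% cl, TRUE))],
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Compare petal and flower traits between species
#'
#' Runs [tukey_hsd()] for the standard trait set of the analysis: per
#' petal `A`, `L`, `W` and the shape ratio `W/L`; per flower `A_T` and the
#' composite ratio `W_KS/L_KS`.
#'
#' @param petals Tibble of petal records.
#' @param flowers Optional tibble of flower summaries (computed from
#'   `petals` when omitted).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per trait x group: `trait`, `group`, `n`,
#'   `mean`, `letters`, `p_min` (smallest pairwise p for the trait).
#' @export
compare_species_traits <- function(petals, flowers = NULL, alpha = 0.05) {
  if (is.null(flowers)) flowers <- aggregate_flowers(petals)
  traits <- list(
    A = list(v = petals$A, g = petals$species),
    L = list(v = petals$L, g = petals$species),
    W = list(v = petals$W, g = petals$species),
    `W/L` = list(v = petals$W / petals$L, g = petals$species),
    A_T = list(v = flowers$A_T, g = flowers$species),
    `W_KS/L_KS` = list(v = flowers$W_KS / flowers$L_KS, g = flowers$species)
  )
  dplyr::bind_rows(lapply(names(traits), function(tn) {
    res <- tukey_hsd(traits[[tn]]$v, traits[[tn]]$g, alpha = alpha,
                     trait = tn)
    dplyr::mutate(res$means, trait = tn, p_min = min(res$pairs$p),
                  .before = 1)
  }))
}
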