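#' Aggregate petal records into per-flower corolla summaries
#'
#' Implements the Koyama-Smith construction for a flower: the total petal
#' area `A_T` is the sum of member petal areas, `L_KS` is the sum of
#' individual petal widths, and `W_KS` is the maximum individual petal
#' length. (The "KS" composite length is a sum of *widths* and the
#' composite width a maximum of *lengths* — the naming follows the
#' foliage-per-shoot analogy, where petals laid side by side form a strip
#' of length sum(W) and width max(L).) Flowers are identified by exact
#' (species, flower_id) string pairs, so flower ids need only be unique
#' within species.
#'
#' Because each petal satisfies `A <= L * W` and `L <= W_KS`, every
#' summary satisfies `A_T <= L_KS * W_KS`; consequently a fitted MKSE
#' proportionality coefficient cannot exceed 1 on measured data.
#'
#' @param petals Tibble/data frame of petal records with columns `species`,
#'   `flower_id`, `A`, `L`, `W` (see [measure_petal()]).
#' @return A tibble with one row per flower: `species`, `flower_id`,
#'   `n_petals`, `A_T`, `L_KS`, `W_KS`.
#' @export
#' @examples
#' petals <- tibble::tibble(
#'   species = "sp", flower_id = "f1", petal_id = as.character(1:3),
#'   A = c(1, 2, 1.5), L = c(2, 2.5, 2), W = c(1, 1.5, 1.2)
#' )
#' aggregate_flowers(petals) # A_T = 4.5, L_KS = 3.7, W_KS = 2.5
aggregate_flowers <- function(petals) {
  if (is.null(petals) || nrow(petals) == 0) {
    stop("no petal records to aggregate", call. = FALSE)
  }
  need <- c("species", "flower_id", "A", "L", "W")
  miss <- setdiff(need, names(petals))
  if (length(miss)) {
    stop("petal table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(petals$species)) || any(!nzchar(petals$flower_id)) ||
      anyNA(petals$species) || anyNA(petals$flower_id)) {
    stop("species and flower_id must be nonempty for every petal",
         call. = FALSE)
  }
  if (any(petals$A <= 0 | petals$L <= 0 | petals$W <= 0)) {
    stop("all petal A, L, W must be positive", call. = FALSE)
  }
  petals |>
    dplyr::group_by(.data$species, .data$flower_id) |>
    dplyr::summarise(
      n_petals = dplyr::n(),
      A_T = sum(.data$A),
      L_KS = sum(.data$W),
      W_KS = max(.data$L),
      .groups = "drop"
    )
}

#' Read a per-petal measurement table
#'
#' Ingests externally measured petal data as delimited text with columns
#' `species,flower_id,petal_id,A,L,W` (area in cm^2, lengths in cm);
#' lines starting with `#` are treated as unit comments. This is also the
#' format written by [write_petal_table()].
#'
#' @param path CSV/TSV path.
#' @return Tibble of petal records.
#' @export
read_petal_table <- function(path) {
  df <- readr::read_delim(path, comment = "#", progress = FALSE,
                          show_col_types = FALSE)
  need <- c("species", "flower_id", "petal_id", "A", "L", "W")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("petal table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$species <- as.character(df$species)
  df$flower_id <- as.character(df$flower_id)
  df$petal_id <- as.character(df$petal_id)
  tibble::as_tibble(df)
}

#' Write a per-petal measurement table
#'
#' @param petals Tibble of petal records.
#' @param path Output CSV path; a `#` comment records the units.
#' @return `path`, invisibly.
#' @export
write_petal_table <- function(petals, path) {
  writeLines("# units: A in cm^2, L and W in cm", path)
  readr::write_csv(petals, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a per-flower summary table
#'
#' @param flowers Tibble from [aggregate_flowers()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flower_table <- function(flowers, path) {
  writeLines("# units: A_T in cm^2, L_KS and W_KS in cm", path)
  readr::write_csv(flowers, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
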