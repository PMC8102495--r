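# Occurrence statistics: detection frequencies, mean-of-detects summaries,
# multi-residue distributions.

#' Summarise residue occurrence per commodity and pesticide
#'
#' Collapses a sample-level residue table to one row per (commodity,
#' pesticide) with at least one detect: number of samples of the commodity,
#' number of detects, and minimum / maximum / mean concentration over the
#' *detected* samples only. Non-detects contribute nothing to the level
#' statistics (no zero or LOD/2 substitution), matching how monitoring
#' surveys report a detects-only range alongside the mean; pesticides never
#' detected in a commodity are omitted.
#'
#' @param samples sample-level tibble as returned by
#'   [read_residue_samples()] or [generate_samples()].
#' @return tibble with columns `commodity`, `pesticide`, `n_samples`,
#'   `n_detects`, `min_ug_kg`, `max_ug_kg`, `mean_ug_kg`, ordered by
#'   commodity then pesticide.
#' @export
#' @examples
#' samples <- tibble::tibble(
#'   sample_id = c("a", "b", "c", "d", "e"),
#'   commodity = "strawberry", pesticide = "boscalid",
#'   concentration_ug_kg = c(10, 20, 30, NA, NA),
#'   detected = c(TRUE, TRUE, TRUE, FALSE, FALSE)
#' )
#' summarize_occurrence(samples)
summarize_occurrence <- function(samples) {
  stop_if_missing_cols(samples, c("sample_id", "commodity", "pesticide",
                                  "concentration_ug_kg", "detected"),
                       "sample table")
  n_per_commodity <- samples |>
    distinct(.data$commodity, .data$sample_id) |>
    count(.data$commodity, name = "n_samples")
  if (!any(samples$detected)) {
    return(tibble(commodity = character(), pesticide = character(),
                  n_samples = integer(), n_detects = integer(),
                  min_ug_kg = double(), max_ug_kg = double(),
                  mean_ug_kg = double()))
  }
  samples |>
    filter(.data$detected) |>
    group_by(.data$commodity, .data$pesticide) |>
    summarise(n_detects = dplyr::n(),
              min_ug_kg = min(.data$concentration_ug_kg),
              max_ug_kg = max(.data$concentration_ug_kg),
              mean_ug_kg = mean(.data$concentration_ug_kg),
              .groups = "drop") |>
    left_join(n_per_commodity, by = "commodity") |>
    select("commodity", "pesticide", "n_samples", "n_detects",
           "min_ug_kg", "max_ug_kg", "mean_ug_kg") |>
    arrange(.data$commodity, .data$pesticide)
}

#' Detection rate per commodity
#'
#' Percentage of samples of a commodity in which at least one pesticide was
#' detected.
#'
#' @param samples sample-level residue tibble.
#' @param commodity optional single commodity label; when given, only that
#'   commodity is returned and an absent commodity is an error.
#' @return tibble with columns `commodity`, `n_samples`,
#'   `n_contaminated`, `detection_rate_pct` (unrounded).
#' @export
detection_rate <- function(samples, commodity = NULL) {
  stop_if_missing_cols(samples, c("sample_id", "commodity", "detected"),
                       "sample table")
  if (!is.null(commodity)) {
    keep <- canon_name(samples$commodity) %in% canon_name(commodity)
    if (!any(keep)) {
      abort(sprintf("no samples of commodity '%s'", commodity))
    }
    samples <- samples[keep, ]
  }
  samples |>
    group_by(.data$commodity, .data$sample_id) |>
    summarise(any_detect = any(.data$detected), .groups = "drop") |>
    group_by(.data$commodity) |>
    summarise(n_samples = dplyr::n(),
              n_contaminated = sum(.data$any_detect),
              detection_rate_pct = 100 * .data$n_contaminated / .data$n_samples,
              .groups = "drop")
}

#' Multi-residue distribution per commodity
#'
#' Tallies, for each commodity, how many samples carry k = 0, 1, 2, ...
#' distinct detected pesticides. The counts over k sum to the commodity
#' sample count, and the share of samples with `k >= 2` is the usual
#' multi-residue headline.
#'
#' @param samples sample-level residue tibble.
#' @return tibble with columns `commodity`, `k` (number of distinct
#'   detected pesticides in a sample), `n` (samples with that k) and
#'   `n_samples` (commodity total).
#' @seealso [prop_with_at_least()], [plot_multi_residue()]
#' @export
multi_residue_distribution <- function(samples) {
  stop_if_missing_cols(samples, c("sample_id", "commodity", "pesticide",
                                  "detected"), "sample table")
  per_sample <- samples |>
    group_by(.data$commodity, .data$sample_id) |>
    summarise(k = dplyr::n_distinct(.data$pesticide[.data$detected]),
              .groups = "drop")
  per_sample |>
    count(.data$commodity, .data$k, name = "n") |>
    group_by(.data$commodity) |>
    mutate(n_samples = sum(.data$n)) |>
    ungroup() |>
    arrange(.data$commodity, .data$k)
}

#' Share of samples carrying at least k residues
#'
#' @param dist tibble from [multi_residue_distribution()].
#' @param k minimum number of distinct detected pesticides (default 2).
#' @return tibble with columns `commodity`, `pct_at_least_k`.
#' @export
prop_with_at_least <- function(dist, k = 2) {
  stop_if_missing_cols(dist, c("commodity", "k", "n", "n_samples"),
                       "multi-residue distribution")
  dist |>
    group_by(.data$commodity) |>
    summarise(pct_at_least_k = 100 * sum(.data$n[.data$k >= !!k]) /
                .data$n_samples[1],
              .groups = "drop")
}
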