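# LC-MS multi-residue method validation metrics: matrix effect, recovery
# and precision against the SANTE acceptance windows, S/N-based LOD/LOQ,
# calibration linearity, and cohort summaries.

#' Matrix effect of a co-extracted sample matrix
#'
#' ME (%) = 100 * (matrix-matched peak area - solvent peak area) / solvent
#' peak area. Signal suppression gives negative values, enhancement
#' positive ones. Classification: `suppression` below -20%, `enhancement`
#' above +20%, otherwise `negligible`; values exactly at +/-20 fall in
#' `negligible` (the acceptable band is conventionally quoted as the open
#' interval -20% < ME < 20%, so the boundary assignment is a package
#' convention).
#'
#' @param matrix_area,solvent_area peak areas of the matrix-matched and
#'   solvent standards at the same concentration; `solvent_area` must be
#'   positive. Vectorised.
#' @return tibble with columns `me_pct`, `me_class`.
#' @export
#' @examples
#' matrix_effect(80, 100)   # -20%, negligible (boundary)
#' matrix_effect(130, 100)  # +30%, enhancement
matrix_effect <- function(matrix_area, solvent_area) {
  if (any(is.na(solvent_area) | solvent_area <= 0)) {
    abort("solvent_area must be positive")
  }
  me <- 100 * (matrix_area - solvent_area) / solvent_area
  tibble(me_pct = me, me_class = classify_me(me))
}

classify_me <- function(me_pct) {
  dplyr::case_when(me_pct < -20 ~ "suppression",
                   me_pct > 20 ~ "enhancement",
                   TRUE ~ "negligible")
}

#' Recovery and precision of a spiked replicate set
#'
#' Mean recovery = 100 * mean(measured) / spiked; RSD = 100 * sd / mean
#' using the sample (n-1) standard deviation, the convention for replicate
#' validation data. The verdict follows the SANTE window: `low` below 70%,
#' `acceptable` within 70-120%, `high` above 120%; `rsd_flag` marks RSD
#' above 20%.
#'
#' @param measured numeric vector of measured concentrations (>= 2
#'   replicates) at one spike level.
#' @param spiked the spiked (true) concentration, > 0, same units.
#' @return one-row tibble: `n`, `mean_recovery_pct`, `rsd_pct`, `verdict`,
#'   `rsd_flag`.
#' @export
#' @examples
#' recovery_stats(c(5.2, 5.3, 5.4), spiked = 10) # low, 53%
recovery_stats <- function(measured, spiked) {
  if (length(spiked) != 1L || is.na(spiked) || spiked <= 0) {
    abort("spiked concentration must be a single positive number")
  }
  if (length(measured) < 2L) abort("at least two replicates are required")
  m <- mean(measured)
  recovery <- 100 * m / spiked
  rsd <- 100 * stats::sd(measured) / m
  tibble(n = length(measured), mean_recovery_pct = recovery, rsd_pct = rsd,
         verdict = classify_recovery(recovery), rsd_flag = rsd > 20)
}

classify_recovery <- function(recovery_pct) {
  dplyr::case_when(recovery_pct < 70 ~ "low",
                   recovery_pct > 120 ~ "high",
                   TRUE ~ "acceptable")
}

#' Detection and quantification limits from signal-to-noise
#'
#' LOD and LOQ are defined as the concentrations giving 3x and 10x the
#' signal-to-background-noise ratio of a spiked blank; assuming a linear
#' response through the spiked level, LOD = 3 * spike / S/N and
#' LOQ = 10 * spike / S/N, so LOQ/LOD is exactly 10/3. No clipping is
#' applied.
#'
#' @param spike_concentration spiked blank concentration, ug/kg (> 0).
#' @param observed_snr signal-to-noise ratio observed at that spike (> 0).
#'   Vectorised.
#' @return tibble with columns `lod_ug_kg`, `loq_ug_kg`.
#' @export
#' @examples
#' lod_loq(10, 50) # LOD 0.6, LOQ 2
lod_loq <- function(spike_concentration, observed_snr) {
  if (any(is.na(observed_snr) | observed_snr <= 0)) {
    abort("observed_snr must be positive")
  }
  if (any(is.na(spike_concentration) | spike_concentration <= 0)) {
    abort("spike concentration must be positive")
  }
  tibble(lod_ug_kg = 3 * spike_concentration / observed_snr,
         loq_ug_kg = 10 * spike_concentration / observed_snr)
}

#' Calibration linearity check
#'
#' @param r_squared coefficient(s) of determination of the matrix-matched
#'   calibration curve, in \[0, 1\].
#' @return logical; `TRUE` when r^2 is strictly greater than 0.990.
#' @export
linearity_check <- function(r_squared) {
  if (any(is.na(r_squared) | r_squared < 0 | r_squared > 1)) {
    abort("r_squared must lie in [0, 1]")
  }
  r_squared > 0.990
}

#' Summarise a cohort of validation records
#'
#' Counts recovery verdicts (and, when present, matrix-effect classes and
#' RSD flags) over per-pesticide validation records, with percentages of
#' the total reported to one decimal (half away from zero).
#'
#' @param records tibble with one row per pesticide; must contain
#'   `mean_recovery_pct`, may contain `rsd_pct` and `me_pct`.
#' @return list of class `validation_summary`: `n_records`, tibble
#'   `recovery` (`verdict`, `n`, `pct`), and (when inputs carry them)
#'   tibbles `me` (`me_class`, `n`, `pct`) and `rsd` (`rsd_flag`, `n`).
#' @export
#' @examples
#' rec <- tibble::tibble(mean_recovery_pct = c(rep(95, 269), rep(60, 3),
#'                                             rep(130, 12)))
#' validation_summary(rec)$recovery
validation_summary <- function(records) {
  stop_if_missing_cols(records, "mean_recovery_pct", "validation records")
  if (!nrow(records)) abort("at least one validation record is required")
  n <- nrow(records)
  recovery <- records |>
    mutate(verdict = factor(classify_recovery(.data$mean_recovery_pct),
                            levels = c("low", "acceptable", "high"))) |>
    count(.data$verdict, .drop = FALSE, name = "n") |>
    mutate(verdict = as.character(.data$verdict),
           pct = round_half_away(100 * .data$n / !!n, 1))
  out <- list(n_records = n, recovery = recovery)
  if ("me_pct" %in% names(records)) {
    out$me <- records |>
      filter(!is.na(.data$me_pct)) |>
      mutate(me_class = factor(classify_me(.data$me_pct),
                               levels = c("suppression", "negligible",
                                          "enhancement"))) |>
      count(.data$me_class, .drop = FALSE, name = "n") |>
      mutate(me_class = as.character(.data$me_class),
             pct = round_half_away(100 * .data$n / sum(.data$n), 1))
  }
  if ("rsd_pct" %in% names(records)) {
    out$rsd <- records |>
      summarise(n_flagged = sum(.data$rsd_pct > 20, na.rm = TRUE),
                max_rsd_pct = max(.data$rsd_pct, na.rm = TRUE))
  }
  structure(out, class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("Method validation summary over %d records\n", x$n_records))
  acc <- x$recovery[x$recovery$verdict == "acceptable", ]
  cat(sprintf("  recovery within 70-120%%: %d (%.1f%%); low: %d; high: %d\n",
              acc$n, acc$pct, x$recovery$n[x$recovery$verdict == "low"],
              x$recovery$n[x$recovery$verdict == "high"]))
  if (!is.null(x$me)) {
    neg <- x$me[x$me$me_class == "negligible", ]
    cat(sprintf("  matrix effect negligible (-20%% < ME < 20%%): %d (%.1f%%)\n",
                neg$n, neg$pct))
  }
  if (!is.null(x$rsd)) {
    cat(sprintf("  RSD > 20%%: %d (max %.1f%%)\n",
                x$rsd$n_flagged, x$rsd$max_rsd_pct))
  }
  invisible(x)
}
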