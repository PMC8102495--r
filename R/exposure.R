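# Deterministic dietary exposure assessment.
#
# Chronic: NEDI = (sum_c R_c * F) / bw, %ADI = 100 * NEDI / ADI, with R the
# mean-of-detects residue per commodity (mg/kg) and F/bw the per-group
# chronic consumption ratio (kg food / kg bw / day).
# Acute:   ESTI = (sum_c HR_c * LP) / bw, %ARfD = 100 * ESTI / ARfD, with HR
# the highest residue per commodity and LP/bw the large-portion ratio.
# A hazard quotient below 100% is deemed an acceptable risk.

#' Chronic intake estimate (NEDI)
#'
#' Sums per-commodity mean residues weighted by the chronic consumption
#' ratio. With a single uniform ratio this is `sum(residues) * f_over_bw`;
#' per-commodity ratios may be given as a named vector matched against
#' `names(residues)`.
#'
#' @param residues_mg_kg numeric vector of mean residues R in mg/kg, one per
#'   commodity (optionally named).
#' @param f_over_bw chronic consumption-to-bodyweight ratio(s), kg food per
#'   kg bw per day: a single number applied to every commodity, or a named
#'   vector covering every name in `residues_mg_kg`.
#' @return NEDI in mg per kg body weight per day.
#' @export
#' @examples
#' nedi(c(strawberry = 0.1514), f_over_bw = 3.0993e-3)
nedi <- function(residues_mg_kg, f_over_bw) {
  sum(residues_mg_kg * match_ratio(f_over_bw, residues_mg_kg, "f_over_bw"))
}

#' Acute intake estimate (ESTI)
#'
#' As [nedi()], but using the highest residue per commodity and the
#' large-portion consumption ratio.
#'
#' @param max_residues_mg_kg numeric vector of highest residues HR in mg/kg
#'   per commodity (optionally named).
#' @param lp_over_bw large-portion-to-bodyweight ratio(s), kg food per kg bw
#'   per day; scalar or named vector as in [nedi()].
#' @return ESTI in mg per kg body weight per day.
#' @export
esti <- function(max_residues_mg_kg, lp_over_bw) {
  sum(max_residues_mg_kg * match_ratio(lp_over_bw, max_residues_mg_kg,
                                       "lp_over_bw"))
}

match_ratio <- function(ratio, residues, what) {
  if (any(is.na(ratio) | ratio <= 0)) {
    abort(sprintf("%s must be positive", what))
  }
  if (length(ratio) == 1L && is.null(names(ratio))) {
    return(rep(unname(ratio), length(residues)))
  }
  if (is.null(names(residues)) || is.null(names(ratio))) {
    abort(sprintf("per-commodity %s needs named residues and ratios", what))
  }
  idx <- match(canon_name(names(residues)), canon_name(names(ratio)))
  if (anyNA(idx)) {
    abort(sprintf("no %s ratio for commodity: %s", what,
                  paste(names(residues)[is.na(idx)], collapse = ", ")))
  }
  unname(ratio[idx])
}

#' Chronic hazard quotient (%ADI)
#'
#' @param nedi chronic intake estimate, mg/kg bw/day.
#' @param adi acceptable daily intake, mg/kg bw/day; must be a positive
#'   number (a chronic assessment is impossible without an ADI).
#' @return %ADI = 100 * NEDI / ADI. Values below 100 are deemed acceptable.
#' @export
#' @examples
#' chronic_risk(nedi(c(strawberry = 0.0202), 6.4089e-4), adi = 0.005)
chronic_risk <- function(nedi, adi) {
  if (length(adi) != 1L || is.na(adi) || adi <= 0) {
    abort("chronic assessment requires a positive ADI")
  }
  100 * nedi / adi
}

#' Acute hazard quotient (%ARfD), or a recorded skip
#'
#' A %ARfD is only defined for pesticides with an established acute
#' reference dose. When the ARfD was judged unnecessary by the evaluating
#' body, or was never established, the assessment is skipped and the reason
#' recorded; skips are data, not errors.
#'
#' @param esti acute intake estimate, mg/kg bw/day.
#' @param arfd acute reference dose, mg/kg bw/day (NA unless established).
#' @param arfd_status `"established"`, `"unnecessary"` or
#'   `"not_established"`.
#' @return one-row tibble with `pct_arfd` (NA when skipped) and
#'   `skip_reason` (`"arfd_unnecessary"`, `"arfd_not_established"`, or NA).
#' @export
acute_risk <- function(esti, arfd, arfd_status = "established") {
  if (!arfd_status %in% ARFD_STATUSES) {
    abort("unknown arfd_status")
  }
  if (arfd_status != "established") {
    return(tibble(pct_arfd = NA_real_,
                  skip_reason = paste0("arfd_", arfd_status)))
  }
  if (length(arfd) != 1L || is.na(arfd) || arfd <= 0) {
    abort("established ARfD status requires a positive ARfD value")
  }
  tibble(pct_arfd = 100 * esti / arfd, skip_reason = NA_character_)
}

#' Chronic and acute risk tables across consumer groups
#'
#' The central computation: from an occurrence summary (mean and maximum
#' residue per commodity and pesticide, in ug/kg), a toxicology registry and
#' consumer-group consumption ratios, computes one chronic row per
#' (pesticide, group) and one acute row per (established-ARfD pesticide,
#' group).
#'
#' Residues enter in ug/kg and are converted to mg/kg at this boundary.
#' Chronic intake always sums mean residues across every commodity in which
#' the pesticide was detected. Acute aggregation defaults to the same
#' whole-diet sum of per-commodity maxima (`"sum"`); `"max_commodity"`
#' instead takes the single worst commodity, the more common convention in
#' international short-term intake models.
#'
#' @param occurrence occurrence summary tibble ([summarize_occurrence()]
#'   schema; `mean_ug_kg` and `max_ug_kg` are used).
#' @param tox toxicology registry tibble ([read_tox_registry()] schema).
#' @param groups consumer-group tibble (`group`, `f_over_bw`, `lp_over_bw`).
#' @param acute_aggregation `"sum"` or `"max_commodity"`.
#' @param consumption optional per-commodity ratios: a tibble with columns
#'   `group`, `commodity`, `f_over_bw`, `lp_over_bw` overriding the uniform
#'   group ratios; it must cover every (group, commodity) present.
#' @return an object of class `exposure_assessment`: a list with tibbles
#'   `chronic` (`pesticide`, `group`, `adi_mg_kg_bw_day`, `nedi`,
#'   `pct_adi`), `acute` (`pesticide`, `group`, `arfd_mg_kg_bw_day`,
#'   `esti`, `pct_arfd`), `skipped_acute` (`pesticide`, `skip_reason`),
#'   `unassessed` (pesticides with no ADI), plus the `groups` table and the
#'   aggregation mode. Use [tidy()][generics::tidy] / [glance()]
#'   [generics::glance] / [ggplot2::autoplot()] on it.
#' @export
#' @examples
#' ra <- risk_table(shanghai_occurrence(), shanghai_tox(),
#'                  china_consumer_groups())
#' dplyr::filter(tidy(ra), pesticide == "Difenoconazole")
risk_table <- function(occurrence, tox, groups,
                       acute_aggregation = c("sum", "max_commodity"),
                       consumption = NULL) {
  acute_aggregation <- match.arg(acute_aggregation)
  stop_if_missing_cols(occurrence, c("commodity", "pesticide", "mean_ug_kg",
                                     "max_ug_kg"), "occurrence summary")
  validate_tox_registry(tox)
  validate_consumer_groups(groups)

  tox_key <- mutate(tox, .pest = canon_name(.data$pesticide))
  occ <- occurrence |>
    mutate(.pest = canon_name(.data$pesticide)) |>
    left_join(select(tox_key, ".pest", "adi_mg_kg_bw_day",
                     "arfd_mg_kg_bw_day", "arfd_status"), by = ".pest")
  missing_tox <- occ |>
    filter(is.na(.data$arfd_status)) |>
    distinct(pesticide = .data$pesticide)
  if (nrow(missing_tox)) {
    warn(sprintf("no toxicology reference for: %s; left unassessed",
                 paste(missing_tox$pesticide, collapse = ", ")))
  }

  per_pesticide <- occ |>
    filter(!is.na(.data$arfd_status)) |>
    group_by(.data$.pest) |>
    summarise(pesticide = .data$pesticide[1],
              adi = .data$adi_mg_kg_bw_day[1],
              arfd = .data$arfd_mg_kg_bw_day[1],
              arfd_status = .data$arfd_status[1],
              commodities = list(.data$commodity),
              r_mg = list(ug_to_mg(.data$mean_ug_kg)),
              hr_mg = list(ug_to_mg(.data$max_ug_kg)),
              .groups = "drop")

  ratio_for <- function(group, commodities, col) {
    if (is.null(consumption)) {
      return(groups[[col]][canon_name(groups$group) == canon_name(group)])
    }
    stop_if_missing_cols(consumption, c("group", "commodity", col),
                         "consumption table")
    sub <- consumption[canon_name(consumption$group) == canon_name(group), ]
    v <- stats::setNames(sub[[col]], sub$commodity)
    idx <- match(canon_name(commodities), canon_name(names(v)))
    if (anyNA(idx)) {
      abort(sprintf("missing %s for group '%s', commodity: %s", col, group,
                    paste(commodities[is.na(idx)], collapse = ", ")))
    }
    stats::setNames(unname(v[idx]), commodities)
  }

  cells <- tidyr::expand_grid(per_pesticide, group = groups$group)
  chronic <- cells |>
    filter(!is.na(.data$adi)) |>
    mutate(nedi = purrr::pmap_dbl(
             list(.data$r_mg, .data$commodities, .data$group),
             function(r, com, g) {
               nedi(stats::setNames(r, com), ratio_for(g, com, "f_over_bw"))
             }),
           pct_adi = 100 * .data$nedi / .data$adi) |>
    select("pesticide", "group", adi_mg_kg_bw_day = "adi", "nedi", "pct_adi") |>
    arrange(.data$pesticide, .data$group)

  unassessed <- cells |>
    filter(is.na(.data$adi)) |>
    distinct(pesticide = .data$pesticide) |>
    bind_rows(missing_tox)

  acute_cells <- cells |> filter(.data$arfd_status == "established")
  acute <- acute_cells |>
    mutate(esti = purrr::pmap_dbl(
             list(.data$hr_mg, .data$commodities, .data$group),
             function(hr, com, g) {
               lp <- ratio_for(g, com, "lp_over_bw")
               contrib <- stats::setNames(hr, com) *
                 match_ratio(lp, stats::setNames(hr, com), "lp_over_bw")
               if (acute_aggregation == "sum") sum(contrib) else max(contrib)
             }),
           pct_arfd = 100 * .data$esti / .data$arfd) |>
    select("pesticide", "group", arfd_mg_kg_bw_day = "arfd", "esti",
           "pct_arfd") |>
    arrange(.data$pesticide, .data$group)

  skipped <- per_pesticide |>
    filter(.data$arfd_status != "established") |>
    transmute(pesticide = .data$pesticide,
              skip_reason = paste0("arfd_", .data$arfd_status)) |>
    arrange(.data$pesticide)

  structure(list(chronic = chronic, acute = acute, skipped_acute = skipped,
                 unassessed = unassessed, groups = groups,
                 acute_aggregation = acute_aggregation),
            class = "exposure_assessment")
}

#' @export
print.exposure_assessment <- function(x, ...) {
  cat("Deterministic dietary exposure assessment\n")
  cat(sprintf("  chronic: %d pesticides x %d groups (max %%ADI %.4f)\n",
              dplyr::n_distinct(x$chronic$pesticide), nrow(x$groups),
              suppressWarnings(max(x$chronic$pct_adi))))
  cat(sprintf("  acute:   %d pesticides x %d groups (max %%ARfD %s)\n",
              dplyr::n_distinct(x$acute$pesticide), nrow(x$groups),
              if (nrow(x$acute)) sprintf("%.4f", max(x$acute$pct_arfd)) else "-"))
  cat(sprintf("  acute aggregation: %s; skipped (no ARfD): %d; unassessed (no ADI): %d\n",
              x$acute_aggregation, nrow(x$skipped_acute), nrow(x$unassessed)))
  invisible(x)
}

#' Rank consumer groups by dietary risk
#'
#' Because each hazard quotient is the product of a pesticide-specific
#' scalar and the group's consumption ratio, the group ordering is the same
#' for every pesticide: groups are ranked by `f_over_bw` (chronic) and
#' `lp_over_bw` (acute), highest risk first. Exact ties keep the original
#' label order and are flagged.
#'
#' @param x an `exposure_assessment` or a consumer-group tibble.
#' @param risk_kind `"chronic"`, `"acute"` or `"both"` (default).
#' @return tibble with columns `risk_kind`, `rank`, `group`, `ratio`,
#'   `tied`.
#' @export
rank_groups <- function(x, risk_kind = c("both", "chronic", "acute")) {
  risk_kind <- match.arg(risk_kind)
  groups <- if (inherits(x, "exposure_assessment")) x$groups else x
  validate_consumer_groups(groups)
  kinds <- if (risk_kind == "both") c("chronic", "acute") else risk_kind
  purrr::map_dfr(kinds, function(kind) {
    col <- if (kind == "chronic") "f_over_bw" else "lp_over_bw"
    ord <- order(-groups[[col]], seq_len(nrow(groups)))
    r <- groups[[col]][ord]
    tibble(risk_kind = kind, rank = seq_along(ord),
           group = groups$group[ord], ratio = r,
           tied = duplicated(r) | duplicated(r, fromLast = TRUE))
  })
}

#' Back-derive consumption ratios from published risk cells
#'
#' When a survey publishes its risk tables but not the underlying
#' body-weight / consumption parameters, the per-group ratios are fully
#' determined by any printed cell of a pesticide with known summed residue:
#' `f_over_bw = pct_adi/100 * ADI / sum(R)` and
#' `lp_over_bw = pct_arfd/100 * ARfD / sum(HR)`. The first pesticide listed
#' is the designated reference; the remaining ones are independent
#' cross-checks required to agree within `tol` relative, guarding against a
#' mis-transcribed table or a wrong aggregation model.
#'
#' @param occurrence occurrence summary supplying the residue sums.
#' @param chronic_reference long tibble (`pesticide`, `adi_mg_kg_bw_day`,
#'   `group`, `pct_adi`), e.g. [shanghai_chronic_reference()].
#' @param acute_reference long tibble (`pesticide`, `arfd_mg_kg_bw_day`,
#'   `group`, `pct_arfd`), e.g. [shanghai_acute_reference()].
#' @param chronic_pesticides,acute_pesticides reference pesticides, the
#'   first being the designated calibration reference.
#' @param tol maximum relative disagreement tolerated among reference
#'   pesticides (default 0.003, i.e. 0.3%).
#' @return consumer-group tibble (`group`, `f_over_bw`, `lp_over_bw`) from
#'   the designated references, with a `calibration` attribute holding each
#'   reference's implied ratio and relative deviation.
#' @export
calibrate_consumption_ratios <- function(occurrence, chronic_reference,
                                         acute_reference,
                                         chronic_pesticides =
                                           c("Bifenazate", "Boscalid", "Fosthiazate"),
                                         acute_pesticides =
                                           c("Fluopyram", "Carbendazim", "Acetamiprid"),
                                         tol = 0.003) {
  sum_residues <- function(pesticide, col) {
    rows <- occurrence[canon_name(occurrence$pesticide) == canon_name(pesticide), ]
    if (!nrow(rows)) abort(sprintf("reference pesticide '%s' not in occurrence", pesticide))
    sum(ug_to_mg(rows[[col]]))
  }
  derive <- function(reference, pesticides, dose_col, pct_col, residue_col, kind) {
    purrr::map_dfr(pesticides, function(p) {
      cells <- reference[canon_name(reference$pesticide) == canon_name(p), ]
      if (!nrow(cells)) abort(sprintf("reference pesticide '%s' not in %s table", p, kind))
      tibble(kind = kind, pesticide = p, group = cells$group,
             ratio = cells[[pct_col]] / 100 * cells[[dose_col]] /
               sum_residues(p, residue_col))
    })
  }
  chron <- derive(chronic_reference, chronic_pesticides, "adi_mg_kg_bw_day",
                  "pct_adi", "mean_ug_kg", "chronic")
  acute <- derive(acute_reference, acute_pesticides, "arfd_mg_kg_bw_day",
                  "pct_arfd", "max_ug_kg", "acute")
  calib <- bind_rows(chron, acute) |>
    group_by(.data$kind, .data$group) |>
    mutate(rel_dev = abs(.data$ratio / .data$ratio[1] - 1)) |>
    ungroup()
  bad <- filter(calib, .data$rel_dev > tol)
  if (nrow(bad)) {
    abort(c("reference cells disagree beyond tolerance",
            sprintf("%s / %s / %s: relative deviation %.4f",
                    bad$kind, bad$pesticide, bad$group, bad$rel_dev)))
  }
  designated <- calib |>
    group_by(.data$kind, .data$group) |>
    summarise(ratio = .data$ratio[1], .groups = "drop") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "ratio") |>
    transmute(group = .data$group, f_over_bw = .data$chronic,
              lp_over_bw = .data$acute)
  # keep the group order of the chronic reference table
  ord <- match(unique(chronic_reference$group), designated$group)
  out <- validate_consumer_groups(designated[ord[!is.na(ord)], ])
  attr(out, "calibration") <- calib
  out
}
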