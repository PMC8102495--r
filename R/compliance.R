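# Jurisdiction-aware MRL compliance: per-measurement verdicts, per-sample
# compliance, aggregated rates and exceedance tables.
#
# Exceedance is a strict inequality (concentration > limit); a residue
# exactly at its limit is compliant. Pairs with no limit in a jurisdiction
# are `not_assessable` and never count against a sample. Residue-definition
# sums (e.g. spirotetramat plus its enol) are aggregated within a sample
# before comparison and reported under the parent name.

#' Look up the applicable residue limit
#'
#' Returns the registry entry for a (pesticide, commodity, jurisdiction)
#' triple regardless of its basis (standard, temporary or EU
#' analytical-determination default all bind equally), or a zero-row tibble
#' when no limit is defined.
#'
#' @param registry MRL registry tibble ([read_mrl_registry()] schema).
#' @param pesticide,commodity,jurisdiction single labels; name matching is
#'   case-insensitive and whitespace-trimmed.
#' @return one- or zero-row tibble in the registry schema.
#' @export
#' @examples
#' applicable_limit(shanghai_mrl(), "triflumuron", "grape", "EU")
applicable_limit <- function(registry, pesticide, commodity, jurisdiction) {
  hit <- registry |>
    filter(canon_name(.data$pesticide) == canon_name(!!pesticide),
           canon_name(.data$commodity) == canon_name(!!commodity),
           .data$jurisdiction == toupper(trimws(!!jurisdiction)))
  if (nrow(hit) > 1L) {
    abort("registry holds more than one limit for this (pesticide, commodity, jurisdiction)")
  }
  hit
}

# fold residue-definition components into their parent analyte: within each
# sample, measurements of any listed component are summed and reported under
# the parent name; detected if any component was detected
apply_sum_definitions <- function(samples, registry) {
  defs <- registry |>
    filter(!is.na(.data$sum_components)) |>
    distinct(.data$pesticide, .data$sum_components)
  if (!nrow(defs)) return(samples)
  comp_map <- purrr::pmap_dfr(defs, function(pesticide, sum_components) {
    comps <- unique(c(canon_name(pesticide),
                      canon_name(strsplit(sum_components, ";")[[1]])))
    tibble(parent = pesticide, component = comps)
  })
  samples <- mutate(samples, .comp = canon_name(.data$pesticide))
  hit <- samples$.comp %in% comp_map$component
  if (!any(hit)) return(select(samples, -".comp"))
  folded <- samples[hit, ] |>
    left_join(comp_map, by = c(".comp" = "component"),
              relationship = "many-to-many") |>
    group_by(.data$sample_id, .data$commodity, parent = .data$parent) |>
    summarise(concentration_ug_kg = if (any(.data$detected)) {
      sum(.data$concentration_ug_kg[.data$detected])
    } else NA_real_,
    detected = any(.data$detected), .groups = "drop") |>
    rename(pesticide = "parent")
  bind_rows(select(samples[!hit, ], -".comp"), folded)
}

#' Assess every detected measurement against a jurisdiction's limits
#'
#' @param samples sample-level residue tibble.
#' @param registry MRL registry tibble.
#' @param jurisdiction `"CN"` or `"EU"` (any registry jurisdiction label).
#' @return tibble with one row per detected measurement (after folding
#'   residue-definition sums): `sample_id`, `commodity`, `pesticide`,
#'   `concentration_ug_kg`, `jurisdiction`, `limit_ug_kg`, `basis` and
#'   `status` (`compliant`, `exceeds`, or `not_assessable` when no limit is
#'   defined).
#' @export
assess_measurements <- function(samples, registry, jurisdiction) {
  jurisdiction <- toupper(trimws(jurisdiction))
  reg <- filter(registry, .data$jurisdiction == !!jurisdiction)
  det <- samples |>
    apply_sum_definitions(reg) |>
    filter(.data$detected)
  if (!nrow(det)) {
    return(tibble(sample_id = character(), commodity = character(),
                  pesticide = character(), concentration_ug_kg = double(),
                  jurisdiction = character(), limit_ug_kg = double(),
                  basis = character(), status = character()))
  }
  reg_key <- reg |>
    transmute(.pest = canon_name(.data$pesticide),
              .com = canon_name(.data$commodity),
              limit_ug_kg = .data$limit_ug_kg, basis = .data$basis)
  det |>
    mutate(.pest = canon_name(.data$pesticide),
           .com = canon_name(.data$commodity)) |>
    left_join(reg_key, by = c(".pest", ".com")) |>
    mutate(jurisdiction = !!jurisdiction,
           status = dplyr::case_when(
             is.na(.data$limit_ug_kg) ~ "not_assessable",
             .data$concentration_ug_kg > .data$limit_ug_kg ~ "exceeds",
             TRUE ~ "compliant"
           )) |>
    select("sample_id", "commodity", "pesticide", "concentration_ug_kg",
           "jurisdiction", "limit_ug_kg", "basis", "status")
}

#' Per-sample compliance under one jurisdiction
#'
#' A sample is compliant when none of its measurements exceeds an existing
#' limit; measurements with no defined limit (`not_assessable`) never count
#' against it, so a sample carrying only unregulated residues is compliant.
#'
#' @inheritParams assess_measurements
#' @return tibble with one row per sample: `sample_id`, `commodity`,
#'   `jurisdiction`, `n_exceeding` and logical `compliant`.
#' @export
sample_compliance <- function(samples, registry, jurisdiction) {
  verdicts <- assess_measurements(samples, registry, jurisdiction)
  exceed <- verdicts |>
    filter(.data$status == "exceeds") |>
    count(.data$sample_id, name = "n_exceeding")
  samples |>
    distinct(.data$sample_id, .data$commodity) |>
    left_join(exceed, by = "sample_id") |>
    mutate(n_exceeding = tidyr::replace_na(.data$n_exceeding, 0L),
           jurisdiction = toupper(trimws(!!jurisdiction)),
           compliant = .data$n_exceeding == 0L) |>
    select("sample_id", "commodity", "jurisdiction", "n_exceeding",
           "compliant")
}

#' Overall compliance rate
#'
#' Percentage of all samples with no residue above an existing limit of the
#' jurisdiction.
#'
#' @inheritParams assess_measurements
#' @return one-row tibble: `jurisdiction`, `n_samples`, `n_compliant`,
#'   `compliance_pct` (unrounded).
#' @export
compliance_rate <- function(samples, registry, jurisdiction) {
  per_sample <- sample_compliance(samples, registry, jurisdiction)
  if (!nrow(per_sample)) abort("compliance_rate needs at least one sample")
  tibble(jurisdiction = per_sample$jurisdiction[1],
         n_samples = nrow(per_sample),
         n_compliant = sum(per_sample$compliant),
         compliance_pct = 100 * sum(per_sample$compliant) / nrow(per_sample))
}

#' Exceedance counts per commodity, pesticide and jurisdiction
#'
#' For every (commodity, pesticide) pair with at least one detect and every
#' jurisdiction, counts the samples whose residue strictly exceeds the
#' applicable limit, with the rate expressed against the commodity sample
#' count. Pairs without a defined limit get an NA count (reported as a dash
#' in rendered tables).
#'
#' @param samples sample-level residue tibble.
#' @param registry MRL registry tibble.
#' @param jurisdictions character vector of jurisdictions to assess.
#' @return tibble with columns `commodity`, `pesticide`, `jurisdiction`,
#'   `limit_ug_kg`, `basis`, `n_samples`, `n_exceed`, `exceed_pct`.
#' @export
exceedance_table <- function(samples, registry, jurisdictions = c("CN", "EU")) {
  purrr::map_dfr(jurisdictions, function(j) {
    verdicts <- assess_measurements(samples, registry, j)
    if (!nrow(verdicts)) return(verdicts[0, ])
    n_per_commodity <- samples |>
      distinct(.data$commodity, .data$sample_id) |>
      count(.data$commodity, name = "n_samples")
    verdicts |>
      group_by(.data$commodity, .data$pesticide, .data$jurisdiction,
               .data$limit_ug_kg, .data$basis) |>
      summarise(n_exceed = if (all(is.na(.data$limit_ug_kg))) NA_integer_ else
        sum(.data$status == "exceeds"), .groups = "drop") |>
      left_join(n_per_commodity, by = "commodity") |>
      mutate(exceed_pct = 100 * .data$n_exceed / .data$n_samples) |>
      select("commodity", "pesticide", "jurisdiction", "limit_ug_kg",
             "basis", "n_samples", "n_exceed", "exceed_pct")
  }) |>
    arrange(.data$commodity, .data$pesticide, .data$jurisdiction)
}
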