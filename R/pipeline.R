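# End-to-end orchestration: load registries -> occurrence -> compliance ->
# exposure -> rankings, with report rendering in the style of monitoring
# publications (occurrence/exceedance table, chronic and acute risk tables).

default_config <- function() {
  list(
    inputs = list(mode = "occurrence_level", occurrence = "packaged",
                  samples = "packaged", mrl = "packaged", tox = "packaged",
                  groups = "packaged"),
    jurisdictions = c("CN", "EU"),
    exposure = list(acute_aggregation = "sum"),
    seed = 1L,
    report = list(output_dir = NULL, digits_pct = 4L, digits_conc = 1L)
  )
}

#' Read (or normalise) a pipeline run configuration
#'
#' A run configuration is a nested key-value structure (YAML on disk) with
#' sections `inputs` (`mode`: `occurrence_level` or `sample_level`; paths
#' for `occurrence`, `samples`, `mrl`, `tox`, `groups`, or `"packaged"` for
#' the shipped fixtures), `jurisdictions`, `exposure`
#' (`acute_aggregation`), `seed` and `report` (`output_dir`, `digits_pct`,
#' `digits_conc`). Missing keys take the defaults shown by
#' `read_run_config(list())`.
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return the fully merged configuration list.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a path or a named list")
  out <- utils::modifyList(default_config(), config)
  if (!out$inputs$mode %in% c("occurrence_level", "sample_level")) {
    abort("inputs.mode must be 'occurrence_level' or 'sample_level'")
  }
  out$seed <- as.integer(out$seed)
  out
}

load_input <- function(spec, packaged, reader) {
  if (identical(spec, "packaged")) packaged() else reader(spec)
}

#' Run the full residue-monitoring pipeline
#'
#' Loads registries and residue data, computes occurrence statistics, MRL
#' exceedance and compliance under every configured jurisdiction, the
#' chronic and acute risk tables, and the group risk rankings.
#' Deterministic given the configuration (including its seed).
#'
#' In `occurrence_level` mode exposure is computed directly from the
#' occurrence summary, and sample-level compliance headlines come from an
#' emulated dataset honouring the summary's counts
#' ([emulate_occurrence_table()]). In `sample_level` mode the sample table
#' is read (or emulated when `"packaged"`) and everything downstream is
#' derived from it.
#'
#' @param config a configuration list or YAML path ([read_run_config()]).
#' @return object of class `report_bundle`: a list with `occurrence`,
#'   `exceedance`, `compliance`, `assessment` (an `exposure_assessment`),
#'   `rankings`, `log` (character) and the merged `config`. When
#'   `report$output_dir` is set, rendered tables are also written there.
#' @export
#' @examples
#' \donttest{
#' bundle <- run_pipeline(list(seed = 1))
#' bundle$compliance
#' }
run_pipeline <- function(config = list()) {
  config <- read_run_config(config)
  log <- character()
  say <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
  }
  say("residuerisk %s pipeline run, mode=%s, seed=%d",
      as.character(utils::packageVersion("residuerisk")),
      config$inputs$mode, config$seed)

  mrl <- load_input(config$inputs$mrl, shanghai_mrl, read_mrl_registry)
  tox <- load_input(config$inputs$tox, shanghai_tox, read_tox_registry)
  groups <- load_input(config$inputs$groups, china_consumer_groups,
                       read_consumer_groups)
  say("registries: %d MRL entries, %d toxicology entries, %d consumer groups",
      nrow(mrl), nrow(tox), nrow(groups))

  if (config$inputs$mode == "occurrence_level") {
    occ <- load_input(config$inputs$occurrence, shanghai_occurrence,
                      function(p) readr::read_csv(p, show_col_types = FALSE))
    samples <- if (nrow(occ)) {
      emulate_occurrence_table(occ, mrl, seed = config$seed)
    } else occ[0, ] |> transmute(sample_id = character(),
                                 commodity = character(),
                                 pesticide = character(),
                                 concentration_ug_kg = double(),
                                 detected = logical())
    say("occurrence mode: %d summary rows; emulated %d samples for compliance",
        nrow(occ), dplyr::n_distinct(samples$sample_id))
  } else {
    samples <- if (identical(config$inputs$samples, "packaged")) {
      emulate_occurrence_table(shanghai_occurrence(), mrl,
                               seed = config$seed)
    } else {
      read_residue_samples(config$inputs$samples)
    }
    occ <- summarize_occurrence(samples)
    say("sample mode: %d samples, %d occurrence rows",
        dplyr::n_distinct(samples$sample_id), nrow(occ))
  }

  if (!nrow(occ)) {
    warn("empty residue input; report tables will carry headers only")
    say("warning: empty residue input")
  }

  exceed <- if (nrow(samples)) {
    exceedance_table(samples, mrl, config$jurisdictions)
  } else tibble()
  compliance <- purrr::map_dfr(config$jurisdictions, function(j) {
    if (!nrow(samples)) {
      return(tibble(jurisdiction = j, n_samples = 0L, n_compliant = 0L,
                    compliance_pct = NA_real_))
    }
    compliance_rate(samples, mrl, j)
  })
  for (i in seq_len(nrow(compliance))) {
    say("compliance (%s): %d / %d samples = %.1f%%",
        compliance$jurisdiction[i], compliance$n_compliant[i],
        compliance$n_samples[i],
        round_half_away(compliance$compliance_pct[i], 1))
  }

  assessment <- if (nrow(occ)) {
    risk_table(occ, tox, groups,
               acute_aggregation = config$exposure$acute_aggregation)
  } else {
    risk_table(tibble(commodity = character(), pesticide = character(),
                      mean_ug_kg = double(), max_ug_kg = double()),
               tox, groups,
               acute_aggregation = config$exposure$acute_aggregation)
  }
  if (nrow(assessment$skipped_acute)) {
    say("acute assessment skipped for %d pesticides (%s)",
        nrow(assessment$skipped_acute),
        paste(sprintf("%s: %s", assessment$skipped_acute$pesticide,
                      assessment$skipped_acute$skip_reason), collapse = "; "))
  }
  if (nrow(assessment$unassessed)) {
    say("unassessed (no ADI): %s",
        paste(assessment$unassessed$pesticide, collapse = ", "))
  }
  rankings <- rank_groups(groups)

  bundle <- structure(
    list(occurrence = occ, exceedance = exceed, compliance = compliance,
         assessment = assessment, rankings = rankings, samples = samples,
         log = log, config = config),
    class = "report_bundle")

  if (!is.null(config$report$output_dir)) {
    write_report(bundle, config$report$output_dir)
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Residue monitoring report bundle\n")
  cat(sprintf("  occurrence rows: %d; samples: %d\n", nrow(x$occurrence),
              dplyr::n_distinct(x$samples$sample_id)))
  for (i in seq_len(nrow(x$compliance))) {
    cat(sprintf("  %s compliance: %.1f%%\n", x$compliance$jurisdiction[i],
                round_half_away(x$compliance$compliance_pct[i], 1)))
  }
  print(x$assessment)
  invisible(x)
}

fmt_fixed <- function(x, digits) {
  ifelse(is.na(x), "-",
         formatC(round_half_away(x, digits), format = "f", digits = digits))
}

basis_marker <- function(basis) {
  dplyr::case_when(is.na(basis) ~ "",
                   basis == "temporary" ~ "*",
                   basis == "analytical_determination_default" ~ "**",
                   TRUE ~ "")
}

#' Render a report bundle as display tables
#'
#' Formats the bundle the way monitoring reports print their tables:
#' concentrations to `digits_conc` decimals with a `min-max` range column,
#' limits suffixed with the basis footnote markers (`*` temporary, `**`
#' analytical-determination default), exceedance counts as `n (rate%)`, and
#' percent columns to `digits_pct` decimals (half away from zero). All
#' rounding happens here; the bundle itself keeps full precision.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param digits_pct decimals for percent columns (default from config).
#' @param digits_conc decimals for concentrations.
#' @return named list of character-formatted tibbles: `occurrence`,
#'   `chronic`, `acute`, plus `headlines` (character lines).
#' @export
render_tables <- function(bundle,
                          digits_pct = bundle$config$report$digits_pct,
                          digits_conc = bundle$config$report$digits_conc) {
  occ <- bundle$occurrence
  exceed <- bundle$exceedance
  occurrence_disp <- if (nrow(occ)) {
    wide_ex <- if (nrow(exceed)) {
      exceed |>
        mutate(limit = paste0(fmt_fixed(.data$limit_ug_kg, 0),
                              basis_marker(.data$basis)),
               n_exc = ifelse(is.na(.data$n_exceed), "-",
                              ifelse(.data$n_exceed > 0,
                                     sprintf("%d (%s%%)", .data$n_exceed,
                                             fmt_fixed(.data$exceed_pct, 1)),
                                     "0"))) |>
        select("commodity", "pesticide", "jurisdiction", "limit", "n_exc") |>
        tidyr::pivot_wider(names_from = "jurisdiction",
                           values_from = c("limit", "n_exc"))
    } else NULL
    out <- occ |>
      mutate(range = ifelse(.data$min_ug_kg == .data$max_ug_kg,
                            fmt_fixed(.data$min_ug_kg, digits_conc),
                            paste0(fmt_fixed(.data$min_ug_kg, digits_conc),
                                   "-",
                                   fmt_fixed(.data$max_ug_kg, digits_conc))),
             mean = fmt_fixed(.data$mean_ug_kg, digits_conc)) |>
      select("commodity", "pesticide", "n_samples", "range", "mean")
    if (!is.null(wide_ex)) {
      out <- left_join(out, wide_ex, by = c("commodity", "pesticide"))
      out[is.na(out)] <- "-"
    }
    out
  } else tibble()

  pct_table <- function(df, dose_col, pct_col) {
    if (!nrow(df)) return(tibble())
    df |>
      mutate(pct = fmt_fixed(.data[[pct_col]], digits_pct)) |>
      select("pesticide", dplyr::all_of(dose_col), "group", "pct") |>
      tidyr::pivot_wider(names_from = "group", values_from = "pct")
  }
  chronic_disp <- pct_table(bundle$assessment$chronic, "adi_mg_kg_bw_day",
                            "pct_adi")
  acute_disp <- pct_table(bundle$assessment$acute, "arfd_mg_kg_bw_day",
                          "pct_arfd")

  headlines <- purrr::map_chr(seq_len(nrow(bundle$compliance)), function(i) {
    sprintf("%s compliance: %s%% of samples at or below existing limits (%d/%d)",
            bundle$compliance$jurisdiction[i],
            fmt_fixed(bundle$compliance$compliance_pct[i], 1),
            bundle$compliance$n_compliant[i], bundle$compliance$n_samples[i])
  })
  list(occurrence = occurrence_disp, chronic = chronic_disp,
       acute = acute_disp, headlines = headlines)
}

#' Write a rendered report to a directory
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return the bundle, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rendered <- render_tables(bundle)
  readr::write_csv(rendered$occurrence, file.path(dir, "occurrence.csv"),
                   na = "")
  readr::write_csv(rendered$chronic, file.path(dir, "chronic_risk.csv"),
                   na = "")
  readr::write_csv(rendered$acute, file.path(dir, "acute_risk.csv"), na = "")
  readr::write_csv(bundle$rankings, file.path(dir, "group_rankings.csv"),
                   na = "")
  readr::write_csv(bundle$assessment$skipped_acute,
                   file.path(dir, "acute_skipped.csv"), na = "")
  writeLines(c(rendered$headlines, "", bundle$log),
             file.path(dir, "report.log"))
  invisible(bundle)
}
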