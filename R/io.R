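# Delimited-text readers/writers for residue sample tables and registries.
#
# All tables are UTF-8 delimited text, comma or tab, auto-detected from the
# header line. Concentrations are stored internally in ug/kg; toxicology
# references in mg/kg bw/day. Non-detects are written back as "ND".

ND_MARKERS <- c("nd", "<lod", "")
MRL_BASES <- c("standard", "temporary", "analytical_determination_default",
               "sum_definition")
ARFD_STATUSES <- c("established", "unnecessary", "not_established")

detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_chr <- function(path) {
  readr::read_delim(path, delim = detect_delim(path),
                    col_types = readr::cols(.default = readr::col_character()),
                    na = character(), trim_ws = TRUE, progress = FALSE,
                    show_col_types = FALSE)
}

#' Read a sample-level residue table
#'
#' Parses a delimited file with one row per (sample, pesticide) measurement.
#' The header must name `sample_id`, `commodity`, `pesticide` and a
#' concentration column (`concentration` or `concentration_ug_kg`, in ug/kg).
#' Concentration cells equal to `"ND"`, `"nd"`, `"<LOD"` or empty are read
#' as censored non-detects (`detected = FALSE`, no quantified value); every
#' other cell must parse as a non-negative number.
#'
#' @param path path to a comma- or tab-delimited text file (auto-detected
#'   from the header line).
#' @param commodities optional character vector of admissible commodity
#'   labels; rows with other commodities are rejected with their line number.
#' @return a tibble with columns `sample_id`, `commodity`, `pesticide`,
#'   `concentration_ug_kg` (NA for non-detects) and `detected`.
#' @details Duplicate (sample, pesticide) rows and samples spanning two
#'   commodities violate the sample-record invariants and raise an error
#'   listing the offending file lines.
#' @seealso [write_residue_samples()], [summarize_occurrence()]
#' @export
read_residue_samples <- function(path, commodities = NULL) {
  raw <- read_delim_chr(path)
  nm <- names(raw)
  conc_col <- intersect(c("concentration", "concentration_ug_kg"), nm)[1]
  if (is.na(conc_col)) {
    abort("sample table needs a 'concentration' or 'concentration_ug_kg' column")
  }
  stop_if_missing_cols(raw, c("sample_id", "commodity", "pesticide"),
                       "sample table")
  line_no <- seq_len(nrow(raw)) + 1L # header is line 1

  conc_raw <- trimws(raw[[conc_col]])
  nd <- tolower(conc_raw) %in% ND_MARKERS | is.na(conc_raw)
  conc <- rep(NA_real_, nrow(raw))
  conc[!nd] <- suppressWarnings(as.numeric(conc_raw[!nd]))

  errs <- character()
  bad_num <- !nd & is.na(conc)
  if (any(bad_num)) {
    errs <- c(errs, sprintf("line %d: concentration '%s' is not a number or ND marker",
                            line_no[bad_num], conc_raw[bad_num]))
  }
  bad_neg <- !nd & !is.na(conc) & conc < 0
  if (any(bad_neg)) {
    errs <- c(errs, sprintf("line %d: negative concentration %s",
                            line_no[bad_neg], conc_raw[bad_neg]))
  }
  if (!is.null(commodities)) {
    bad_com <- !(canon_name(raw$commodity) %in% canon_name(commodities))
    if (any(bad_com)) {
      errs <- c(errs, sprintf("line %d: unknown commodity '%s'",
                              line_no[bad_com], raw$commodity[bad_com]))
    }
  }
  key <- paste(canon_name(raw$sample_id), canon_name(raw$pesticide), sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup & duplicated(key))) {
    dup_lines <- split(line_no[dup], key[dup])
    errs <- c(errs, vapply(dup_lines, function(l) {
      sprintf("duplicate (sample, pesticide) rows at lines %s",
              paste(l, collapse = ", "))
    }, character(1)))
  }
  if (length(errs)) {
    abort(c("invalid residue sample table", stats::setNames(errs, rep("x", length(errs)))))
  }

  out <- tibble(
    sample_id = raw$sample_id,
    commodity = raw$commodity,
    pesticide = stringr::str_squish(raw$pesticide),
    concentration_ug_kg = conc,
    detected = !nd
  )
  multi <- out |>
    distinct(.data$sample_id, .data$commodity) |>
    count(.data$sample_id) |>
    filter(.data$n > 1L)
  if (nrow(multi)) {
    abort(sprintf("sample(s) %s appear under more than one commodity",
                  paste(multi$sample_id, collapse = ", ")))
  }
  out
}

#' Write a sample-level residue table
#'
#' Inverse of [read_residue_samples()]: non-detected measurements are written
#' with the `"ND"` marker so a write/read round trip is the identity.
#'
#' @param x tibble as returned by [read_residue_samples()] or
#'   [generate_samples()].
#' @param path output file path.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return `x`, invisibly.
#' @export
write_residue_samples <- function(x, path, delim = ",") {
  stop_if_missing_cols(x, c("sample_id", "commodity", "pesticide",
                            "concentration_ug_kg", "detected"), "sample table")
  out <- x |>
    mutate(concentration = ifelse(.data$detected,
                                  format_num(.data$concentration_ug_kg), "ND")) |>
    select("sample_id", "commodity", "pesticide", "concentration")
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(x)
}

# full-precision, locale-free numeric formatting for round-trips
format_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                      digits = 15), character(1)))
}

#' Read an MRL registry
#'
#' A maximum-residue-limit registry has one row per (jurisdiction, commodity,
#' pesticide) with columns `jurisdiction` (`CN` or `EU`), `commodity`,
#' `pesticide`, `limit_ug_kg` (> 0), `basis` and optionally `sum_components`
#' (a `;`-separated list of analytes counted toward the limit, for residue
#' definitions such as spirotetramat plus its enol metabolite).
#'
#' `basis` is one of `standard`, `temporary` (provisional national limits,
#' China only), `analytical_determination_default` (EU placeholder at the
#' routine method's lower determination bound, EU only) or `sum_definition`.
#'
#' @param path delimited text file.
#' @return a tibble with the columns above (`sum_components` NA when absent).
#' @export
read_mrl_registry <- function(path) {
  raw <- read_delim_chr(path)
  stop_if_missing_cols(raw, c("jurisdiction", "commodity", "pesticide",
                              "limit_ug_kg", "basis"), "MRL registry")
  out <- tibble(
    jurisdiction = toupper(trimws(raw$jurisdiction)),
    commodity = raw$commodity,
    pesticide = stringr::str_squish(raw$pesticide),
    limit_ug_kg = as.numeric(raw$limit_ug_kg),
    basis = trimws(raw$basis),
    sum_components = if ("sum_components" %in% names(raw)) {
      na_if(trimws(raw$sum_components), "")
    } else NA_character_
  )
  validate_mrl_registry(out)
}

validate_mrl_registry <- function(x, what = "MRL registry") {
  if (any(is.na(x$limit_ug_kg) | x$limit_ug_kg <= 0)) {
    abort(sprintf("%s: limits must be positive numbers", what))
  }
  if (!all(x$basis %in% MRL_BASES)) {
    abort(sprintf("%s: basis must be one of %s", what,
                  paste(MRL_BASES, collapse = ", ")))
  }
  if (any(x$basis == "temporary" & x$jurisdiction != "CN")) {
    abort(sprintf("%s: temporary limits are defined for CN only", what))
  }
  if (any(x$basis == "analytical_determination_default" & x$jurisdiction != "EU")) {
    abort(sprintf("%s: analytical-determination defaults are EU entries only", what))
  }
  key <- paste(x$jurisdiction, canon_name(x$commodity), canon_name(x$pesticide))
  if (anyDuplicated(key)) {
    abort(sprintf("%s: duplicated (jurisdiction, commodity, pesticide) entries", what))
  }
  x
}

#' Write an MRL registry
#' @param x tibble as returned by [read_mrl_registry()].
#' @param path output file path.
#' @param delim field delimiter.
#' @return `x`, invisibly.
#' @export
write_mrl_registry <- function(x, path, delim = ",") {
  validate_mrl_registry(x)
  out <- mutate(x, limit_ug_kg = format_num(.data$limit_ug_kg))
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(x)
}

#' Read a toxicology reference registry
#'
#' One row per pesticide with `adi_mg_kg_bw_day` (acceptable daily intake,
#' required for chronic assessment), `arfd_mg_kg_bw_day` (acute reference
#' dose) and `arfd_status`, one of `established`, `unnecessary` (the
#' evaluating body judged an acute reference dose unnecessary) or
#' `not_established`. An ARfD value must be present exactly when the status
#' is `established`.
#'
#' @param path delimited text file.
#' @return tibble with columns `pesticide`, `adi_mg_kg_bw_day`,
#'   `arfd_mg_kg_bw_day`, `arfd_status`.
#' @export
read_tox_registry <- function(path) {
  raw <- read_delim_chr(path)
  stop_if_missing_cols(raw, c("pesticide", "adi_mg_kg_bw_day",
                              "arfd_mg_kg_bw_day", "arfd_status"),
                       "toxicology registry")
  out <- tibble(
    pesticide = stringr::str_squish(raw$pesticide),
    adi_mg_kg_bw_day = as.numeric(raw$adi_mg_kg_bw_day),
    arfd_mg_kg_bw_day = as.numeric(raw$arfd_mg_kg_bw_day),
    arfd_status = trimws(raw$arfd_status)
  )
  validate_tox_registry(out)
}

validate_tox_registry <- function(x, what = "toxicology registry") {
  if (!all(x$arfd_status %in% ARFD_STATUSES)) {
    abort(sprintf("%s: arfd_status must be one of %s", what,
                  paste(ARFD_STATUSES, collapse = ", ")))
  }
  est <- x$arfd_status == "established"
  if (any(est & is.na(x$arfd_mg_kg_bw_day))) {
    abort(sprintf("%s: established ARfD status requires an ARfD value", what))
  }
  if (any(!est & !is.na(x$arfd_mg_kg_bw_day))) {
    abort(sprintf("%s: ARfD value given for pesticide(s) whose status is not 'established'", what))
  }
  if (any(!is.na(x$adi_mg_kg_bw_day) & x$adi_mg_kg_bw_day <= 0) ||
      any(!is.na(x$arfd_mg_kg_bw_day) & x$arfd_mg_kg_bw_day <= 0)) {
    abort(sprintf("%s: reference doses must be positive when present", what))
  }
  if (anyDuplicated(canon_name(x$pesticide))) {
    abort(sprintf("%s: duplicated pesticide entries", what))
  }
  x
}

#' Write a toxicology reference registry
#' @inheritParams write_mrl_registry
#' @return `x`, invisibly.
#' @export
write_tox_registry <- function(x, path, delim = ",") {
  validate_tox_registry(x)
  out <- mutate(x,
                adi_mg_kg_bw_day = format_num(.data$adi_mg_kg_bw_day),
                arfd_mg_kg_bw_day = format_num(.data$arfd_mg_kg_bw_day))
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(x)
}

#' Read consumer-group parameters
#'
#' Consumer strata (age band by sex) drive the exposure equations through
#' two ratios in kg food per kg body weight per day: `f_over_bw` (chronic
#' daily consumption F divided by body weight) and `lp_over_bw` (large
#' portion LP divided by body weight). The file may either carry the ratios
#' directly (`group`, `f_over_bw`, `lp_over_bw`) or absolute parameters
#' (`group`, `bw_kg`, `f_kg_day`, `lp_kg_day`), which are reduced to ratios
#' on load.
#'
#' @param path delimited text file.
#' @return tibble with columns `group`, `f_over_bw`, `lp_over_bw`.
#' @export
read_consumer_groups <- function(path) {
  raw <- read_delim_chr(path)
  stop_if_missing_cols(raw, "group", "consumer group table")
  if (all(c("f_over_bw", "lp_over_bw") %in% names(raw))) {
    out <- tibble(group = trimws(raw$group),
                  f_over_bw = as.numeric(raw$f_over_bw),
                  lp_over_bw = as.numeric(raw$lp_over_bw))
  } else if (all(c("bw_kg", "f_kg_day", "lp_kg_day") %in% names(raw))) {
    bw <- as.numeric(raw$bw_kg)
    if (any(is.na(bw) | bw <= 0)) abort("body weights must be positive")
    out <- tibble(group = trimws(raw$group),
                  f_over_bw = as.numeric(raw$f_kg_day) / bw,
                  lp_over_bw = as.numeric(raw$lp_kg_day) / bw)
  } else {
    abort(paste("consumer group table needs either (f_over_bw, lp_over_bw)",
                "or (bw_kg, f_kg_day, lp_kg_day) columns"))
  }
  validate_consumer_groups(out)
}

validate_consumer_groups <- function(x, what = "consumer group table") {
  if (any(is.na(x$f_over_bw) | x$f_over_bw <= 0) ||
      any(is.na(x$lp_over_bw) | x$lp_over_bw <= 0)) {
    abort(sprintf("%s: consumption ratios must be positive", what))
  }
  if (anyDuplicated(canon_name(x$group))) {
    abort(sprintf("%s: duplicated group labels", what))
  }
  x
}

#' Write consumer-group parameters
#' @inheritParams write_mrl_registry
#' @return `x`, invisibly.
#' @export
write_consumer_groups <- function(x, path, delim = ",") {
  validate_consumer_groups(x)
  out <- mutate(x, f_over_bw = format_num(.data$f_over_bw),
                lp_over_bw = format_num(.data$lp_over_bw))
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(x)
}

# ---- packaged fixtures (Shanghai fruit survey, 260 samples, 2019-2020) ----

rr_extdata <- function(file) {
  system.file("extdata", file, package = "residuerisk", mustWork = TRUE)
}

#' Packaged occurrence summary from the Shanghai fruit survey
#'
#' Per-(commodity, pesticide) occurrence statistics for the 260-sample
#' survey of five fruit cultivars (strawberry n = 80, watermelon n = 50,
#' melon n = 50, peach n = 40, grape n = 40): minimum, maximum and mean of
#' the detected concentrations (ug/kg) and the number of samples exceeding
#' the Chinese and EU limits (NA where no limit is defined).
#'
#' The survey did not publish per-pesticide detection counts; the
#' `n_detects` column carries package-assumed counts (frozen from
#' [assume_detect_counts()]): 1 for single-value rows, forced equal to the
#' exceedance count where even the minimum detect exceeds the limit (e.g.
#' grape triflumuron, 40), and otherwise the smallest count under which the
#' published mean is attainable given the exceedance quotas.
#'
#' @return tibble with columns `commodity`, `pesticide`, `n_samples`,
#'   `n_detects`, `min_ug_kg`, `max_ug_kg`, `mean_ug_kg`, `cn_exceed`,
#'   `eu_exceed`.
#' @seealso [shanghai_mrl()], [shanghai_tox()], [emulate_occurrence_table()]
#' @export
shanghai_occurrence <- function() {
  readr::read_csv(rr_extdata("shanghai_occurrence.csv"),
                  col_types = "ccidddddd", progress = FALSE) |>
    rename(n_detects = "n_detects_assumed") |>
    mutate(n_detects = as.integer(.data$n_detects),
           n_samples = as.integer(.data$n_samples))
}

#' Packaged MRL registry (Chinese and EU limits for the surveyed pairs)
#'
#' Limits in ug/kg for every (commodity, pesticide) pair of the survey for
#' which a limit exists; pairs with no limit in a jurisdiction simply have
#' no row. Chinese temporary limits carry basis `temporary`; EU entries at
#' the lower limit of analytical determination carry basis
#' `analytical_determination_default`. The spirotetramat rows carry the
#' residue-definition components (spirotetramat; spirotetramat-enol).
#'
#' @return tibble in the [read_mrl_registry()] schema.
#' @export
shanghai_mrl <- function() {
  read_mrl_registry(rr_extdata("shanghai_mrl.csv"))
}

#' Packaged toxicology registry for the 57 detected pesticides
#'
#' ADI values (Chinese national standard) for all 57 detected pesticides,
#' ARfD values (JMPR) for the 25 pesticides with an established acute
#' reference dose, and skip statuses for the remainder (21 `unnecessary`,
#' 11 `not_established`).
#'
#' @return tibble in the [read_tox_registry()] schema.
#' @export
shanghai_tox <- function() {
  read_tox_registry(rr_extdata("tox_reference.csv"))
}

#' Packaged Chinese consumer-group consumption ratios
#'
#' Six strata (2-4, 18-30 and 60-70 year olds, by sex) with chronic
#' (`f_over_bw`) and large-portion (`lp_over_bw`) fruit consumption ratios
#' in kg food per kg body weight per day. The survey's absolute body-weight
#' and consumption table is unpublished; these ratios are back-derived from
#' printed single-reference risk cells (see
#' [calibrate_consumption_ratios()]) and reproduce the published chronic and
#' acute risk tables.
#'
#' @return tibble with columns `group`, `f_over_bw`, `lp_over_bw`.
#' @export
china_consumer_groups <- function() {
  read_consumer_groups(rr_extdata("consumer_groups.csv"))
}

read_reference_pct <- function(file, dose_col) {
  wide <- readr::read_csv(rr_extdata(file), col_types = readr::cols(),
                          progress = FALSE)
  tidyr::pivot_longer(wide, cols = -c("pesticide", dplyr::all_of(dose_col)),
                      names_to = "group", values_to = "pct")
}

#' Published chronic risk table (%ADI) from the Shanghai survey
#'
#' The published chronic hazard quotients: 57 pesticides by six consumer
#' groups, each cell the national estimated daily intake as a percentage of
#' the ADI, printed to four decimals. Used as calibration input (reference
#' cells) and as the verification target for [risk_table()].
#'
#' @return long tibble with columns `pesticide`, `adi_mg_kg_bw_day`,
#'   `group`, `pct_adi`.
#' @export
shanghai_chronic_reference <- function() {
  read_reference_pct("chronic_risk_reference.csv", "adi_mg_kg_bw_day") |>
    rename(pct_adi = "pct")
}

#' Published acute risk table (%ARfD) from the Shanghai survey
#'
#' The published acute hazard quotients: 25 pesticides with an established
#' ARfD by six consumer groups, each cell the estimated short-term intake as
#' a percentage of the ARfD.
#'
#' @return long tibble with columns `pesticide`, `arfd_mg_kg_bw_day`,
#'   `group`, `pct_arfd`.
#' @export
shanghai_acute_reference <- function() {
  read_reference_pct("acute_risk_reference.csv", "arfd_mg_kg_bw_day") |>
    rename(pct_arfd = "pct")
}
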