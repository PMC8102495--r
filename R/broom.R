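# broom-style accessors for fitted/assessment objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an exposure assessment into one row per cell
#'
#' @param x an `exposure_assessment` from [risk_table()].
#' @param type `"chronic"` (default), `"acute"`, or `"both"` (rows stacked
#'   with a `risk_kind` column).
#' @param ... unused.
#' @return a tibble with one row per (pesticide, group) cell; chronic rows
#'   carry `nedi` and `pct_adi`, acute rows `esti` and `pct_arfd`.
#' @method tidy exposure_assessment
#' @export
tidy.exposure_assessment <- function(x, type = c("chronic", "acute", "both"),
                                     ...) {
  type <- match.arg(type)
  chronic <- mutate(x$chronic, risk_kind = "chronic")
  acute <- mutate(x$acute, risk_kind = "acute")
  switch(type,
         chronic = x$chronic,
         acute = x$acute,
         both = bind_rows(chronic, acute))
}

#' One-row summary of an exposure assessment
#'
#' @param x an `exposure_assessment`.
#' @param ... unused.
#' @return one-row tibble: numbers of pesticides and groups assessed, the
#'   worst chronic and acute hazard quotients with the cells attaining
#'   them, and whether every quotient sits below the 100% acceptability
#'   line.
#' @method glance exposure_assessment
#' @export
glance.exposure_assessment <- function(x, ...) {
  worst <- function(df, col) {
    if (!nrow(df)) {
      return(list(pesticide = NA_character_, group = NA_character_,
                  value = NA_real_))
    }
    i <- which.max(df[[col]])
    list(pesticide = df$pesticide[i], group = df$group[i],
         value = df[[col]][i])
  }
  wc <- worst(x$chronic, "pct_adi")
  wa <- worst(x$acute, "pct_arfd")
  tibble(
    n_pesticides_chronic = dplyr::n_distinct(x$chronic$pesticide),
    n_pesticides_acute = dplyr::n_distinct(x$acute$pesticide),
    n_groups = nrow(x$groups),
    n_skipped_acute = nrow(x$skipped_acute),
    n_unassessed = nrow(x$unassessed),
    max_pct_adi = wc$value, max_pct_adi_pesticide = wc$pesticide,
    max_pct_adi_group = wc$group,
    max_pct_arfd = wa$value, max_pct_arfd_pesticide = wa$pesticide,
    max_pct_arfd_group = wa$group,
    all_acceptable = all(c(x$chronic$pct_adi, x$acute$pct_arfd) < 100)
  )
}
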