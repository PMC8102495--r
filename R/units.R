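#' Convert residue concentrations between mass-fraction units
#'
#' Residue levels are conventionally reported in micrograms of analyte per
#' kilogram of commodity, while toxicological reference doses (ADI, ARfD)
#' are in milligrams per kilogram body weight per day. Exposure arithmetic
#' therefore needs an exact factor-of-1000 rescaling at the boundary between
#' the two; this helper performs it without floating drift beyond scaling.
#'
#' @param value numeric vector of concentrations (mass fractions).
#' @param from,to unit strings; `"ug/kg"` (accepted aliases `"µg/kg"`,
#'   `"ppb"`) or `"mg/kg"` (alias `"ppm"`).
#' @return numeric vector of the same length as `value`, expressed in `to`.
#' @export
#' @examples
#' convert_concentration(12.9, "ug/kg", "mg/kg")   # 0.0129
#' convert_concentration(6260.5, "ug/kg", "mg/kg") # 6.2605
convert_concentration <- function(value, from, to) {
  if (!is.numeric(value)) abort("`value` must be numeric")
  value * (unit_factor(from) / unit_factor(to))
}

# factor relative to ug/kg
unit_factor <- function(unit) {
  if (length(unit) != 1L || is.na(unit)) abort("unit must be a single string")
  u <- tolower(trimws(unit))
  u <- gsub("µ|μ", "u", u)
  switch(u,
    "ug/kg" = , "ppb" = 1,
    "mg/kg" = , "ppm" = 1000,
    abort(sprintf("unknown concentration unit: '%s'", unit))
  )
}

ug_to_mg <- function(x) x / 1000
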