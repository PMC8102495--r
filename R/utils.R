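# shared internal helpers

#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# canonical matching key for pesticide/commodity names: case-insensitive,
# whitespace-trimmed (registry lookups must not depend on capitalisation)
canon_name <- function(x) {
  stringr::str_squish(tolower(as.character(x)))
}

#' Round half away from zero
#'
#' Display rounding used throughout report rendering. Unlike [base::round()]
#' (banker's rounding), ties go away from zero, so `0.25` at one decimal is
#' `0.3`, matching how monitoring reports conventionally print rates.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_away(93.75, 1)
#' round_half_away(-0.25, 1)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
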