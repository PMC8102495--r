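# toy data builders and independent brute-force oracles used across tests

make_samples <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(sample_id = r[[1]], commodity = r[[2]], pesticide = r[[3]],
                   concentration_ug_kg = if (is.na(r[[4]])) NA_real_ else as.numeric(r[[4]]),
                   detected = !is.na(r[[4]]))
  })
}

toy_mrl <- function() {
  tibble::tribble(
    ~jurisdiction, ~commodity, ~pesticide, ~limit_ug_kg, ~basis, ~sum_components,
    "CN", "apple", "captan", 100, "standard", NA,
    "EU", "apple", "captan", 50, "standard", NA,
    "CN", "apple", "folpet", 200, "temporary", NA,
    "EU", "apple", "spirotetramat", 80, "standard",
    "spirotetramat;spirotetramat-enol"
  )
}

# brute-force compliance oracle: plain loops, no joins, no vectorisation
oracle_sample_compliance <- function(samples, registry, jurisdiction) {
  ids <- unique(samples$sample_id)
  out <- logical(length(ids))
  for (i in seq_along(ids)) {
    rows <- samples[samples$sample_id == ids[i] & samples$detected, ]
    ok <- TRUE
    for (j in seq_len(nrow(rows))) {
      lim <- registry[registry$jurisdiction == jurisdiction &
                        tolower(registry$commodity) == tolower(rows$commodity[j]) &
                        tolower(registry$pesticide) == tolower(rows$pesticide[j]), ]
      if (nrow(lim) == 1 && rows$concentration_ug_kg[j] > lim$limit_ug_kg) {
        ok <- FALSE
      }
    }
    out[i] <- ok
  }
  stats::setNames(out, ids)
}

oracle_exceed_count <- function(samples, registry, jurisdiction,
                                commodity, pesticide) {
  lim <- registry[registry$jurisdiction == jurisdiction &
                    tolower(registry$commodity) == tolower(commodity) &
                    tolower(registry$pesticide) == tolower(pesticide), ]
  if (nrow(lim) != 1) return(NA_integer_)
  rows <- samples[samples$detected &
                    tolower(samples$commodity) == tolower(commodity) &
                    tolower(samples$pesticide) == tolower(pesticide), ]
  n <- 0L
  for (j in seq_len(nrow(rows))) {
    if (rows$concentration_ug_kg[j] > lim$limit_ug_kg) n <- n + 1L
  }
  n
}

# random single-pesticide toy dataset for property sweeps
random_toy <- function(n_samples, limit, seed) {
  set.seed(seed)
  det <- stats::runif(n_samples) < 0.8
  conc <- ifelse(det, stats::rlnorm(n_samples, log(limit), 1), NA_real_)
  tibble::tibble(sample_id = sprintf("s%03d", seq_len(n_samples)),
                 commodity = "apple", pesticide = "captan",
                 concentration_ug_kg = conc, detected = det)
}

cells_within_tol <- function(est, ref, abs_tol = 0.003, rel_tol = 0.002) {
  abs(est - ref) <= pmax(abs_tol, rel_tol * abs(ref))
}
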