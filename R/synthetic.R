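# Synthetic residue datasets with known ground truth.
#
# Two generators: a free-form one (per-pair detection probabilities and
# censored log-normal levels) and an occurrence emulator that manufactures a
# sample-level dataset reproducing a published occurrence summary exactly in
# its counts (n_samples, n_detects, per-jurisdiction exceedances) and
# approximately in its mean of detects.

#' Specify a synthetic residue study
#'
#' @param levels tibble with one row per (commodity, pesticide):
#'   `detection_probability` in \[0, 1\], log-normal `meanlog` and `sdlog`
#'   (> 0) on the ug/kg scale, and `censor_limit_ug_kg` (the LOD below
#'   which a draw is redrawn; detects are always >= LOD, as reported
#'   concentrations are).
#' @param n_samples named integer vector or tibble (`commodity`,
#'   `n_samples`) giving the number of samples per commodity.
#' @return validated object of class `synthetic_spec`.
#' @seealso [generate_samples()]
#' @export
synthetic_spec <- function(levels, n_samples) {
  stop_if_missing_cols(levels, c("commodity", "pesticide",
                                 "detection_probability", "meanlog", "sdlog",
                                 "censor_limit_ug_kg"), "synthetic levels")
  if (is.data.frame(n_samples)) {
    stop_if_missing_cols(n_samples, c("commodity", "n_samples"), "n_samples")
    n_samples <- stats::setNames(as.integer(n_samples$n_samples),
                                 n_samples$commodity)
  }
  p <- levels$detection_probability
  if (any(is.na(p) | p < 0 | p > 1)) {
    abort("detection probabilities must lie in [0, 1]")
  }
  if (any(is.na(levels$sdlog) | levels$sdlog <= 0)) {
    abort("sdlog must be positive")
  }
  if (any(is.na(levels$censor_limit_ug_kg) | levels$censor_limit_ug_kg < 0)) {
    abort("censor limits must be non-negative")
  }
  miss <- setdiff(canon_name(levels$commodity), canon_name(names(n_samples)))
  if (length(miss)) {
    abort(sprintf("no sample count for commodity: %s",
                  paste(miss, collapse = ", ")))
  }
  if (any(is.na(n_samples) | n_samples <= 0)) {
    abort("sample counts must be positive")
  }
  structure(list(levels = as_tibble(levels), n_samples = n_samples),
            class = "synthetic_spec")
}

#' Generate a sample-level residue dataset
#'
#' For every sample and (commodity, pesticide) pair, detection is a
#' Bernoulli draw; detected concentrations are log-normal, redrawn until at
#' or above the censor limit (at most 1000 redraws per value). Identical
#' seed and spec give an identical dataset; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return sample-level residue tibble in the [read_residue_samples()]
#'   schema, including non-detect rows (`detected = FALSE`).
#' @export
generate_samples <- function(spec, seed = 1) {
  if (!inherits(spec, "synthetic_spec")) abort("spec must be a synthetic_spec")
  with_seed(seed, {
    purrr::map_dfr(names(spec$n_samples), function(com) {
      n <- spec$n_samples[[com]]
      ids <- sprintf("%s-%03d", com, seq_len(n))
      lv <- spec$levels[canon_name(spec$levels$commodity) == canon_name(com), ]
      purrr::pmap_dfr(lv, function(commodity, pesticide, detection_probability,
                                   meanlog, sdlog, censor_limit_ug_kg, ...) {
        det <- stats::runif(n) < detection_probability
        conc <- rep(NA_real_, n)
        if (any(det)) {
          conc[det] <- rlnorm_censored(sum(det), meanlog, sdlog,
                                       censor_limit_ug_kg)
        }
        tibble(sample_id = ids, commodity = com, pesticide = pesticide,
               concentration_ug_kg = conc, detected = det)
      })
    })
  })
}

rlnorm_censored <- function(n, meanlog, sdlog, censor, max_redraws = 1000) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (i in seq_len(max_redraws)) {
    low <- x < censor
    if (!any(low)) return(x)
    x[low] <- stats::rlnorm(sum(low), meanlog, sdlog)
  }
  abort("censor limit not reachable within 1000 redraws; check the level distribution")
}

# ---- occurrence emulation -------------------------------------------------

# sort thresholds, merge duplicates, drop vacuous constraints (count 0 and
# max below the limit), and check structural consistency
norm_constraints <- function(th, cnt, minv, maxv) {
  keep <- !is.na(th)
  th <- th[keep]; cnt <- cnt[keep]
  if (any(is.na(cnt))) abort("exceedance count missing where a limit is defined")
  o <- order(th); th <- th[o]; cnt <- cnt[o]
  if (anyDuplicated(th)) {
    agg <- tapply(cnt, th, unique, simplify = FALSE)
    if (any(lengths(agg) > 1)) abort("conflicting exceedance counts for one limit")
    th <- as.numeric(names(agg)); cnt <- unlist(agg)
    o <- order(th); th <- th[o]; cnt <- cnt[o]
  }
  keep <- !(cnt == 0 & maxv <= th)
  th <- th[keep]; cnt <- cnt[keep]
  if (length(th)) {
    if (any(diff(cnt) > 0)) abort("exceedance counts must not increase with the limit")
    if (any(cnt > 0 & maxv <= th)) {
      abort("positive exceedance count but the maximum detect is at or below the limit")
    }
    if (any(cnt == 0 & maxv > th)) {
      abort("maximum detect exceeds a limit with a zero exceedance count")
    }
  }
  list(th = th, cnt = as.integer(cnt))
}

# per-slot value bounds for d detects honouring all strictly-above counts;
# slot 1 is pinned at min, the last slot at max; NULL when d is infeasible
slot_bounds <- function(d, minv, maxv, th, cnt, eps = 0.01) {
  m <- length(th)
  occ <- if (m == 0) d else c(d - cnt[1],
                              if (m > 1) cnt[-m] - cnt[-1] else NULL, cnt[m])
  if (any(occ < 0)) return(NULL)
  seg_lo <- c(minv, pmax(minv, th + eps))
  seg_hi <- c(if (m >= 1) pmin(th[1], maxv) else maxv,
              if (m >= 1) c(if (m > 1) pmin(th[-1], maxv) else NULL, maxv))
  if (any(occ > 0 & seg_lo > seg_hi)) return(NULL)
  nonempty <- which(occ > 0)
  j0 <- nonempty[1]; j1 <- nonempty[length(nonempty)]
  if (minv < seg_lo[j0] - 1e-9 || minv > seg_hi[j0] + 1e-9) return(NULL)
  if (maxv < seg_lo[j1] - 1e-9 || maxv > seg_hi[j1] + 1e-9) return(NULL)
  lo <- rep(seg_lo, occ); hi <- rep(seg_hi, occ)
  lo[1] <- hi[1] <- minv
  lo[d] <- hi[d] <- maxv
  list(lo = lo, hi = hi)
}

# smallest detect count under which the reported mean is attainable given
# the exceedance quotas (exactly if possible, else within 5% relative)
choose_detect_count <- function(minv, maxv, meanv, th, cnt, n_samples,
                                eps = 0.01) {
  if (minv == maxv) return(1L)
  m <- length(th)
  forced <- m > 0 && minv > th[1] # every detect exceeds the lowest limit
  d_range <- if (forced) cnt[1] else seq(max(2L, if (m) cnt[1] + 1L else 2L),
                                         n_samples)
  best_d <- NA_integer_; best_dev <- Inf
  for (d in d_range) {
    b <- slot_bounds(d, minv, maxv, th, cnt, eps)
    if (is.null(b)) next
    s <- meanv * d
    lo <- sum(b$lo); hi <- sum(b$hi)
    if (s >= lo - 1e-9 && s <= hi + 1e-9) return(as.integer(d))
    dev <- if (s < lo) (lo - s) / s else (s - hi) / s
    if (dev < best_dev) { best_dev <- dev; best_d <- d }
  }
  if (!is.na(best_d) && best_dev <= 0.05) return(as.integer(best_d))
  abort(sprintf("no detect count in [2, %d] can reproduce mean %.4g under the exceedance quotas",
                n_samples, meanv))
}

# nudge values toward an exact target sum, each within its [lo, hi] bounds
adjust_to_sum <- function(x, lo, hi, target, max_iter = 200) {
  for (i in seq_len(max_iter)) {
    diff <- target - sum(x)
    if (abs(diff) <= 1e-9) break
    adj <- if (diff > 0) which(x < hi - 1e-12) else which(x > lo + 1e-12)
    if (!length(adj)) break
    x[adj] <- pmin(hi[adj], pmax(lo[adj], x[adj] + diff / length(adj)))
  }
  x
}

#' Assume detection counts for an occurrence summary that lacks them
#'
#' Monitoring surveys often publish the detects' min/max/mean and exceedance
#' counts without the underlying detection counts. This fills in a
#' deterministic, minimal assumption: 1 for single-value rows (min = max);
#' forced equal to the exceedance count when even the minimum detect
#' exceeds the lowest limit; otherwise the smallest count under which the
#' published mean is attainable within the exceedance quotas.
#'
#' @param occurrence occurrence tibble with `commodity`, `pesticide`,
#'   `n_samples`, `min_ug_kg`, `max_ug_kg`, `mean_ug_kg` and (optionally)
#'   `cn_exceed` / `eu_exceed` columns.
#' @param mrl MRL registry supplying the limits the exceedance counts refer
#'   to; `NULL` for unconstrained rows.
#' @return `occurrence` with an `n_detects` column (existing values are
#'   replaced).
#' @export
assume_detect_counts <- function(occurrence, mrl = NULL) {
  stop_if_missing_cols(occurrence, c("commodity", "pesticide", "n_samples",
                                     "min_ug_kg", "max_ug_kg", "mean_ug_kg"),
                       "occurrence summary")
  occurrence$n_detects <- purrr::pmap_int(
    occurrence[c("commodity", "pesticide", "n_samples", "min_ug_kg",
                 "max_ug_kg", "mean_ug_kg")],
    function(commodity, pesticide, n_samples, min_ug_kg, max_ug_kg,
             mean_ug_kg) {
      cons <- occurrence_constraints(occurrence, commodity, pesticide, mrl)
      choose_detect_count(min_ug_kg, max_ug_kg, mean_ug_kg, cons$th,
                          cons$cnt, n_samples)
    })
  occurrence
}

occurrence_constraints <- function(occurrence, commodity, pesticide, mrl) {
  if (is.null(mrl)) return(list(th = numeric(), cnt = integer()))
  row <- occurrence[canon_name(occurrence$commodity) == canon_name(commodity) &
                    canon_name(occurrence$pesticide) == canon_name(pesticide), ]
  th <- numeric(); cnt <- numeric()
  for (j in unique(mrl$jurisdiction)) {
    lim <- applicable_limit(mrl, pesticide, commodity, j)
    if (!nrow(lim)) next
    col <- paste0(tolower(j), "_exceed")
    if (!col %in% names(occurrence)) next # unconstrained emulation
    th <- c(th, lim$limit_ug_kg)
    cnt <- c(cnt, row[[col]][1])
  }
  norm_constraints(th, cnt, row$min_ug_kg[1], row$max_ug_kg[1])
}

#' Emulate a published occurrence summary at sample level
#'
#' Manufactures a sample-level dataset whose [summarize_occurrence()] output
#' matches the input exactly in `n_samples` and `n_detects` per (commodity,
#' pesticide) and whose per-jurisdiction exceedance counts match exactly
#' (the required number of detects is placed strictly above each limit).
#' The mean of detects is reproduced as closely as the count constraints
#' allow, by nudging interior values within their admissible band toward
#' the target sum with the endpoints pinned at the published min and max;
#' the result deviates from the published mean by more than 5% relative
#' only if no placement can do better, which is an error.
#'
#' @param occurrence occurrence tibble ([shanghai_occurrence()] schema); if
#'   `n_detects` is absent it is filled by [assume_detect_counts()].
#' @param mrl MRL registry giving the limits behind the `cn_exceed` /
#'   `eu_exceed` columns; `NULL` disables exceedance constraints.
#' @param seed integer seed (value placement and sample assignment).
#' @return sample-level residue tibble including non-detect rows.
#' @export
#' @examples
#' occ <- shanghai_occurrence()
#' samples <- emulate_occurrence_table(occ, shanghai_mrl(), seed = 1)
#' all.equal(summarize_occurrence(samples)$n_detects, occ$n_detects)
emulate_occurrence_table <- function(occurrence, mrl = NULL, seed = 1) {
  if (!"n_detects" %in% names(occurrence)) {
    occurrence <- assume_detect_counts(occurrence, mrl)
  }
  stop_if_missing_cols(occurrence, c("commodity", "pesticide", "n_samples",
                                     "n_detects", "min_ug_kg", "max_ug_kg",
                                     "mean_ug_kg"), "occurrence summary")
  n_com <- occurrence |> distinct(.data$commodity, .data$n_samples)
  if (anyDuplicated(n_com$commodity)) {
    abort("inconsistent n_samples within a commodity")
  }
  if (any(occurrence$n_detects > occurrence$n_samples) ||
      any(occurrence$n_detects < 1L)) {
    abort("n_detects must lie in [1, n_samples]")
  }
  with_seed(seed, {
    purrr::pmap_dfr(n_com, function(commodity, n_samples) {
      ids <- sprintf("%s-%03d", commodity, seq_len(n_samples))
      rows <- occurrence[canon_name(occurrence$commodity) ==
                           canon_name(commodity), ]
      purrr::pmap_dfr(
        rows[c("pesticide", "n_detects", "min_ug_kg", "max_ug_kg",
               "mean_ug_kg")],
        function(pesticide, n_detects, min_ug_kg, max_ug_kg, mean_ug_kg) {
          cons <- occurrence_constraints(occurrence, commodity, pesticide, mrl)
          vals <- draw_detect_values(n_detects, min_ug_kg, max_ug_kg,
                                     mean_ug_kg, cons$th, cons$cnt)
          idx <- sample.int(n_samples, n_detects)
          conc <- rep(NA_real_, n_samples)
          # decouple value order from sample order (sample() would treat a
          # single value as a range, so guard the length-1 case)
          conc[idx] <- if (n_detects > 1L) sample(vals) else vals
          tibble(sample_id = ids, commodity = commodity,
                 pesticide = pesticide, concentration_ug_kg = conc,
                 detected = !is.na(conc))
        })
    })
  })
}

draw_detect_values <- function(d, minv, maxv, meanv, th, cnt, eps = 0.01) {
  if (d == 1L) {
    if (minv != maxv) abort("a single detect requires min = max")
    return(meanv)
  }
  b <- slot_bounds(d, minv, maxv, th, cnt, eps)
  if (is.null(b)) {
    abort(sprintf("infeasible occurrence row: %d detects cannot honour the exceedance quotas", d))
  }
  target <- meanv * d
  lo <- sum(b$lo); hi <- sum(b$hi)
  clamped <- min(max(target, lo), hi)
  if (abs(clamped - target) / target > 0.05) {
    abort("published mean not attainable within 5% under the exceedance quotas")
  }
  x <- stats::runif(d, b$lo, b$hi)
  adjust_to_sum(x, b$lo, b$hi, clamped)
}

#' Simulate a spiked-recovery experiment
#'
#' Measured concentrations are drawn as
#' Normal(spike x recovery/100, sd = cv/100 x that mean), clamped at zero,
#' for each spike level and replicate — the usual two-level, six-replicate
#' accuracy/precision design.
#'
#' @param true_recovery true mean recovery, percent.
#' @param cv between-replicate coefficient of variation, percent (>= 0).
#' @param spike_levels spiked concentrations, ug/kg.
#' @param n_replicates replicates per level (>= 2).
#' @param seed integer seed.
#' @return tibble with columns `spike_ug_kg`, `replicate`,
#'   `measured_ug_kg`.
#' @export
#' @examples
#' x <- generate_recovery_experiment(85, cv = 10, seed = 42)
#' dplyr::group_by(x, spike_ug_kg) |>
#'   dplyr::group_modify(~ recovery_stats(.x$measured_ug_kg, .y$spike_ug_kg))
generate_recovery_experiment <- function(true_recovery, cv,
                                         spike_levels = c(10, 100),
                                         n_replicates = 6, seed = 1) {
  if (is.na(cv) || cv < 0) abort("cv must be non-negative")
  if (n_replicates < 2) abort("at least two replicates are required")
  with_seed(seed, {
    purrr::map_dfr(spike_levels, function(sp) {
      mu <- sp * true_recovery / 100
      tibble(spike_ug_kg = sp, replicate = seq_len(n_replicates),
             measured_ug_kg = pmax(0, stats::rnorm(n_replicates, mu,
                                                   cv / 100 * mu)))
    })
  })
}
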