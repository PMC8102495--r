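# synthetic generators: censored log-normal sampling, occurrence emulation,
# recovery experiments

toy_spec <- function(p = 0.5, meanlog = 3, sdlog = 0.5, censor = 0, n = 40) {
  synthetic_spec(
    tibble::tibble(commodity = "apple", pesticide = "captan",
                   detection_probability = p, meanlog = meanlog,
                   sdlog = sdlog, censor_limit_ug_kg = censor),
    c(apple = n))
}

test_that("generation is deterministic under a fixed seed and leaves the RNG alone", {
  a <- generate_samples(toy_spec(), seed = 7)
  b <- generate_samples(toy_spec(), seed = 7)
  expect_identical(a, b)
  c <- generate_samples(toy_spec(), seed = 8)
  expect_false(identical(a, c))

  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(generate_samples(toy_spec(), seed = 1))
  expect_identical(stats::runif(1), before)
})

test_that("detection probability extremes behave and are recovered statistically", {
  none <- generate_samples(toy_spec(p = 0), seed = 1)
  expect_equal(sum(none$detected), 0L)
  all_ <- generate_samples(toy_spec(p = 1), seed = 1)
  expect_equal(detection_rate(all_)$detection_rate_pct, 100)

  # estimated detection probability within a 99% binomial interval
  x <- generate_samples(toy_spec(p = 0.3, n = 500), seed = 11)
  k <- sum(x$detected)
  expect_gte(k, qbinom(0.005, 500, 0.3))
  expect_lte(k, qbinom(0.995, 500, 0.3))
})

test_that("detect levels converge to the log-normal mean and honour censoring", {
  x <- generate_samples(toy_spec(p = 1, n = 10000), seed = 3)
  m <- mean(x$concentration_ug_kg)
  mu <- exp(3 + 0.5^2 / 2) # 22.76
  se <- sqrt((exp(0.25) - 1) * exp(6 + 0.25) / 10000)
  expect_lt(abs(m - mu), 3 * se)

  cens <- generate_samples(toy_spec(p = 1, censor = 20, n = 2000), seed = 4)
  expect_true(all(cens$concentration_ug_kg >= 20))
  # unreachable censor limit errors out instead of spinning forever
  expect_error(generate_samples(toy_spec(p = 1, censor = 1e6), seed = 1),
               "redraws")
})

test_that("invalid specs are rejected before any sampling", {
  lv <- tibble::tibble(commodity = "apple", pesticide = "captan",
                       detection_probability = 1.4, meanlog = 3, sdlog = 0.5,
                       censor_limit_ug_kg = 0)
  expect_error(synthetic_spec(lv, c(apple = 10)), "\\[0, 1\\]")
  lv$detection_probability <- 0.5
  lv$sdlog <- 0
  expect_error(synthetic_spec(lv, c(apple = 10)), "sdlog")
  lv$sdlog <- 1
  expect_error(synthetic_spec(lv, c(pear = 10)), "no sample count")
})

test_that("occurrence emulation reproduces counts exactly and means closely", {
  occ <- shanghai_occurrence()
  mrl <- shanghai_mrl()
  samples <- emulate_occurrence_table(occ, mrl, seed = 5)
  s <- summarize_occurrence(samples)
  j <- dplyr::inner_join(occ, s, by = c("commodity", "pesticide"),
                         suffix = c("", ".sim"))
  expect_equal(nrow(j), nrow(occ))
  expect_equal(j$n_samples.sim, j$n_samples)
  expect_equal(j$n_detects.sim, j$n_detects)
  expect_equal(j$min_ug_kg.sim, j$min_ug_kg)
  expect_equal(j$max_ug_kg.sim, j$max_ug_kg)
  expect_true(all(abs(j$mean_ug_kg.sim / j$mean_ug_kg - 1) <= 0.05))

  # exceedance placement: strawberry fluopyram row
  flu <- dplyr::filter(samples, commodity == "strawberry",
                       pesticide == "Fluopyram", detected)
  expect_true(all(flu$concentration_ug_kg >= 3.3 &
                    flu$concentration_ug_kg <= 6260.5))
  expect_equal(sum(flu$concentration_ug_kg > 400), 13L)
  expect_equal(sum(flu$concentration_ug_kg > 2000), 4L)

  # grape triflumuron: all 40 samples detected and above the EU default
  tri <- dplyr::filter(samples, commodity == "grape",
                       pesticide == "Triflumuron", detected)
  expect_equal(nrow(tri), 40L)
  expect_true(all(tri$concentration_ug_kg > 10))
})

test_that("infeasible occurrence rows are rejected", {
  occ <- tibble::tibble(commodity = "apple", pesticide = "captan",
                        n_samples = 10L, n_detects = 2L, min_ug_kg = 5,
                        max_ug_kg = 150, mean_ug_kg = 80,
                        cn_exceed = 3, eu_exceed = NA)
  mrl <- dplyr::filter(toy_mrl(), jurisdiction == "CN")
  expect_error(emulate_occurrence_table(occ, mrl, seed = 1), "infeasible")
})

test_that("assumed detect counts are minimal and honour forced rows", {
  occ <- shanghai_occurrence() |> dplyr::select(-n_detects)
  filled <- assume_detect_counts(occ, shanghai_mrl())
  expect_equal(filled$n_detects, shanghai_occurrence()$n_detects)
  # single-value rows get one detect; the all-exceeding grape row gets 40
  expect_equal(filled$n_detects[filled$commodity == "strawberry" &
                                  filled$pesticide == "Pyriproxyfen"], 1L)
  expect_equal(filled$n_detects[filled$commodity == "grape" &
                                  filled$pesticide == "Triflumuron"], 40L)
})

test_that("recovery experiments recover their true parameters", {
  exact <- generate_recovery_experiment(85, cv = 0, seed = 1)
  by_level <- dplyr::group_by(exact, spike_ug_kg) |>
    dplyr::group_modify(~recovery_stats(.x$measured_ug_kg, .y$spike_ug_kg)) |>
    dplyr::ungroup()
  expect_equal(nrow(by_level), 2L) # two spike levels by default
  expect_equal(by_level$mean_recovery_pct, c(85, 85))
  expect_equal(by_level$rsd_pct, c(0, 0))

  big <- generate_recovery_experiment(85, cv = 10, spike_levels = 10,
                                      n_replicates = 1000, seed = 9)
  est <- recovery_stats(big$measured_ug_kg, 10)
  expect_lt(abs(est$mean_recovery_pct - 85), 1)
  expect_lt(abs(est$rsd_pct - 10), 1.5)
  expect_error(generate_recovery_experiment(85, cv = -1), "non-negative")
})
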