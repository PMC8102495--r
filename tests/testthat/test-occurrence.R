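# occurrence statistics: mean-of-detects summaries, detection rates,
# multi-residue distributions

test_that("occurrence summaries use detects only and omit never-detected pairs", {
  samples <- make_samples(
    list("s1", "apple", "captan", 10), list("s2", "apple", "captan", 20),
    list("s3", "apple", "captan", 30), list("s4", "apple", "captan", NA),
    list("s5", "apple", "captan", NA), list("s1", "apple", "folpet", NA))
  occ <- summarize_occurrence(samples)
  expect_equal(nrow(occ), 1L) # folpet never detected -> no row
  expect_equal(occ$n_samples, 5L)
  expect_equal(occ$n_detects, 3L)
  expect_equal(c(occ$min_ug_kg, occ$mean_ug_kg, occ$max_ug_kg), c(10, 20, 30))

  single <- summarize_occurrence(
    make_samples(list("s1", "apple", "captan", 7.7)))
  expect_equal(c(single$min_ug_kg, single$mean_ug_kg, single$max_ug_kg),
               c(7.7, 7.7, 7.7))
})

test_that("mean-of-detects is permutation invariant and bounded by min/max", {
  set.seed(11)
  for (i in 1:20) {
    vals <- stats::rlnorm(sample(2:12, 1), 3, 1)
    ids <- sprintf("s%02d", seq_along(vals))
    s1 <- do.call(make_samples,
                  purrr::map2(ids, vals, ~list(.x, "apple", "captan", .y)))
    s2 <- s1[sample(nrow(s1)), ]
    o1 <- summarize_occurrence(s1)
    o2 <- summarize_occurrence(s2)
    expect_equal(o1$mean_ug_kg, o2$mean_ug_kg)
    expect_true(o1$min_ug_kg <= o1$mean_ug_kg &&
                  o1$mean_ug_kg <= o1$max_ug_kg)
  }
})

test_that("detection rate counts samples with at least one detect", {
  all_hit <- purrr::map_dfr(1:40, function(i) {
    make_samples(list(sprintf("g%02d", i), "grape", "triflumuron", 20))
  })
  expect_equal(detection_rate(all_hit)$detection_rate_pct, 100)

  none <- make_samples(list("s1", "apple", "captan", NA),
                       list("s2", "apple", "captan", NA))
  expect_equal(detection_rate(none)$detection_rate_pct, 0)

  mixed <- purrr::map_dfr(1:50, function(i) {
    make_samples(list(sprintf("w%02d", i), "watermelon", "acetamiprid",
                      if (i <= 41) 10 else NA))
  })
  expect_equal(detection_rate(mixed, "watermelon")$detection_rate_pct, 82)
  expect_error(detection_rate(mixed, "apple"), "no samples")
})

test_that("multi-residue distribution matches a per-sample brute-force tally", {
  set.seed(7)
  pests <- paste0("p", 1:6)
  samples <- purrr::map_dfr(1:60, function(i) {
    det <- stats::runif(6) < 0.4
    tibble::tibble(sample_id = sprintf("s%02d", i), commodity = "apple",
                   pesticide = pests,
                   concentration_ug_kg = ifelse(det, 10, NA), detected = det)
  })
  dist <- multi_residue_distribution(samples)
  # oracle: count detects per sample with a plain loop
  tally <- integer(0)
  for (id in unique(samples$sample_id)) {
    k <- sum(samples$detected[samples$sample_id == id])
    tally <- c(tally, k)
  }
  for (i in seq_len(nrow(dist))) {
    expect_equal(dist$n[i], sum(tally == dist$k[i]))
  }
  # conservation and the detection-rate consistency identity
  expect_equal(sum(dist$n), 60L)
  k0 <- sum(dist$n[dist$k == 0])
  expect_equal(detection_rate(samples)$detection_rate_pct,
               100 - 100 * k0 / 60)
  expect_equal(prop_with_at_least(dist, 2)$pct_at_least_k,
               100 * sum(tally >= 2) / 60)
})

test_that("degenerate multi-residue inputs tally correctly", {
  none <- make_samples(list("s1", "apple", "captan", NA),
                       list("s2", "apple", "captan", NA))
  d <- multi_residue_distribution(none)
  expect_equal(d$k, 0L)
  expect_equal(d$n, 2L)

  one <- make_samples(list("s1", "apple", "a", 1), list("s1", "apple", "b", 2),
                      list("s1", "apple", "c", 3))
  d <- multi_residue_distribution(one)
  expect_equal(d$k, 3L)
  expect_equal(d$n, 1L)
})
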