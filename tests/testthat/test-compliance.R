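# MRL compliance: limit lookup, strict-inequality verdicts, sum
# definitions, rates, and oracle/monotonicity properties

test_that("applicable limits are returned regardless of basis, none for dashes", {
  mrl <- shanghai_mrl()
  tri <- applicable_limit(mrl, "Triflumuron", "grape", "EU")
  expect_equal(tri$limit_ug_kg, 10)
  expect_equal(tri$basis, "analytical_determination_default")
  sul <- applicable_limit(mrl, "Sulfoxaflor", "strawberry", "CN")
  expect_equal(sul$limit_ug_kg, 500)
  expect_equal(sul$basis, "temporary")
  expect_equal(nrow(applicable_limit(mrl, "dinotefuran", "watermelon", "EU")),
               0L)
})

test_that("exceedance is strict: above fails, at the limit is compliant", {
  mrl <- toy_mrl()
  samples <- make_samples(list("s1", "apple", "captan", 100),
                          list("s2", "apple", "captan", 100.01),
                          list("s3", "apple", "nicotine", 5))
  v <- assess_measurements(samples, mrl, "CN")
  expect_equal(v$status[match(c("s1", "s2", "s3"), v$sample_id)],
               c("compliant", "exceeds", "not_assessable"))
})

test_that("residue-definition components are summed within a sample", {
  mrl <- toy_mrl() # EU spirotetramat limit 80, sum with the enol
  samples <- make_samples(list("s1", "apple", "spirotetramat", 50),
                          list("s1", "apple", "spirotetramat-enol", 40),
                          list("s2", "apple", "spirotetramat", 50))
  v <- assess_measurements(samples, mrl, "EU")
  expect_equal(nrow(v), 2L) # folded under the parent name
  expect_setequal(v$pesticide, "spirotetramat")
  expect_equal(v$status[v$sample_id == "s1"], "exceeds") # 90 > 80
  expect_equal(v$status[v$sample_id == "s2"], "compliant")
})

test_that("unregulated residues never count against a sample", {
  mrl <- toy_mrl()
  samples <- make_samples(list("s1", "apple", "captan", 200),
                          list("s1", "apple", "folpet", 10),
                          list("s2", "apple", "nicotine", 9000),
                          list("s3", "apple", "captan", NA))
  sc <- sample_compliance(samples, mrl, "CN")
  expect_equal(sc$compliant[match(c("s1", "s2", "s3"), sc$sample_id)],
               c(FALSE, TRUE, TRUE))
  cr <- compliance_rate(samples, mrl, "CN")
  expect_equal(cr$compliance_pct, 100 * 2 / 3)
})

test_that("verdicts and rates agree with a brute-force loop oracle", {
  mrl <- toy_mrl()
  n_checked <- 0L
  for (seed in 1:25) {
    toy <- random_toy(n_samples = 40, limit = 100, seed = seed)
    got <- sample_compliance(toy, mrl, "CN")
    want <- oracle_sample_compliance(toy, mrl, "CN")
    expect_equal(stats::setNames(got$compliant, got$sample_id),
                 want[got$sample_id])
    ex <- exceedance_table(toy, mrl, "CN")
    expect_equal(ex$n_exceed[1],
                 oracle_exceed_count(toy, mrl, "CN", "apple", "captan"))
    expect_equal(compliance_rate(toy, mrl, "CN")$compliance_pct,
                 100 * mean(want))
    n_checked <- n_checked + nrow(toy)
  }
  expect_gte(n_checked, 1000L)
})

test_that("raising limits or lowering concentrations never adds exceedances", {
  base <- random_toy(n_samples = 60, limit = 100, seed = 99)
  mrl <- toy_mrl()
  count <- function(samples, registry) {
    exceedance_table(samples, registry, "CN")$n_exceed[1]
  }
  n0 <- count(base, mrl)
  for (f in c(1.5, 3, 10)) {
    up <- dplyr::mutate(mrl, limit_ug_kg = limit_ug_kg * f)
    expect_lte(count(base, up), n0)
    hot <- dplyr::mutate(base,
                         concentration_ug_kg = concentration_ug_kg * f)
    expect_gte(count(hot, mrl), n0)
  }
})

test_that("verdicts under one jurisdiction ignore the other registry", {
  toy <- random_toy(n_samples = 30, limit = 100, seed = 5)
  mrl <- toy_mrl()
  tweaked <- dplyr::mutate(mrl, limit_ug_kg = ifelse(jurisdiction == "EU",
                                                     limit_ug_kg / 100,
                                                     limit_ug_kg))
  expect_equal(sample_compliance(toy, mrl, "CN"),
               sample_compliance(toy, tweaked, "CN"))
})
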