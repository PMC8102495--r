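# exposure equations, risk tables, group rankings and ratio calibration

test_that("intake estimates follow the summed residue x ratio model", {
  expect_equal(nedi(c(a = 0, b = 0), 0.003), 0)
  # hand arithmetic: summed means for a four-commodity pesticide
  r <- c(strawberry = 28.1, melon = 6.8, peach = 36.6, grape = 106.3) / 1000
  expect_equal(nedi(r, 3.0993e-3), sum(r) * 3.0993e-3, tolerance = 1e-12)
  expect_equal(nedi(r, 3.0993e-3), 5.511e-4, tolerance = 1e-3)
  expect_equal(nedi(2 * r, 3.0993e-3), 2 * nedi(r, 3.0993e-3))
  # per-commodity ratios must cover every commodity present
  expect_error(nedi(r, c(strawberry = 1e-3)), "no f_over_bw ratio")
  expect_equal(esti(c(strawberry = 0.1631), 2.4071e-2), 3.926e-3,
               tolerance = 1e-3)
  # monotonicity: larger residues and ratios give at least as much intake
  expect_gte(esti(c(a = 2, b = 3), 0.02), nedi(c(a = 1, b = 3), 0.01))
})

test_that("chronic hazard quotients reproduce printed single-commodity cells", {
  # hexaconazole, 60-70 female: strawberry only, ADI 0.005
  expect_equal(chronic_risk(nedi(c(strawberry = 0.0202), 6.4089e-4), 0.005),
               0.2589, tolerance = 2e-3)
  expect_equal(chronic_risk(0, 0.1), 0)
  # fluopyram, 2-4 male: strawberry + melon, ADI 0.01
  expect_equal(chronic_risk(nedi(c(0.5449, 0.2109), 3.0993e-3), 0.01),
               23.4244, tolerance = 1e-4 * 23.4244)
  expect_error(chronic_risk(1e-4, NA), "requires a positive ADI")
  expect_error(chronic_risk(1e-4, 0), "requires a positive ADI")
})

test_that("acute quotients compute when established and skip otherwise", {
  got <- acute_risk(esti(c(strawberry = 0.1631), 2.4071e-2), 0.05)
  expect_equal(got$pct_arfd, 7.8510, tolerance = 2e-4)
  expect_true(is.na(got$skip_reason))
  skip1 <- acute_risk(1, NA, "unnecessary")
  expect_true(is.na(skip1$pct_arfd))
  expect_equal(skip1$skip_reason, "arfd_unnecessary")
  skip2 <- acute_risk(1, NA, "not_established")
  expect_equal(skip2$skip_reason, "arfd_not_established")
})

test_that("risk_table produces full chronic and established-only acute grids", {
  ra <- risk_table(shanghai_occurrence(), shanghai_tox(),
                   china_consumer_groups())
  expect_s3_class(ra, "exposure_assessment")
  expect_equal(nrow(ra$chronic), 57L * 6L)
  expect_equal(nrow(ra$acute), 25L * 6L)
  expect_equal(nrow(ra$skipped_acute), 32L)
  expect_setequal(ra$skipped_acute$skip_reason[
    ra$skipped_acute$pesticide == "Bifenazate"], "arfd_unnecessary")
  expect_setequal(ra$skipped_acute$skip_reason[
    ra$skipped_acute$pesticide == "Triflumuron"], "arfd_not_established")

  cell <- dplyr::filter(ra$chronic, pesticide == "Difenoconazole",
                        group == "2-4 Male")
  expect_equal(cell$pct_adi, 5.5105, tolerance = 1e-4)

  empty <- risk_table(shanghai_occurrence()[0, ], shanghai_tox(),
                      china_consumer_groups())
  expect_equal(nrow(empty$chronic), 0L)
  expect_equal(nrow(empty$acute), 0L)
})

test_that("pesticides without toxicology are reported, not dropped silently", {
  occ <- tibble::tibble(commodity = "apple", pesticide = "mysterycide",
                        n_samples = 10L, n_detects = 2L, min_ug_kg = 1,
                        max_ug_kg = 3, mean_ug_kg = 2)
  expect_warning(ra <- risk_table(occ, shanghai_tox(),
                                  china_consumer_groups()),
                 "mysterycide")
  expect_equal(ra$unassessed$pesticide, "mysterycide")
  expect_equal(nrow(ra$chronic), 0L)
})

test_that("every chronic cell equals the scalar hand recomputation", {
  occ <- shanghai_occurrence()
  tox <- shanghai_tox()
  groups <- china_consumer_groups()
  ra <- risk_table(occ, tox, groups)
  # independent oracle: explicit per-cell loop over base-R aggregates
  sums <- tapply(occ$mean_ug_kg / 1000, tolower(occ$pesticide), sum)
  set.seed(42)
  for (i in sample(nrow(ra$chronic), 60)) {
    p <- tolower(ra$chronic$pesticide[i])
    g <- ra$chronic$group[i]
    adi <- tox$adi_mg_kg_bw_day[tolower(tox$pesticide) == p]
    f <- groups$f_over_bw[groups$group == g]
    expect_equal(ra$chronic$pct_adi[i], 100 * sums[[p]] * f / adi)
  }
})

test_that("hazard quotients are linear, additive and scale invariant", {
  occ <- shanghai_occurrence()
  tox <- shanghai_tox()
  groups <- china_consumer_groups()
  ra <- risk_table(occ, tox, groups)
  # scale invariance: c times the residues, c times every quotient
  for (c_ in c(0.5, 3)) {
    scaled <- dplyr::mutate(occ, mean_ug_kg = mean_ug_kg * c_,
                            max_ug_kg = max_ug_kg * c_)
    rs <- risk_table(scaled, tox, groups)
    expect_equal(rs$chronic$pct_adi, c_ * ra$chronic$pct_adi)
    expect_equal(rs$acute$pct_arfd, c_ * ra$acute$pct_arfd)
  }
  # additivity: a multi-commodity quotient is the sum of per-commodity runs
  flu <- dplyr::filter(occ, pesticide == "Fluopyram")
  whole <- risk_table(flu, tox, groups)$chronic
  parts <- purrr::map(seq_len(nrow(flu)), function(i) {
    risk_table(flu[i, ], tox, groups)$chronic$pct_adi
  })
  expect_equal(whole$pct_adi, Reduce(`+`, parts))
})

test_that("acute aggregation switch takes the worst commodity instead of the sum", {
  occ <- shanghai_occurrence()
  tox <- shanghai_tox()
  groups <- china_consumer_groups()
  ra_sum <- risk_table(occ, tox, groups, acute_aggregation = "sum")
  ra_max <- risk_table(occ, tox, groups, acute_aggregation = "max_commodity")
  expect_true(all(ra_max$acute$pct_arfd <= ra_sum$acute$pct_arfd + 1e-12))
  flu_max <- dplyr::filter(ra_max$acute, pesticide == "Fluopyram",
                           group == "2-4 Male")
  # strawberry maximum dominates the melon one
  expect_equal(flu_max$esti, 6.2605 * groups$lp_over_bw[groups$group == "2-4 Male"])
})

test_that("cross-cell consistency holds between printed single-commodity cells", {
  # for two pesticides detected only in strawberry, the printed %ADI ratio
  # equals (R1/ADI1)/(R2/ADI2) in every group
  ref <- shanghai_chronic_reference()
  occ <- shanghai_occurrence()
  pick <- function(p) dplyr::filter(ref, tolower(pesticide) == p)
  r_bif <- occ$mean_ug_kg[occ$pesticide == "Bifenazate"]
  r_hex <- occ$mean_ug_kg[occ$pesticide == "Hexaconazole"]
  want <- (r_bif / 0.01) / (r_hex / 0.005)
  got <- pick("bifenazate")$pct_adi / pick("hexaconazole")$pct_adi
  expect_equal(got, rep(want, 6), tolerance = 5e-3)
})

test_that("group rankings order by consumption ratio with ties flagged", {
  groups <- china_consumer_groups()
  rk <- rank_groups(groups)
  expect_equal(dplyr::filter(rk, risk_kind == "chronic")$group,
               c("2-4 Female", "2-4 Male", "18-30 Female", "18-30 Male",
                 "60-70 Female", "60-70 Male"))
  expect_equal(dplyr::filter(rk, risk_kind == "acute")$group,
               c("2-4 Female", "2-4 Male", "18-30 Female", "60-70 Female",
                 "18-30 Male", "60-70 Male"))
  expect_false(any(rk$tied))

  tied <- tibble::tibble(group = c("a", "b"), f_over_bw = c(1e-3, 1e-3),
                         lp_over_bw = c(2e-3, 1e-3))
  rt <- rank_groups(tied, "chronic")
  expect_true(all(rt$tied))
  expect_equal(rt$group, c("a", "b")) # label order preserved on ties
})

test_that("ratio calibration agrees across reference pesticides within 0.3%", {
  groups <- calibrate_consumption_ratios(shanghai_occurrence(),
                                         shanghai_chronic_reference(),
                                         shanghai_acute_reference())
  calib <- attr(groups, "calibration")
  expect_lte(max(calib$rel_dev), 0.003)
  # the packaged fixture stores these same derived ratios (5 significant
  # figures)
  expect_equal(groups$f_over_bw, china_consumer_groups()$f_over_bw,
               tolerance = 1e-4)
  expect_equal(groups$lp_over_bw, china_consumer_groups()$lp_over_bw,
               tolerance = 1e-4)
  expect_error(
    calibrate_consumption_ratios(shanghai_occurrence(),
                                 shanghai_chronic_reference(),
                                 shanghai_acute_reference(),
                                 chronic_pesticides = c("Bifenazate", "nope")),
    "not in")
})
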