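mk_pheno <- function(bp, pairs = NULL) {
  if (is.null(pairs))
    pairs <- data.frame(pair_id = unique(bp$pair_id), pre_pregnancy_bmi = 21,
                        birth_weight = 3000, placental_weight = 550,
                        gestational_age_at_delivery = 39.5,
                        fetal_sex = "female", parity = "nulliparous",
                        hypertension_flag = "none")
  structure(list(pairs = pairs, bp = bp), class = "pheno_table")
}

test_that("PP and MAP follow their formulas and period means split correctly", {
  bp <- data.frame(pair_id = "P1", gestational_week = c(12, 25, 36),
                   sbp = c(120, 110, 118), dbp = c(80, 70, 78))
  der <- derive_bp(mk_pheno(bp))
  expect_equal(der$obs$pp, c(40, 40, 40))
  expect_equal(der$obs$map, c(93 + 1 / 3, 83 + 1 / 3, 91 + 1 / 3))
  pm <- der$period_means
  expect_equal(pm$sbp[pm$period == "early"], 120)
  expect_equal(pm$sbp[pm$period == "middle"], 110)
  expect_equal(pm$sbp[pm$period == "late"], 118)
  # dbp < map < sbp whenever pp > 0
  expect_true(all(der$obs$dbp < der$obs$map & der$obs$map < der$obs$sbp))
})

test_that("period boundaries are [<20), [20,34), [34,) and order-invariant", {
  bp <- data.frame(pair_id = "P1",
                   gestational_week = c(19.9, 20, 33.9, 34),
                   sbp = c(100, 110, 120, 130), dbp = c(60, 70, 80, 90))
  pm <- derive_bp(mk_pheno(bp))$period_means
  expect_equal(pm$sbp[pm$period == "early"], 100)
  expect_equal(pm$sbp[pm$period == "middle"], 115)
  expect_equal(pm$sbp[pm$period == "late"], 130)
  shuf <- bp[c(3, 1, 4, 2), ]
  pm2 <- derive_bp(mk_pheno(shuf))$period_means
  expect_equal(pm2$sbp, pm$sbp)
})

test_that("a record with no reading in a period is flagged missing there", {
  bp <- data.frame(pair_id = "P1", gestational_week = c(12, 36),
                   sbp = c(120, 118), dbp = c(80, 78))
  pm <- derive_bp(mk_pheno(bp))$period_means
  expect_true(is.na(pm$sbp[pm$period == "middle"]))
})

test_that("eligibility excludes hypertension flags and early deliveries", {
  pairs <- data.frame(pair_id = sprintf("P%d", 1:4), pre_pregnancy_bmi = 21,
                      birth_weight = 3000, placental_weight = 550,
                      gestational_age_at_delivery = c(39, 39, 39, 33.5),
                      fetal_sex = "female", parity = "nulliparous",
                      hypertension_flag = c("none", "HDP", "chronic", "none"))
  bp <- data.frame(pair_id = "P1", gestational_week = 12, sbp = 120, dbp = 80)
  out <- filter_eligible(mk_pheno(bp, pairs))
  expect_equal(out$pairs$pair_id, "P1")
  # all-eligible input passes through unchanged
  ok <- pairs[1, , drop = FALSE]
  expect_equal(filter_eligible(mk_pheno(bp, ok))$pairs, ok)
})

test_that("chart standardization is the stratum z-score and inverts exactly", {
  chart <- placmed_chart()
  pairs <- data.frame(pair_id = "P1", pre_pregnancy_bmi = 21,
                      birth_weight = NA_real_, placental_weight = NA_real_,
                      gestational_age_at_delivery = 39.2,
                      fetal_sex = "male", parity = "parous",
                      hypertension_flag = "none")
  strat <- chart[chart$week == 39 & chart$sex == "male" &
                   chart$parity == "parous", ]
  pairs$birth_weight <- strat$bw_mean + 1.0 * strat$bw_sd
  pairs$placental_weight <- strat$pw_mean
  adj <- chart_adjust(mk_pheno(data.frame(pair_id = "P1",
                                          gestational_week = 12,
                                          sbp = 120, dbp = 80), pairs),
                      chart)
  expect_equal(adj$bw_z, 1.0)
  expect_equal(adj$pw_z, 0.0)

  # simulator round trip: generated z is recovered to numerical precision
  study <- simulate_study(tiny_config(seed = 121))
  rec <- chart_adjust(study$phenotypes, study$chart)
  expect_equal(rec$bw_z, study$truth$Y_z, tolerance = 1e-9)
  expect_equal(rec$pw_z, study$truth$M_z, tolerance = 1e-9)

  # missing stratum errors at use time
  pairs$gestational_age_at_delivery <- 33
  expect_error(chart_adjust(mk_pheno(data.frame(pair_id = "P1",
                                                gestational_week = 12,
                                                sbp = 120, dbp = 80),
                                     pairs), chart),
               "chart-coverage")
})

test_that("z-scaling is affine-invariant, idempotent and degenerate-safe", {
  z <- zscale(c(1, 2, 3))
  expect_equal(mean(z$z), 0)
  expect_equal(sd(z$z), 1)
  x <- rnorm(50)
  expect_equal(zscale(zscale(x)$z)$z, zscale(x)$z, tolerance = 1e-12)
  expect_equal(zscale(3 * x + 7)$z, zscale(x)$z, tolerance = 1e-12)
  zc <- zscale(rep(5, 10))
  expect_true(zc$degenerate)
  expect_equal(zc$z, rep(0, 10))
})
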