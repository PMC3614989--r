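test_that("POF fractions convert to the reported spawning intervals", {
  est <- spawning_fraction(mature_pof_table(20, 9))
  expect_equal(est$fraction, 0.45)
  expect_equal(round(est$interval_days, 1), 2.2)
  expect_equal(est$se, sqrt(0.45 * 0.55 / 20))
  est2 <- spawning_fraction(mature_pof_table(20, 15), months = 10:12)
  expect_equal(est2$fraction, 0.75)
  expect_equal(round(est2$interval_days, 1), 1.3)
  # daily spawning when every ovary carries POFs
  est3 <- spawning_fraction(mature_pof_table(10, 10))
  expect_equal(est3$interval_days, 1)
})

test_that("interval times fraction is exactly one whenever defined", {
  for (k in 1:19) {
    est <- spawning_fraction(mature_pof_table(19, k))
    expect_equal(est$fraction * est$interval_days, 1)
  }
  est0 <- spawning_fraction(mature_pof_table(12, 0))
  expect_true(is.na(est0$interval_days))
  expect_equal(est0$fraction, 0)
})

test_that("the latitude band and month filters shape the denominator", {
  x <- dplyr::bind_rows(
    mature_pof_table(10, 5, month = 11, latitude = -15),
    mature_pof_table(10, 0, month = 4, latitude = -15),
    mature_pof_table(10, 10, month = 11, latitude = -40))
  est <- spawning_fraction(x)                      # band drops the -40 fish
  expect_equal(est$n_mature, 20L)
  expect_equal(est$fraction, 0.25)
  est_pk <- spawning_fraction(x, months = 10:12)
  expect_equal(est_pk$fraction, 0.5)
  expect_error(spawning_fraction(x, months = 6), "no mature females")
})

test_that("the POF degeneration clock is piecewise and monotone", {
  expect_equal(expected_pof_stage(c(0, 3.9, 4, 11.9, 12, 23.9, 24, 30)),
               c("new", "new", "lt12h", "lt12h", "h12_24", "h12_24",
                 "absent", "absent"))
  expect_error(expected_pof_stage(-1), "non-negative")
  hrs <- sort(runif(100, 0, 48))
  idx <- match(expected_pof_stage(hrs),
               c("new", "lt12h", "h12_24", "absent"))
  expect_true(all(diff(idx) >= 0))
})

test_that("diel consistency matches observed POF ages to capture times", {
  x <- tibble::tibble(
    fish_id = c("a", "b", "c", "d"),
    capture_time = c("00:22", "15:00", "02:00", NA),
    mago_stage = c("hydrated", "advanced_yolked", "advanced_yolked",
                   "unyolked"),
    pof_stage = c("new", "h12_24", "h12_24", "absent"))
  out <- diel_consistency(x, spawn_hour = 0)
  expect_equal(nrow(out), 3L)                     # missing time skipped
  expect_equal(attr(out, "n_skipped"), 1L)
  expect_true(out$consistent[out$fish_id == "a"])  # spawning imminent/ongoing
  expect_true(out$consistent[out$fish_id == "b"])  # >12 h stage after 1400
  expect_false(out$consistent[out$fish_id == "c"]) # 2 h cannot give >12 h POF
})

test_that("gravimetric batch fecundity raises counts to lobe weights", {
  two <- tibble::tibble(
    lobe = c("left", "right"), subsample_weight_g = c(0.06, 0.05),
    oocyte_count = c(120L, 100L), lobe_weight_g = c(300, 250))
  est <- batch_fecundity(two)
  expect_equal(est$batch_fecundity, 120 / 0.06 * 300 + 100 / 0.05 * 250)
  expect_equal(est$batch_fecundity, 1100000)
  expect_false(est$single_lobe)
  zero <- dplyr::mutate(two, oocyte_count = 0L)
  expect_equal(batch_fecundity(zero)$batch_fecundity, 0)
  one <- batch_fecundity(two[1, ])
  expect_equal(one$batch_fecundity, 600000)
  expect_true(one$single_lobe)
  expect_error(batch_fecundity(dplyr::mutate(two, subsample_weight_g = 0)),
               "subsample_weight_g")
})

test_that("batch fecundity is linear in counts and lobe weights", {
  set.seed(31)
  for (i in 1:10) {
    x <- tibble::tibble(
      lobe = c("left", "right"),
      subsample_weight_g = runif(2, 0.05, 0.09),
      oocyte_count = as.integer(sample(50:300, 2)),
      lobe_weight_g = runif(2, 100, 400))
    b <- batch_fecundity(x)$batch_fecundity
    expect_equal(batch_fecundity(
      dplyr::mutate(x, oocyte_count = oocyte_count * 3L))$batch_fecundity,
      3 * b)
    expect_equal(batch_fecundity(
      dplyr::mutate(x, lobe_weight_g = lobe_weight_g * 1.5))$batch_fecundity,
      1.5 * b)
  }
})

test_that("relative fecundity scales to oocytes per gram of body weight", {
  expect_equal(round(relative_batch_fecundity(1100000, 17), 1), 64.7)
  expect_equal(relative_batch_fecundity(0, 20), 0)
  expect_true(is.na(relative_batch_fecundity(1e6, NA)))
  expect_error(relative_batch_fecundity(1e6, 0), "positive")
})

test_that("per-fish fecundity table carries weights and months", {
  fx <- fixture_small()
  tab <- batch_fecundity_table(fx$subsamples, fx$samples)
  a12 <- tab[tab$fish_id == "A12", ]
  expect_equal(a12$batch_fecundity, 1100000)
  expect_equal(round(a12$relative_fecundity, 1), 64.7)
  expect_equal(a12$month, 10L)
  a14 <- tab[tab$fish_id == "A14", ]
  expect_true(a14$single_lobe)
})

test_that("the annual integrator multiplies batch, fraction and days", {
  b <- setNames(rep(1e6, 12), 1:12)
  f <- setNames(rep(0.5, 12), 1:12)
  d30 <- setNames(rep(30, 12), 1:12)
  out <- potential_annual_fecundity(b, f, d30)
  expect_equal(out$monthly$monthly_fecundity, rep(15e6, 12))
  expect_equal(out$annual, 180e6)
  # zero fraction everywhere -> zero annual output
  expect_equal(potential_annual_fecundity(b, f * 0, d30)$annual, 0)
  # a single active month contributes exactly its product
  f1 <- setNames(c(0.6, rep(0, 11)), 1:12)
  expect_equal(potential_annual_fecundity(b, f1, d30)$annual,
               1e6 * 0.6 * 30)
  # calendar default
  expect_equal(potential_annual_fecundity(b, f)$annual, 1e6 * 0.5 * 365)
  expect_error(potential_annual_fecundity(b[1:6], f), "same named months")
})

test_that("annual fecundity is monotone in every monthly input", {
  set.seed(41)
  b <- setNames(runif(12, 5e5, 2e6), 1:12)
  f <- setNames(runif(12, 0, 1), 1:12)
  base <- potential_annual_fecundity(b, f)$annual
  for (m in sample(12, 4)) {
    b2 <- b; b2[m] <- b2[m] * 1.2
    expect_gt(potential_annual_fecundity(b2, f)$annual, base)
    f2 <- f; f2[m] <- min(1, f2[m] + 0.1)
    expect_gte(potential_annual_fecundity(b, f2)$annual, base)
  }
})

test_that("the integrator evaluates grids row-wise over length", {
  months <- as.character(10:12)
  b <- matrix(c(1e6, 1e6, 1e6, 2e6, 2e6, 2e6), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, months))
  f <- matrix(0.5, 2, 3, dimnames = list(NULL, months))
  d <- setNames(rep(30, 3), months)
  out <- potential_annual_fecundity(b, f, d)
  expect_equal(out$annual, c(45e6, 90e6))
})
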