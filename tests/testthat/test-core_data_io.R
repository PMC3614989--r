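test_that("fixture tables round-trip through CSV unchanged", {
  fx <- fixture_small()
  dir <- withr::local_tempdir()
  readr::write_csv(fx$samples[setdiff(names(fx$samples), "month")],
                   file.path(dir, "samples.csv"), na = "")
  readr::write_csv(fx$histology, file.path(dir, "histology.csv"), na = "")
  readr::write_csv(fx$subsamples, file.path(dir, "subsamples.csv"), na = "")
  s2 <- read_samples(file.path(dir, "samples.csv"))
  expect_equal(as.data.frame(s2), as.data.frame(fx$samples))
  expect_equal(as.data.frame(read_histology(file.path(dir, "histology.csv"))),
               as.data.frame(fx$histology))
  expect_equal(
    as.data.frame(read_subsamples(file.path(dir, "subsamples.csv"))),
    as.data.frame(fx$subsamples))
})

test_that("simulated population round-trips through write_population", {
  sim <- simulate_population(
    modifyList(default_truth(3L), list(n_sets = 20L)), seed = 3L)
  dir <- withr::local_tempdir()
  write_population(sim, dir)
  s2 <- read_samples(file.path(dir, "samples.csv"))
  expect_equal(nrow(s2), nrow(sim$samples))
  expect_equal(as.data.frame(s2), as.data.frame(sim$samples))
})

test_that("missing cells become missing values and rows are preserved", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "s.csv")
  writeLines(c(
    "fish_id,set_id,region,date,latitude,longitude,fork_length_cm,length_binned,whole_weight_kg,sex,gonad_weight_g,sst_c,age_years",
    "F1,S1,Tonga,2010-11-02,-18.5,185.2,98,FALSE,18.2,female,320,,",
    "F2,S1,Tonga,2010-11-02,-18.5,185.2,95,FALSE,,male,,,"), p)
  x <- read_samples(p)
  expect_equal(nrow(x), 2L)
  expect_true(is.na(x$gonad_weight_g[2]))
  expect_true(is.na(x$whole_weight_kg[2]))
  expect_equal(x$month, c(11L, 11L))
})

test_that("row-level validation names the offending rows", {
  bad <- fixture_small()$samples
  bad$sex[3] <- "hermaphrodite"
  expect_error(validate_samples(bad), "sex level.*3")
  bad2 <- fixture_small()$samples
  bad2$fork_length_cm[5] <- -10
  expect_error(validate_samples(bad2), "fork_length_cm.*5")
})

test_that("join keeps fish without histology and reports orphans", {
  fx <- fixture_small()
  s <- fx$samples[fx$samples$fish_id %in% c("A01", "A02", "M01"), ]
  h <- fx$histology[fx$histology$fish_id %in% c("A01", "A02"), ]
  # 3 samples, 2 matching histology rows -> 3 rows, 1 without histology
  j <- join_records(s, h)
  expect_equal(nrow(j), 3L)
  expect_equal(sum(is.na(j$mago_stage)), 1L)
  orphan <- tibble::tibble(
    fish_id = "ZZZ", mago_stage = "unyolked", pof_stage = "absent",
    alpha_atresia = "absent", beta_atresia = "absent",
    maturity_markers = "absent")
  expect_warning(j2 <- join_records(s, orphan), "unmatched")
  expect_equal(nrow(attr(j2, "orphans")$histology), 1L)
})

test_that("duplicate fish ids are an error listing the duplicates", {
  s <- fixture_small()$samples[c(1, 1, 2), ]
  expect_error(join_records(s), "duplicate fish_id.*M01")
})

test_that("join then split reproduces the inputs", {
  fx <- fixture_small()
  j <- join_records(fx$samples, fx$histology, fx$subsamples)
  expect_equal(nrow(j), nrow(fx$samples))
  back <- j[names(fx$samples)]
  expect_equal(as.data.frame(back), as.data.frame(fx$samples),
               ignore_attr = TRUE)
  hist_back <- j[!is.na(j$mago_stage), names(fx$histology)]
  expect_equal(as.data.frame(dplyr::arrange(hist_back, fish_id)),
               as.data.frame(dplyr::arrange(fx$histology, fish_id)),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(attr(j, "subsamples")),
               as.data.frame(fx$subsamples))
})

test_that("clock times parse to decimal hours", {
  expect_equal(parse_clock_time(c("00:22", "15:30", "23:59")),
               c(22 / 60, 15.5, 23 + 59 / 60))
  expect_true(is.na(parse_clock_time("25:00")))
  expect_true(is.na(parse_clock_time(NA_character_)))
})

test_that("run configs read from YAML and reject unknown fields", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.yaml")
  writeLines(c("seed: 9", "peak_months: [10, 11, 12]"), p)
  cfg <- read_run_config(p)
  expect_equal(cfg$seed, 9L)
  writeLines("not_a_field: 1", p)
  expect_error(read_run_config(p), "unknown config field")
})
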