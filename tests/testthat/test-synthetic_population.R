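test_that("the same seed reproduces the dataset exactly", {
  tr <- modifyList(default_truth(9L), list(n_sets = 40L))
  a <- simulate_population(tr, seed = 9L)
  b <- simulate_population(tr, seed = 9L)
  expect_identical(a$samples, b$samples)
  expect_identical(a$histology, b$histology)
  expect_identical(a$subsamples, b$subsamples)
  expect_identical(a$latent, b$latent)
  c <- simulate_population(tr, seed = 10L)
  expect_false(identical(a$samples, c$samples))
})

test_that("truth validation rejects out-of-range parameters", {
  tr <- default_truth()
  tr$pof_frac_by_month[3] <- 1.4
  expect_error(validate_truth(tr), "\\[0, 1\\]")
  tr2 <- default_truth()
  tr2$activity_by_month <- rev(tr2$activity_by_month) # peak moves to Jan-Mar
  expect_error(validate_truth(tr2), "October-December")
  tr3 <- default_truth()
  tr3$relfec_sd <- -1
  expect_error(validate_truth(tr3), "SD")
})

test_that("the classifier inverts the generative histology exactly", {
  sim <- simulate_population(default_truth(13L), seed = 13L)
  cls <- classify_histology(sim$histology)
  lat <- sim$latent[match(cls$fish_id, sim$latent$fish_id), ]
  expect_identical(cls$class_code, lat$true_class)
  expect_false(any(cls$class_code == "unclassifiable"))
  # latent flags agree with the decision-table classes
  expect_equal(cls$mature, lat$mature)
  expect_equal(cls$active, lat$active)
})

test_that("latent spawning state matches the generated POF stages", {
  sim <- simulate_population(default_truth(17L), seed = 17L)
  h <- sim$histology
  lat <- sim$latent[match(h$fish_id, sim$latent$fish_id), ]
  expect_equal(h$pof_stage %in% c("new", "lt12h", "h12_24"),
               as.logical(lat$spawned_24h))
  sp <- which(lat$spawned_24h)
  expect_equal(h$pof_stage[sp],
               expected_pof_stage(lat$hours_since_spawn[sp]))
})

test_that("no active females are generated outside the spawning band", {
  sim <- simulate_population(default_truth(19L), seed = 19L)
  j <- join_records(sim$samples, classify_histology(sim$histology))
  act <- j[!is.na(j$active) & j$active, ]
  expect_gt(nrow(act), 100)
  expect_true(all(act$latitude >= -25 & act$latitude <= -10))
})

test_that("class seasonality reproduces the expected pattern north of 25S", {
  # regenerating dominates austral autumn/winter; spawning classes dominate
  # the Oct-Dec peak
  props <- lapply(1:3, function(i) {
    sim <- simulate_population(default_truth(100L + i), seed = 100L + i)
    j <- join_records(sim$samples, classify_histology(sim$histology))
    freq <- class_frequencies(j[!is.na(j$class_code), ])
    north <- freq[grepl("^north", freq$zone) & freq$n_mature > 0, ]
    win <- north[north$month %in% 3:8, ]
    pk <- north[north$month %in% 10:12, ]
    c(win_regen = sum(win$n_class[win$class_code == "7"]) /
        sum(win$n_class),
      pk_spawn = sum(pk$n_class[pk$class_code %in% c("3", "4")]) /
        sum(pk$n_class))
  })
  props <- do.call(rbind, props)
  expect_true(all(props[, "win_regen"] > 0.5))
  expect_true(all(props[, "pk_spawn"] > 0.5))
})

test_that("empirical relative fecundity converges to the configured mean", {
  tr <- modifyList(default_truth(23L), list(n_sets = 500L))
  sim <- simulate_population(tr, seed = 23L)
  fec <- batch_fecundity_table(sim$subsamples, sim$samples)
  rf <- fec$relative_fecundity[!is.na(fec$relative_fecundity)]
  expect_gt(length(rf), 200)
  se <- sd(rf) / sqrt(length(rf))
  # truncation at zero lifts the mean of N(64.4, 24.7) by ~0.1; negligible
  expect_lt(abs(mean(rf) - 64.4), 2 * se + 1)
})

test_that("aged females are a subset and ages grow with length", {
  sim <- simulate_population(default_truth(29L), seed = 29L)
  aged <- sim$samples[!is.na(sim$samples$age_years), ]
  expect_lte(nrow(aged), 500)
  expect_true(all(aged$sex == "female"))
  expect_gt(stats::cor(aged$age_years, aged$fork_length_cm), 0.5)
})

test_that("the small fixture covers classes, sexes, months and fecundity", {
  fx <- fixture_small()
  cls <- classify_histology(fx$histology)
  expect_true(all(c("1", "2", "3", "4", "5", "6a", "6b", "7") %in%
                    cls$class_code))
  expect_setequal(unique(fx$samples$sex), c("female", "male"))
  expect_setequal(unique(fx$samples$month), 1:12)
  # a fecundity-ready fish in each peak spawning month
  fec <- batch_fecundity_table(fx$subsamples, fx$samples)
  expect_true(all(c(10, 11, 12, 1) %in% fec$month))
  # deterministic
  expect_identical(fixture_small()$samples, fx$samples)
})
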