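# Individual-based generator for set-clustered fish sampling data with a
# fully known latent truth, so every estimator in the pipeline can be
# validated without field data.
#
# The generative chain per fish is: sampling set (region, position, month,
# haul hour, set-level random effect) -> fork length -> sex (length-
# dependent, males dominating the largest classes) -> maturity (logistic in
# length) -> daily spawning state within the spawning latitude band
# (month-by-month spawning fraction with a length effect and the set random
# intercept on the logit scale) -> histological criteria written by running
# the classification decision table in reverse -> gonad weight, oocyte
# diameters and ovary-lobe subsamples.
#
# Because the monthly spawning fractions are population-level targets while
# the per-fish probabilities carry logit-scale heterogeneity (set effect and
# length effect), the baseline logit of each month is calibrated by root
# finding so that the marginal fraction over the realized pool equals the
# configured target.

#' Default synthetic-population truth
#'
#' Calibration: ~350 sets of ~10 fish across 10 regions mirroring the
#' field sampling design (~3500 fish); maturity logistic with L50 = 87 cm;
#' peak-season (Oct-Dec) daily spawning fraction 0.75 of mature females in
#' the 10-25 degS band and 0.45 annually; relative batch fecundity normal
#' with mean 64.4 and SD 24.7 oocytes per g, truncated at zero; oocyte
#' diameters within 332-571 um increasing with length and MAGO stage;
#' spawning at midnight with a 24-h POF degeneration cycle.
#'
#' @param seed Integer seed stored in the truth (used by
#'   [simulate_population()] unless overridden).
#' @return Named list of generator parameters (class `synthetic_truth`).
#' @export
default_truth <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    n_sets = 350L,
    fish_per_set_mean = 10,
    regions = tibble(
      region = c("American Samoa", "Australia", "Cook Islands", "Fiji",
                 "French Polynesia", "International Waters 1",
                 "International Waters 2", "New Caledonia", "New Zealand",
                 "Tonga"),
      weight = c(404, 1496, 186, 201, 363, 30, 9, 226, 449, 133),
      lat_min = c(-15, -40, -22, -20, -25, -25, -32, -24, -45, -23),
      lat_max = c(-11, -15, -10, -15, -9, -20, -26, -18, -34, -15),
      lon_min = c(187, 145, 195, 176, 205, 160, 225, 162, 166, 182),
      lon_max = c(193, 155, 203, 182, 220, 163, 235, 170, 179, 187)),
    juvenile_lat = -30,        # sets south of this sample the juvenile grounds
    fl_juvenile_mean = 62, fl_juvenile_sd = 9,
    fl_adult_mean = 96, fl_adult_sd = 8,
    fl_range = c(45, 120),
    p_unknown_sex = 0.01,
    # P(male | FL): female-biased small fish, male-biased above ~95 cm
    sexratio_base = 0.35, sexratio_span = 0.35,
    sexratio_mid = 95, sexratio_scale = 6,
    maturity_l50 = 87, maturity_slope = 0.4,      # logit units per cm
    spawn_lat_band = c(-25, -10),
    # monthly targets over mature females in the band
    activity_by_month = c(0.70, 0.55, 0.40, 0.20, 0.12, 0.12,
                          0.18, 0.25, 0.40, 0.88, 0.92, 0.88),
    pof_frac_by_month = c(0.60, 0.45, 0.25, 0.10, 0.05, 0.05,
                          0.08, 0.12, 0.25, 0.75, 0.75, 0.75),
    beta_fl_spawn = 0.06,      # logit/cm, centred at the mature mean length
    beta_fl_active = 0.08,
    sd_set_spawn = 0.5,        # random set intercept SD on the spawning logit
    # regenerating share of inactive mature fish, by month
    p_regen_by_month = c(0.45, 0.45, 0.80, 0.80, 0.80, 0.80,
                         0.80, 0.80, 0.60, 0.30, 0.30, 0.30),
    regress_split = c("5" = 0.4, "6a" = 0.3, "6b" = 0.3),
    p_class2 = 0.05,
    hist_min_fl = 70,
    # gonad index model (lognormal; multiplicative month and longitude)
    gi_mean_active = 2.3, gi_mean_inactive = 0.9, gi_mean_immature = 0.25,
    gi_mean_male = 1.1, gi_mean_male_juv = 0.3,
    gi_sd_log = 0.3, gi_lon_slope = 0.002,
    gi_month_mult = c(1.00, 0.95, 0.90, 0.85, 0.80, 0.80,
                      0.85, 0.90, 1.00, 1.20, 1.25, 1.20),
    lw_a = 1.34e-5, lw_b = 3.107,                 # W (kg) = a * FL^b
    relfec_mean = 64.4, relfec_sd = 24.7,         # oocytes / g, truncated at 0
    diam_base = 360, diam_fl_slope = 1.1, diam_mn_shift = 25,
    diam_sd = 15, diam_clamp = c(335, 568),
    spawn_hour = 0, pof_new_h = 4,
    sst_base = 29.5, sst_lat_slope = 0.22, sst_amp = 1.2,
    p_weight_obs = 0.7, p_gw_obs = 0.8,
    n_aged = 500L,
    growth_linf = 106, growth_k = 0.25, growth_t0 = -1,
    mis_rate = 0                                  # histology noise, off
  ), class = "synthetic_truth")
}

#' Validate a synthetic truth
#' @param truth A `synthetic_truth` list.
#' @return The truth, invisibly, or an error.
#' @export
validate_truth <- function(truth) {
  probs <- c(truth$activity_by_month, truth$pof_frac_by_month,
             truth$p_regen_by_month, truth$p_class2, truth$p_unknown_sex,
             truth$p_weight_obs, truth$p_gw_obs)
  if (any(probs < 0 | probs > 1)) {
    stop("truth probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(truth$sd_set_spawn, truth$relfec_sd, truth$gi_sd_log,
            truth$diam_sd) < 0)) {
    stop("truth SDs must be non-negative", call. = FALSE)
  }
  if (!(which.max(truth$activity_by_month) %in% 10:12)) {
    stop("activity multipliers must peak in October-December", call. = FALSE)
  }
  if (any(truth$pof_frac_by_month > truth$activity_by_month)) {
    stop("spawning fraction cannot exceed the active fraction", call. = FALSE)
  }
  stopifnot(length(truth$activity_by_month) == 12,
            length(truth$pof_frac_by_month) == 12,
            abs(sum(truth$regress_split) - 1) < 1e-9)
  invisible(truth)
}

rtruncnorm0 <- function(n, mean, sd) {
  qnorm(runif(n, pnorm(0, mean, sd), 1), mean, sd)
}

#' Simulate a set-clustered fish-sampling dataset with known truth
#'
#' @param truth Generator parameters from [default_truth()] (possibly
#'   modified).
#' @param seed Integer seed; defaults to `truth$seed`. The output is fully
#'   reproducible given the seed.
#' @return List with tibbles `samples`, `histology`, `subsamples` (the three
#'   analysis inputs), `latent` (per-fish latent truth: maturity, activity,
#'   spawned-within-24 h, hours since spawning, true class, true weight and
#'   fecundity) and the `truth` used.
#' @export
simulate_population <- function(truth = default_truth(), seed = truth$seed) {
  validate_truth(truth)
  set.seed(seed)

  ## sampling sets -----------------------------------------------------------
  ns <- truth$n_sets
  ri <- sample.int(nrow(truth$regions), ns, replace = TRUE,
                   prob = truth$regions$weight)
  sets <- tibble(
    set_id = sprintf("S%04d", seq_len(ns)),
    region = truth$regions$region[ri],
    set_lat = runif(ns, truth$regions$lat_min[ri], truth$regions$lat_max[ri]),
    set_lon = runif(ns, truth$regions$lon_min[ri], truth$regions$lon_max[ri]),
    month = sample.int(12, ns, replace = TRUE),
    day = sample.int(28, ns, replace = TRUE),
    haul_hour = ifelse(runif(ns) < 0.7, runif(ns, 14, 24), runif(ns, 6, 14)),
    u_set = rnorm(ns, 0, truth$sd_set_spawn))
  nf <- 1L + rpois(ns, truth$fish_per_set_mean - 1)
  fish <- sets[rep(seq_len(ns), nf), ]
  n <- nrow(fish)
  fish$fish_id <- sprintf("F%05d", seq_len(n))

  ## morphometrics and sex ---------------------------------------------------
  juv <- fish$set_lat < truth$juvenile_lat
  fl <- rnorm(n, ifelse(juv, truth$fl_juvenile_mean, truth$fl_adult_mean),
              ifelse(juv, truth$fl_juvenile_sd, truth$fl_adult_sd))
  fl <- round(pmin(pmax(fl, truth$fl_range[1]), truth$fl_range[2]))
  binned <- fish$region == "Fiji"
  fl[binned] <- floor(fl[binned] / 5) * 5
  p_male <- truth$sexratio_base + truth$sexratio_span *
    plogis((fl - truth$sexratio_mid) / truth$sexratio_scale)
  sex <- ifelse(runif(n) < truth$p_unknown_sex, "unknown",
                ifelse(runif(n) < p_male, "male", "female"))
  w_true <- truth$lw_a * fl^truth$lw_b * exp(rnorm(n, 0, 0.05))

  ## female latent reproductive state ----------------------------------------
  female <- sex == "female"
  mature <- female & runif(n) < plogis(truth$maturity_slope *
                                         (fl - truth$maturity_l50))
  band <- sort(truth$spawn_lat_band)
  in_band <- fish$set_lat >= band[1] & fish$set_lat <= band[2]
  pool <- mature & in_band
  fl_centre <- if (any(pool)) mean(fl[pool]) else truth$fl_adult_mean
  # Calibrate the baseline logit per month so that the *marginal* monthly
  # fraction over the realized pool (length effect + set effect included)
  # equals the configured target exactly.
  calibrate_eta0 <- function(target, offset) {
    target <- min(max(target, 1e-9), 1 - 1e-9)
    if (!length(offset)) return(qlogis(target))
    stats::uniroot(function(e0) mean(plogis(e0 + offset)) - target,
                   interval = qlogis(target) + c(-10, 10),
                   tol = 1e-10)$root
  }
  off_spawn <- truth$beta_fl_spawn * (fl - fl_centre) + fish$u_set
  p_spawn <- rep(0, n)
  for (m in 1:12) {
    idx <- which(pool & fish$month == m)
    if (!length(idx)) next
    e0 <- calibrate_eta0(truth$pof_frac_by_month[m], off_spawn[idx])
    p_spawn[idx] <- plogis(e0 + off_spawn[idx])
  }
  spawned24 <- pool & runif(n) < p_spawn
  q_m <- pmax(truth$activity_by_month - truth$pof_frac_by_month, 0) /
    (1 - truth$pof_frac_by_month)
  off_cap <- truth$beta_fl_active * (fl - fl_centre)
  p_cap <- rep(0, n)
  for (m in 1:12) {
    idx <- which(pool & fish$month == m)
    if (!length(idx)) next
    e0 <- calibrate_eta0(q_m[m], off_cap[idx])
    p_cap[idx] <- plogis(e0 + off_cap[idx])
  }
  capable <- pool & !spawned24 & runif(n) < p_cap
  active <- spawned24 | capable

  ## capture times and POF / MAGO stages -------------------------------------
  cap_hour <- (fish$haul_hour + runif(n, 0, 1.5)) %% 24
  hours_since <- (cap_hour - truth$spawn_hour) %% 24
  pof <- rep("absent", n)
  pof[spawned24] <- expected_pof_stage(hours_since[spawned24],
                                       new_h = truth$pof_new_h)
  mago_active <- ifelse(cap_hour >= 1 & cap_hour < 14, "advanced_yolked",
                        ifelse(cap_hour >= 14 & cap_hour < 19,
                               "migratory_nucleus", "hydrated"))

  ## histology criteria, decision table run in reverse -----------------------
  has_hist <- female & fl >= truth$hist_min_fl
  mago <- rep(NA_character_, n)
  alpha <- rep(NA_character_, n)
  beta <- rep(NA_character_, n)
  markers <- rep(NA_character_, n)
  imm <- has_hist & !mature
  class2 <- imm & runif(n) < truth$p_class2
  mago[imm] <- ifelse(class2[imm], "early_yolked", "unyolked")
  alpha[imm] <- "absent"; beta[imm] <- "absent"; markers[imm] <- "absent"
  act_h <- has_hist & active
  mago[act_h] <- mago_active[act_h]
  alpha[act_h] <- sample(c("absent", "lt50"), sum(act_h), TRUE, c(0.8, 0.2))
  beta[act_h] <- sample(c("absent", "present"), sum(act_h), TRUE, c(0.8, 0.2))
  markers[act_h] <- sample(c("absent", "present"), sum(act_h), TRUE)
  inact <- has_hist & mature & !active
  regen <- inact & runif(n) < truth$p_regen_by_month[fish$month]
  mago[regen] <- sample(c("unyolked", "early_yolked"), sum(regen), TRUE)
  alpha[regen] <- "absent"; beta[regen] <- "absent"; markers[regen] <- "present"
  regr <- inact & !regen
  regr_class <- sample(names(truth$regress_split), sum(regr), TRUE,
                       truth$regress_split)
  i5 <- which(regr)[regr_class == "5"]
  mago[i5] <- "advanced_yolked"
  alpha[i5] <- sample(c("ge50", "all100"), length(i5), TRUE, c(0.8, 0.2))
  beta[i5] <- "present"
  markers[i5] <- sample(c("absent", "present"), length(i5), TRUE)
  i6a <- which(regr)[regr_class == "6a"]
  mago[i6a] <- sample(c("unyolked", "early_yolked"), length(i6a), TRUE,
                      c(0.6, 0.4))
  alpha[i6a] <- "all100"
  beta[i6a] <- sample(c("absent", "present"), length(i6a), TRUE)
  markers[i6a] <- sample(c("absent", "present"), length(i6a), TRUE)
  i6b <- which(regr)[regr_class == "6b"]
  mago[i6b] <- sample(c("unyolked", "early_yolked"), length(i6b), TRUE,
                      c(0.6, 0.4))
  alpha[i6b] <- "absent"; beta[i6b] <- "present"
  markers[i6b] <- sample(c("absent", "present"), length(i6b), TRUE)
  pof[has_hist & !active] <- "absent"

  if (truth$mis_rate > 0) {
    flip <- which(has_hist & runif(n) < truth$mis_rate)
    lv <- field_levels()
    fields <- c("mago_stage", "alpha_atresia", "beta_atresia",
                "maturity_markers")
    pick <- sample(fields, length(flip), TRUE)
    for (j in seq_along(flip)) {
      i <- flip[j]
      val <- sample(lv[[pick[j]]], 1)
      switch(pick[j],
             mago_stage = {mago[i] <- val},
             alpha_atresia = {alpha[i] <- val},
             beta_atresia = {beta[i] <- val},
             maturity_markers = {markers[i] <- val})
    }
  }

  ## gonad weight via the gonad-index model ----------------------------------
  lon_eff <- 1 + truth$gi_lon_slope * (fish$set_lon - 180)
  mm <- truth$gi_month_mult[fish$month]
  gi_mean <- rep(truth$gi_mean_immature, n)
  gi_mean[sex == "male" & fl >= 80] <-
    (truth$gi_mean_male * mm * lon_eff)[sex == "male" & fl >= 80]
  gi_mean[sex == "male" & fl < 80] <- truth$gi_mean_male_juv
  gi_mean[mature & !active] <-
    (truth$gi_mean_inactive * mm * lon_eff)[mature & !active]
  gi_mean[active] <- (truth$gi_mean_active * mm * lon_eff)[active]
  gi_true <- gi_mean * exp(rnorm(n, 0, truth$gi_sd_log))
  gw_true <- gi_true * fl^3 / 1e4

  ## oocyte diameters (advanced-yolked / migratory-nucleus ovaries) ----------
  diam <- matrix(NA_real_, n, 5)
  dm <- has_hist & mago %in% c("advanced_yolked", "migratory_nucleus")
  if (any(dm)) {
    mu <- truth$diam_base + truth$diam_fl_slope * (fl[dm] - 70) +
      truth$diam_mn_shift * (mago[dm] == "migratory_nucleus")
    d <- matrix(rnorm(sum(dm) * 5, rep(mu, 5), truth$diam_sd), ncol = 5)
    diam[dm, ] <- round(pmin(pmax(d, truth$diam_clamp[1]),
                             truth$diam_clamp[2]), 1)
  }

  ## ovary-lobe subsamples for batch fecundity -------------------------------
  fec <- has_hist & mago %in% c("migratory_nucleus", "hydrated")
  relfec <- rep(NA_real_, n)
  batch_true <- rep(NA_real_, n)
  relfec[fec] <- rtruncnorm0(sum(fec), truth$relfec_mean, truth$relfec_sd)
  batch_true[fec] <- relfec[fec] * w_true[fec] * 1000
  fid <- fish$fish_id[fec]
  split_l <- runif(sum(fec), 0.45, 0.55)
  lobe_w <- cbind(gw_true[fec] * split_l, gw_true[fec] * (1 - split_l))
  dens <- batch_true[fec] / gw_true[fec]
  sub_w <- matrix(runif(sum(fec) * 2, 0.05, 0.09), ncol = 2)
  counts <- matrix(rpois(sum(fec) * 2, dens * sub_w), ncol = 2)
  subsamples <- tibble(
    fish_id = rep(fid, each = 2),
    lobe = rep(c("left", "right"), sum(fec)),
    subsample_weight_g = round(as.vector(t(sub_w)), 5),
    oocyte_count = as.integer(as.vector(t(counts))),
    lobe_weight_g = round(as.vector(t(lobe_w)), 2))

  ## ages for a female subset -------------------------------------------------
  age <- rep(NA_integer_, n)
  fem_idx <- which(female)
  aged <- sample(fem_idx, min(truth$n_aged, length(fem_idx)))
  a <- truth$growth_t0 -
    log(1 - pmin(fl[aged], truth$growth_linf - 2) / truth$growth_linf) /
    truth$growth_k + rnorm(length(aged), 0, 0.5)
  age[aged] <- as.integer(pmin(pmax(round(a), 1), 14))

  ## assemble tables ----------------------------------------------------------
  sst <- truth$sst_base - truth$sst_lat_slope * abs(fish$set_lat) +
    truth$sst_amp * cos(2 * pi * (fish$month - 0.5) / 12)
  samples <- tibble(
    fish_id = fish$fish_id, set_id = fish$set_id, region = fish$region,
    date = as.Date(sprintf("2010-%02d-%02d", fish$month, fish$day)),
    latitude = round(fish$set_lat, 3), longitude = round(fish$set_lon, 3),
    fork_length_cm = fl, length_binned = binned,
    whole_weight_kg = ifelse(runif(n) < truth$p_weight_obs | fec,
                             round(w_true, 1), NA_real_),
    sex = sex,
    gonad_weight_g = ifelse(runif(n) < truth$p_gw_obs | has_hist,
                            round(gw_true, 1), NA_real_),
    sst_c = round(sst, 2), age_years = age)
  samples <- validate_samples(samples)

  histology <- tibble(
    fish_id = fish$fish_id[has_hist],
    mago_stage = mago[has_hist], pof_stage = pof[has_hist],
    alpha_atresia = alpha[has_hist], beta_atresia = beta[has_hist],
    maturity_markers = markers[has_hist],
    capture_time = sprintf("%02d:%02d", floor(cap_hour[has_hist]),
                           floor((cap_hour[has_hist] %% 1) * 60)))
  dd <- as.data.frame(diam[has_hist, , drop = FALSE])
  names(dd) <- paste0("oocyte_diam_um_", 1:5)
  histology <- dplyr::bind_cols(histology, as_tibble(dd))

  true_class <- rep(NA_character_, n)
  true_class[has_hist] <- classify_histology(histology)$class_code

  latent <- tibble(
    fish_id = fish$fish_id, sex = sex, fork_length_cm = fl,
    whole_weight_true_kg = w_true, gi_true = gi_true,
    mature = ifelse(female, mature, NA),
    active = ifelse(female, active, NA),
    spawned_24h = ifelse(female, spawned24, NA),
    hours_since_spawn = ifelse(spawned24, hours_since, NA_real_),
    true_class = true_class,
    relative_fecundity_true = relfec, batch_fecundity_true = batch_true,
    u_set = fish$u_set)

  list(samples = samples, histology = histology, subsamples = subsamples,
       latent = latent, truth = truth)
}

#' Write a simulated population to CSV (+ truth sidecar)
#'
#' Writes `samples.csv`, `histology.csv`, `subsamples.csv`, the latent truth
#' `truth_latent.csv` and the generator parameters `truth.yaml`.
#'
#' @param sim Output of [simulate_population()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$samples[setdiff(names(sim$samples), "month")],
                   file.path(dir, "samples.csv"), na = "")
  readr::write_csv(sim$histology, file.path(dir, "histology.csv"), na = "")
  readr::write_csv(sim$subsamples, file.path(dir, "subsamples.csv"), na = "")
  readr::write_csv(sim$latent, file.path(dir, "truth_latent.csv"), na = "")
  tr <- unclass(sim$truth)
  tr$regions <- lapply(seq_len(nrow(tr$regions)),
                       function(i) as.list(tr$regions[i, ]))
  yaml::write_yaml(tr, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Simulate clustered Gaussian observations
#'
#' Minimal random-intercept testbed: `y = mu + u_set + e`,
#' `u_set ~ N(0, sd_set^2)`, `e ~ N(0, sd_resid^2)`; used to check that the
#' mixed-model machinery recovers a known between-set SD.
#'
#' @param n_sets,fish_per_set Design size.
#' @param sd_set,sd_resid,mu Truth.
#' @param seed Integer seed.
#' @return Tibble with `set_id`, `y`.
#' @export
simulate_clustered_gaussian <- function(n_sets = 200, fish_per_set = 10,
                                        sd_set = 1, sd_resid = 1, mu = 0,
                                        seed = 1L) {
  set.seed(seed)
  u <- rnorm(n_sets, 0, sd_set)
  tibble(
    set_id = rep(sprintf("S%04d", seq_len(n_sets)), each = fish_per_set),
    y = mu + rep(u, each = fish_per_set) +
      rnorm(n_sets * fish_per_set, 0, sd_resid))
}
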