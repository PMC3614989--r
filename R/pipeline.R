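# End-to-end orchestration: simulate or ingest -> classify -> metrics ->
# spawning/fecundity -> model selection -> annual fecundity -> report
# bundle. Every exclusion is logged with a reason code; no fish is silently
# dropped.

#' Default run configuration
#'
#' @return Named list (class `run_config`) understood by [run_all()]:
#'   simulate-or-ingest switch, truth overrides, latitude band and peak
#'   months for the spawning estimates, the female histology length
#'   threshold, candidate model lists per response, annual-fecundity
#'   options and the seed.
#' @export
default_run_config <- function() {
  structure(list(
    simulate = TRUE,
    truth_overrides = list(),
    samples_path = NULL, histology_path = NULL, subsamples_path = NULL,
    seed = 1L,
    lat_band = c(-25, -10),
    peak_months = c(10L, 11L, 12L),
    min_histology_fl = 70,
    bin_width_cm = 5,
    zone_boundary_lat = -25,
    spawn_hour = 0,
    pof_new_h = 4,
    gi_mature_females_only = TRUE,
    days_per_month = "calendar",      # or "fixed30"
    annual_fl_grid = seq(87, 106),
    models = list(
      sex_ratio = list(
        list(terms = list(fork_length_cm = 3, month = 2)),
        list(terms = list(fork_length_cm = 3)),
        list(terms = list())),
      spawning_fraction = list(
        list(terms = list(fork_length_cm = "linear", month = 2)),
        list(terms = list(fork_length_cm = "linear")),
        list(terms = list())),
      batch_fecundity = list(
        list(terms = list(fork_length_cm = 2, month = 2)),
        list(terms = list(fork_length_cm = "linear")),
        list(terms = list()))),
    out_dir = NULL), class = "run_config")
}

#' Validate a run configuration
#' @param config A `run_config` list.
#' @return The config, invisibly, or an error.
#' @export
validate_run_config <- function(config) {
  if (!isTRUE(config$simulate) &&
      (is.null(config$samples_path) || is.null(config$histology_path))) {
    stop("config must either set simulate: true or provide input paths",
         call. = FALSE)
  }
  stopifnot(length(config$lat_band) == 2,
            all(config$peak_months %in% 1:12),
            config$min_histology_fl > 0,
            config$days_per_month %in% c("calendar", "fixed30"))
  invisible(config)
}

days_schedule <- function(kind) {
  if (kind == "fixed30") setNames(rep(30, 12), as.character(1:12))
  else setNames(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31),
                as.character(1:12))
}

#' Run the full reproductive-dynamics analysis
#'
#' Stages: (1) simulate a population or read the three CSVs; (2) join and
#' classify histology for females at or above the length threshold;
#' (3) metrics: gonad index + screen, sex-ratio table, class frequencies,
#' oocyte diameters; (4) POF spawning estimates, annual (all months, in the
#' latitude band) and peak-season; (5) gravimetric batch and relative
#' fecundity; (6) AICc model selection per configured response; (7)
#' potential annual fecundity by fork length (model-based when the batch
#' and spawning-fraction fits succeed, otherwise empirical monthly means).
#' Deterministic given `config$seed`.
#'
#' @param config A [default_run_config()]-style list.
#' @return Report bundle: list with `data`, `exclusions`, `metrics`,
#'   `spawning`, `fecundity`, `model_tables`, `annual`, `log`, `config`.
#'   If `config$out_dir` is set, CSV/JSON artifacts are written there.
#' @export
run_all <- function(config = default_run_config()) {
  validate_run_config(config)
  set.seed(config$seed)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  ## stage: data -------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    truth <- default_truth(seed = config$seed)
    truth[names(config$truth_overrides)] <- config$truth_overrides
    sim <- simulate_population(truth, seed = config$seed)
    samples <- sim$samples; histology <- sim$histology
    subsamples <- sim$subsamples
    note("simulated %d fish in %d sets", nrow(samples), truth$n_sets)
  } else {
    samples <- read_samples(config$samples_path)
    histology <- read_histology(config$histology_path)
    subsamples <- if (!is.null(config$subsamples_path)) {
      read_subsamples(config$subsamples_path)
    } else NULL
    note("read %d fish", nrow(samples))
  }

  ## stage: classify ---------------------------------------------------------
  eligible <- histology$fish_id %in%
    samples$fish_id[samples$sex %in% "female" &
                      !is.na(samples$fork_length_cm) &
                      samples$fork_length_cm >= config$min_histology_fl]
  if (any(!eligible)) {
    note("%d histology rows outside the female >= %g cm selection",
         sum(!eligible), config$min_histology_fl)
  }
  classified <- classify_histology(histology[eligible, ])
  data <- join_records(samples, classified, subsamples)
  exclusions <- bind_rows(
    tibble(fish_id = samples$fish_id[!samples$sex %in% c("female", "male")],
           reason = "unknown_sex"),
    tibble(fish_id = histology$fish_id[!eligible],
           reason = "histology_outside_selection"),
    tibble(fish_id = data$fish_id[!is.na(data$class_code) &
                                    data$class_code == "unclassifiable"],
           reason = "unclassifiable_histology"))
  n_uncls <- sum(exclusions$reason == "unclassifiable_histology")
  if (n_uncls) note("%d unclassifiable histology combinations", n_uncls)

  ## stage: metrics ----------------------------------------------------------
  gi_rows <- if (config$gi_mature_females_only) {
    (data$sex == "male") | (!is.na(data$mature) & data$mature)
  } else !is.na(data$gonad_weight_g)
  gi_tab <- data %>%
    filter(gi_rows & !is.na(.data$gonad_weight_g)) %>%
    mutate(gi = gonad_index(.data$gonad_weight_g, .data$fork_length_cm),
           gi_zone = gi_maturity_screen(.data$gi)) %>%
    select("fish_id", "sex", "month", "longitude", "gi", "gi_zone")
  metrics <- list(
    gi = gi_tab,
    sex_ratio = sex_ratio_table(samples, config$bin_width_cm),
    sex_ratio_by_month = sex_ratio_table(samples, config$bin_width_cm,
                                         by_month = TRUE),
    class_frequencies = class_frequencies(
      filter(data, !is.na(.data$class_code)), config$zone_boundary_lat),
    oocyte_diameter = {
      d <- ovary_mean_diameters(data)
      tibble(fish_id = data$fish_id, mean_diam_um = d)[!is.na(d), ]
    })

  ## stage: spawning ---------------------------------------------------------
  spawning <- list(
    annual = spawning_fraction(data, lat_band = config$lat_band),
    peak = spawning_fraction(data, lat_band = config$lat_band,
                             months = config$peak_months))
  diel <- diel_consistency(
    filter(data, !is.na(.data$pof_stage) & !is.na(.data$capture_time)),
    spawn_hour = config$spawn_hour, new_h = config$pof_new_h)
  spawning$diel_agreement <- attr(diel, "agreement_rate")

  ## stage: fecundity --------------------------------------------------------
  fecundity <- NULL
  if (!is.null(subsamples) && nrow(subsamples)) {
    fecundity <- batch_fecundity_table(subsamples, samples)
    note("batch fecundity for %d fish, mean relative fecundity %.1f /g",
         nrow(fecundity),
         mean(fecundity$relative_fecundity, na.rm = TRUE))
  }

  ## stage: model selection --------------------------------------------------
  model_data <- list(
    sex_ratio = samples %>%
      filter(.data$sex %in% c("female", "male"),
             !is.na(.data$fork_length_cm)) %>%
      mutate(is_male = as.integer(.data$sex == "male")),
    spawning_fraction = data %>%
      filter(!is.na(.data$mature) & .data$mature,
             .data$latitude >= min(config$lat_band),
             .data$latitude <= max(config$lat_band)) %>%
      mutate(pof01 = as.integer(.data$pof_stage %in%
                                  c("new", "lt12h", "h12_24"))),
    batch_fecundity = if (!is.null(fecundity)) {
      mutate(fecundity, batch_millions = .data$batch_fecundity / 1e6)
    } else tibble())
  responses <- c(sex_ratio = "is_male", spawning_fraction = "pof01",
                 batch_fecundity = "batch_millions")
  families <- c(sex_ratio = "binomial_logit",
                spawning_fraction = "binomial_logit",
                batch_fecundity = "gaussian_identity")
  model_tables <- list()
  fits_kept <- list()
  for (resp in names(config$models)) {
    dat <- model_data[[resp]]
    fits <- list()
    for (m in config$models[[resp]]) {
      spec <- model_spec(responses[[resp]], families[[resp]],
                         terms = m$terms,
                         random_set = if (is.null(m$random_set)) "set_id"
                         else m$random_set)
      f <- tryCatch(fit_model(spec, dat), error = function(e) {
        note("model '%s' for %s failed: %s", spec$label, resp,
             conditionMessage(e))
        NULL
      })
      if (!is.null(f)) fits <- c(fits, list(f))
    }
    model_tables[[resp]] <- if (length(fits)) rank_models(fits) else tibble()
    fits_kept[[resp]] <- fits
  }

  ## stage: potential annual fecundity ---------------------------------------
  days <- days_schedule(config$days_per_month)
  annual <- tryCatch(
    annual_fecundity_by_length(
      fits_kept$batch_fecundity, fits_kept$spawning_fraction,
      model_tables, model_data, config$annual_fl_grid, days),
    error = function(e) {
      note("annual fecundity surface: %s", conditionMessage(e))
      NULL
    })
  if (is.null(annual)) {
    annual <- tryCatch({
      a <- annual_fecundity_empirical(data, fecundity, days)
      note("annual fecundity computed from empirical monthly means")
      a
    }, error = function(e) {
      note("annual fecundity unavailable: %s", conditionMessage(e))
      NULL
    })
  }

  bundle <- list(data = data, exclusions = exclusions, metrics = metrics,
                 spawning = spawning, fecundity = fecundity,
                 model_tables = model_tables, annual = annual,
                 log = log, config = config)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# Model-based annual fecundity: best batch and spawning-fraction fits
# predicted over a fork-length x month grid, integrated with days-in-month.
annual_fecundity_by_length <- function(batch_fits, frac_fits, model_tables,
                                       model_data, fl_grid, days) {
  pick_best <- function(fits, tab) {
    if (!length(fits)) stop("no fitted models", call. = FALSE)
    fits[[which.max(vapply(
      fits, function(f) f$spec$label == tab$model[1], TRUE))]]
  }
  bf <- pick_best(batch_fits, model_tables$batch_fecundity)
  ff <- pick_best(frac_fits, model_tables$spawning_fraction)
  if (!("month" %in% names(bf$spec$terms)) ||
      !("month" %in% names(ff$spec$terms))) {
    stop("best fits lack a month term; cannot build monthly schedules",
         call. = FALSE)
  }
  months <- sort(unique(model_data$spawning_fraction$month))
  grid <- tidyr::expand_grid(fork_length_cm = fl_grid, month = months)
  b <- pmax(predict(bf, grid), 0) * 1e6
  f <- pmin(pmax(predict(ff, grid), 0), 1)
  to_mat <- function(v) {
    m <- matrix(v, nrow = length(fl_grid), byrow = TRUE,
                dimnames = list(NULL, as.character(months)))
    m
  }
  # expand_grid varies month fastest within each fl
  bm <- to_mat(b); fm <- to_mat(f)
  paf <- potential_annual_fecundity(bm, fm, days[as.character(months)])
  list(method = "model",
       by_length = tibble(fork_length_cm = fl_grid, annual = paf$annual),
       monthly = paf$monthly, months = months)
}

# Fallback: empirical monthly mean batch (overall mean where a month has no
# estimate) times the observed monthly POF fraction.
annual_fecundity_empirical <- function(data, fecundity, days) {
  if (is.null(fecundity) || !nrow(fecundity)) {
    stop("no fecundity estimates available", call. = FALSE)
  }
  mature <- filter(data, !is.na(.data$mature) & .data$mature)
  months <- sort(unique(mature$month))
  frac <- vapply(months, function(m) {
    x <- mature[mature$month == m, ]
    mean(x$pof_stage %in% c("new", "lt12h", "h12_24"))
  }, numeric(1))
  bm <- vapply(months, function(m) {
    b <- fecundity$batch_fecundity[fecundity$month == m]
    if (length(b)) mean(b) else NA_real_
  }, numeric(1))
  bm[is.na(bm)] <- mean(fecundity$batch_fecundity)
  names(bm) <- names(frac) <- as.character(months)
  paf <- potential_annual_fecundity(bm, frac, days[as.character(months)])
  list(method = "empirical", monthly = paf$monthly, annual = paf$annual,
       months = months)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$data[setdiff(names(bundle$data), "date")],
                   file.path(dir, "classified.csv"), na = "")
  readr::write_csv(bundle$exclusions, file.path(dir, "exclusions.csv"))
  readr::write_csv(bundle$metrics$sex_ratio, file.path(dir, "sex_ratio.csv"))
  readr::write_csv(bundle$metrics$class_frequencies,
                   file.path(dir, "class_frequencies.csv"))
  for (nm in names(bundle$model_tables)) {
    readr::write_csv(bundle$model_tables[[nm]],
                     file.path(dir, paste0("models_", nm, ".csv")))
  }
  if (!is.null(bundle$fecundity)) {
    readr::write_csv(bundle$fecundity, file.path(dir, "fecundity.csv"),
                     na = "")
  }
  if (!is.null(bundle$annual$by_length)) {
    readr::write_csv(bundle$annual$by_length,
                     file.path(dir, "annual_fecundity_by_length.csv"))
  }
  summary <- list(
    n_fish = nrow(bundle$data),
    spawning_annual = bundle$spawning$annual[
      c("n_mature", "n_with_pof", "fraction", "se", "interval_days")],
    spawning_peak = bundle$spawning$peak[
      c("n_mature", "n_with_pof", "fraction", "se", "interval_days")],
    diel_agreement = bundle$spawning$diel_agreement,
    mean_relative_fecundity = if (!is.null(bundle$fecundity)) {
      mean(bundle$fecundity$relative_fecundity, na.rm = TRUE)
    } else NULL,
    annual_method = bundle$annual$method,
    log = bundle$log)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
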