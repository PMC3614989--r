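# POF-method spawning fraction and interval, the 24-h POF degeneration
# clock, gravimetric batch fecundity and the potential-annual-fecundity
# integrator.

POF_PRESENT <- c("new", "lt12h", "h12_24")  # stages <= 24 h old

#' Daily spawning fraction and interval by the POF method
#'
#' Among mature females inside a latitude band (default 10-25 degS, bounds
#' inclusive) and an optional set of months, the spawning fraction is the
#' proportion whose ovaries carry postovulatory follicles of any stage less
#' than 24 hours old; its inverse is the mean spawning interval in days.
#'
#' @param classified Classified, joined table with `mature`, `pof_stage`,
#'   `latitude`, `month` and (unless `females_only = FALSE`) `sex`.
#' @param lat_band Length-2 numeric, latitude interval (negative south);
#'   default `c(-25, -10)`. `NULL` for no spatial filter.
#' @param months Integer months to retain (e.g. `10:12` for the peak
#'   season); `NULL` for all.
#' @param females_only Restrict to `sex == "female"` (default `TRUE`).
#' @return Object of class `spawning_estimate`: list with `n_mature`,
#'   `n_with_pof`, `fraction`, `se` (binomial), `interval_days` (`NA` when
#'   the fraction is 0), and the filters used.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   sex = "female", mature = TRUE, latitude = -15, month = 11,
#'   pof_stage = rep(c("lt12h", "absent"), c(9, 11)))
#' spawning_fraction(x)$interval_days # 1/0.45 = 2.22...
spawning_fraction <- function(classified, lat_band = c(-25, -10),
                              months = NULL, females_only = TRUE) {
  x <- as_tibble(classified)
  stopifnot(all(c("mature", "pof_stage", "latitude", "month") %in% names(x)))
  if (females_only && "sex" %in% names(x)) x <- x[x$sex %in% "female", ]
  if (!is.null(lat_band)) {
    stopifnot(length(lat_band) == 2)
    lat_band <- sort(lat_band)
    x <- x[!is.na(x$latitude) &
             x$latitude >= lat_band[1] & x$latitude <= lat_band[2], ]
  }
  if (!is.null(months)) x <- x[x$month %in% months, ]
  x <- x[!is.na(x$mature) & x$mature & !is.na(x$pof_stage), ]
  n <- nrow(x)
  if (n == 0) stop("no mature females in the requested stratum", call. = FALSE)
  k <- sum(x$pof_stage %in% POF_PRESENT)
  f <- k / n
  structure(list(
    n_mature = n, n_with_pof = k, fraction = f,
    se = sqrt(f * (1 - f) / n),
    interval_days = if (f > 0) 1 / f else NA_real_,
    lat_band = lat_band, months = months), class = "spawning_estimate")
}

#' @export
print.spawning_estimate <- function(x, ...) {
  cat(sprintf(
    "POF-method spawning estimate: %d of %d mature females with POFs\n",
    x$n_with_pof, x$n_mature))
  cat(sprintf("  spawning fraction %.3f (SE %.3f), interval %s days\n",
              x$fraction, x$se,
              if (is.na(x$interval_days)) "undefined"
              else sprintf("%.1f", x$interval_days)))
  invisible(x)
}

#' Expected POF stage at a given time since spawning
#'
#' Piecewise degeneration clock over the ~24-hour POF resorption cycle:
#' `[0, new_h)` -> `"new"`, `[new_h, 12)` -> `"lt12h"`, `[12, 24)` ->
#' `"h12_24"`, and `>= 24` h -> `"absent"` (fully resorbed). The `new_h`
#' boundary (default 4 h) is a configuration constant; the published staging
#' criteria do not quantify it.
#'
#' @param hours_since_spawn Non-negative hours.
#' @param new_h Upper bound of the `"new"` stage, in `(0, 12]`.
#' @return Character vector of POF stages.
#' @export
expected_pof_stage <- function(hours_since_spawn, new_h = 4) {
  if (any(hours_since_spawn < 0, na.rm = TRUE)) {
    stop("hours_since_spawn must be non-negative", call. = FALSE)
  }
  stopifnot(new_h > 0, new_h <= 12)
  breaks <- c(0, new_h, 12, 24, Inf)
  stages <- c("new", "lt12h", "h12_24", "absent")
  stages[findInterval(hours_since_spawn, breaks, rightmost.closed = TRUE)]
}

#' Diel consistency of observed POF stages with a spawning hour
#'
#' For each fish with a capture time, computes hours elapsed since the
#' assumed population spawning hour (default midnight: spawning around
#' midnight and the early morning hours), the POF stage expected from the
#' degeneration clock at that elapsed time, and whether the observed stage
#' agrees. Fish observed with no POFs are consistent with any elapsed time
#' (they need not have spawned last night), so agreement is assessed only
#' where a POF is observed: an observed stage agrees when it matches the
#' expected stage at the elapsed time, and hydrated ovaries captured within
#' two hours of the spawning hour with `"new"` POFs are consistent
#' (spawning imminent or ongoing).
#'
#' @param records Tibble with `capture_time` (`"HH:MM"`), `pof_stage` and
#'   optionally `mago_stage`.
#' @param spawn_hour Assumed spawning hour, decimal hours (default 0).
#' @param new_h Passed to [expected_pof_stage()].
#' @return Tibble (one row per fish with a capture time) with
#'   `hours_since_spawn`, `expected_stage`, `observed_stage`, `consistent`;
#'   attributes `n_skipped` (missing capture time) and `agreement_rate`
#'   (over fish with POFs observed).
#' @export
diel_consistency <- function(records, spawn_hour = 0, new_h = 4) {
  x <- as_tibble(records)
  stopifnot(all(c("capture_time", "pof_stage") %in% names(x)))
  hrs <- parse_clock_time(x$capture_time)
  skipped <- sum(is.na(hrs))
  x <- x[!is.na(hrs), ]
  hrs <- hrs[!is.na(hrs)]
  since <- (hrs - spawn_hour) %% 24
  expected <- expected_pof_stage(since, new_h = new_h)
  observed <- x$pof_stage
  has_pof <- observed %in% POF_PRESENT
  imminent <- if ("mago_stage" %in% names(x)) {
    x$mago_stage %in% "hydrated" & since < 2 & observed %in% c("new", "absent")
  } else rep(FALSE, nrow(x))
  consistent <- !has_pof | observed == expected | imminent
  out <- tibble(fish_id = if ("fish_id" %in% names(x)) x$fish_id
                else as.character(seq_len(nrow(x))),
                capture_hour = hrs, hours_since_spawn = since,
                expected_stage = expected, observed_stage = observed,
                consistent = consistent)
  attr(out, "n_skipped") <- skipped
  attr(out, "agreement_rate") <-
    if (any(has_pof)) mean(consistent[has_pof]) else NA_real_
  out
}

#' Gravimetric batch fecundity for one fish
#'
#' Raises each lobe's subsample oocyte count to the lobe weight
#' (`count / subsample_weight x lobe_weight`) and sums over the available
#' lobes (one or two).
#'
#' @param subsamples Tibble of lobe subsamples for a single fish (`lobe`,
#'   `subsample_weight_g`, `oocyte_count`, `lobe_weight_g`).
#' @return List with `batch_fecundity` (oocytes), `lobes_used` and
#'   `single_lobe` flag.
#' @export
#' @examples
#' batch_fecundity(tibble::tibble(
#'   lobe = c("left", "right"), subsample_weight_g = c(0.06, 0.05),
#'   oocyte_count = c(120L, 100L), lobe_weight_g = c(300, 250)))
batch_fecundity <- function(subsamples) {
  x <- validate_subsamples(
    if (!"fish_id" %in% names(subsamples)) {
      dplyr::mutate(as_tibble(subsamples), fish_id = "fish")
    } else subsamples)
  if (length(unique(x$fish_id)) > 1) {
    stop("batch_fecundity() takes subsamples for a single fish; see ",
         "batch_fecundity_table()", call. = FALSE)
  }
  if (!nrow(x) || nrow(x) > 2) {
    stop("expected 1 or 2 lobe subsamples", call. = FALSE)
  }
  per_lobe <- x$oocyte_count / x$subsample_weight_g * x$lobe_weight_g
  list(batch_fecundity = sum(per_lobe), lobes_used = nrow(x),
       single_lobe = nrow(x) == 1)
}

#' Batch and relative fecundity for every fish in a subsample table
#'
#' @param subsamples Validated subsample tibble (any number of fish).
#' @param samples Optional samples tibble supplying `whole_weight_kg` and
#'   `month` for relative fecundity.
#' @return Tibble with one row per fish: `batch_fecundity`, `lobes_used`,
#'   `single_lobe`, and (when samples given) `relative_fecundity` (oocytes
#'   per g body weight; missing when weight unknown) and `month`.
#' @export
batch_fecundity_table <- function(subsamples, samples = NULL) {
  x <- validate_subsamples(subsamples)
  out <- x %>%
    group_by(.data$fish_id) %>%
    summarise(
      batch_fecundity = sum(.data$oocyte_count / .data$subsample_weight_g *
                              .data$lobe_weight_g),
      lobes_used = dplyr::n(), .groups = "drop") %>%
    mutate(single_lobe = .data$lobes_used == 1L)
  if (!is.null(samples)) {
    keep <- intersect(c("fish_id", "whole_weight_kg", "month",
                        "fork_length_cm", "age_years", "set_id"),
                      names(samples))
    out <- left_join(out, as_tibble(samples)[keep], by = "fish_id") %>%
      mutate(relative_fecundity = relative_batch_fecundity(
        .data$batch_fecundity, .data$whole_weight_kg))
  }
  out
}

#' Relative batch fecundity (oocytes per gram of body weight)
#'
#' @param batch_fecundity Oocyte count per batch.
#' @param whole_weight_kg Body weight (kg); missing gives a missing result.
#' @return Oocytes per gram.
#' @export
relative_batch_fecundity <- function(batch_fecundity, whole_weight_kg) {
  if (any(whole_weight_kg <= 0, na.rm = TRUE)) {
    stop("whole_weight_kg must be positive", call. = FALSE)
  }
  batch_fecundity / (whole_weight_kg * 1000)
}

#' Potential annual fecundity from monthly batch and spawning-fraction
#' schedules
#'
#' For an indeterminate spawner, potential fecundity in month `m` is
#' `batch_m x fraction_m x days_m` (spawnings per day times oocytes per
#' spawning, integrated over the month); the annual total is the sum across
#' months. Inputs may be vectors (one value per month) or matrices with one
#' row per grid point (e.g. a fork-length or age grid) and one column per
#' month, in which case the result is computed per grid point.
#'
#' @param batch_by_month Named numeric vector (names = months `"1"`..`"12"`)
#'   or matrix with month columns: oocytes per batch.
#' @param fraction_by_month Same shape: daily spawning fraction in `[0, 1]`.
#' @param days_per_month Named numeric vector of days per month covering the
#'   same months; default the calendar days of a non-leap year. Use
#'   `rep(30, 12)`-style input for a fixed-30-day convention.
#' @return List with `monthly` (tibble or matrix of monthly totals) and
#'   `annual` (scalar or vector over grid points).
#' @export
#' @examples
#' b <- setNames(rep(1e6, 12), 1:12)
#' f <- setNames(rep(0.5, 12), 1:12)
#' potential_annual_fecundity(b, f, setNames(rep(30, 12), 1:12))$annual
potential_annual_fecundity <- function(batch_by_month, fraction_by_month,
                                       days_per_month = NULL) {
  month_names <- function(x) if (is.matrix(x)) colnames(x) else names(x)
  mb <- month_names(batch_by_month)
  mf <- month_names(fraction_by_month)
  if (is.null(mb) || is.null(mf) || !setequal(mb, mf)) {
    stop("batch and fraction schedules must cover the same named months",
         call. = FALSE)
  }
  if (is.null(days_per_month)) {
    days_per_month <- setNames(
      c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31), as.character(1:12))
  }
  if (!all(mb %in% names(days_per_month))) {
    stop("days_per_month does not cover all months", call. = FALSE)
  }
  ord <- as.character(sort(as.integer(mb)))
  days <- days_per_month[ord]
  as_mat <- function(x) {
    if (is.matrix(x)) x[, ord, drop = FALSE]
    else matrix(x[ord], nrow = 1, dimnames = list(NULL, ord))
  }
  b <- as_mat(batch_by_month)
  f <- as_mat(fraction_by_month)
  if (!all(dim(b) == dim(f))) {
    stop("batch and fraction grids have different sizes", call. = FALSE)
  }
  if (any(f < 0 | f > 1, na.rm = TRUE)) {
    stop("spawning fractions must lie in [0, 1]", call. = FALSE)
  }
  monthly <- sweep(b * f, 2, days, `*`)
  annual <- rowSums(monthly)
  if (nrow(monthly) == 1) {
    list(monthly = tibble(month = as.integer(ord),
                          monthly_fecundity = unname(monthly[1, ])),
         annual = unname(annual))
  } else {
    list(monthly = monthly, annual = annual)
  }
}
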