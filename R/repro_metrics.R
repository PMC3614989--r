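# Gonad index, GI-based maturity screen, length/month sex-ratio tables and
# per-ovary mean oocyte diameter.

#' Gonad index
#'
#' `GI = GW / FL^3 x 10^4`, gonad weight in grams over fork length in cm
#' cubed. Dimensionless and invariant under geometric scaling of the fish
#' (doubling length and multiplying gonad weight by 8 leaves GI unchanged).
#'
#' @param gonad_weight_g Non-negative gonad weight (g).
#' @param fork_length_cm Positive fork length (cm).
#' @return Numeric GI, same length as the inputs.
#' @export
#' @examples
#' gonad_index(170, 100) # 1.7, the classical maturity reference level
gonad_index <- function(gonad_weight_g, fork_length_cm) {
  if (any(fork_length_cm <= 0, na.rm = TRUE)) {
    stop("fork_length_cm must be positive", call. = FALSE)
  }
  if (any(gonad_weight_g < 0, na.rm = TRUE)) {
    stop("gonad_weight_g must be non-negative", call. = FALSE)
  }
  gonad_weight_g / fork_length_cm^3 * 1e4
}

#' GI maturity screening zones
#'
#' Coarse screen only — histology remains authoritative. Females below
#' GI 0.38 were uniformly immature and above GI 0.86 uniformly mature in the
#' albacore data this pipeline was built around; in between the GI does not
#' separate the classes.
#'
#' @param gi Non-negative gonad index values.
#' @param immature_below,mature_above Zone thresholds (defaults 0.38, 0.86).
#' @return Character vector in `{immature_zone, ambiguous, mature_zone}`.
#' @export
gi_maturity_screen <- function(gi, immature_below = 0.38, mature_above = 0.86) {
  stopifnot(immature_below <= mature_above)
  out <- ifelse(gi < immature_below, "immature_zone",
                ifelse(gi > mature_above, "mature_zone", "ambiguous"))
  out[is.na(gi)] <- NA_character_
  out
}

#' Sex ratio by length bin (optionally by month)
#'
#' Half-open length bins `[lo, hi)` tile the observed fork-length range;
#' within each bin (and month, if requested) the proportion male is
#' `n_male / (n_male + n_female)`. Unknown-sex fish are excluded from the
#' ratio and reported in the `n_excluded` attribute.
#'
#' @param samples Samples tibble with `sex`, `fork_length_cm` and (if
#'   `by_month`) `month`.
#' @param bin_width_cm Positive bin width; default 5 cm, the coarsest
#'   resolution of the length records.
#' @param by_month If `TRUE`, tabulate per month; otherwise pooled
#'   (`month = NA`).
#' @return Tibble with `length_lo`, `length_hi`, `month`, `n_male`,
#'   `n_female`, `p_male` (missing when the bin is empty).
#' @export
sex_ratio_table <- function(samples, bin_width_cm = 5, by_month = FALSE) {
  if (!is.numeric(bin_width_cm) || bin_width_cm <= 0) {
    stop("bin_width_cm must be positive", call. = FALSE)
  }
  x <- as_tibble(samples)
  keep <- x$sex %in% c("female", "male") & !is.na(x$fork_length_cm)
  n_excluded <- sum(!keep)
  x <- x[keep, ]
  if (!nrow(x)) stop("no fish with known sex and length", call. = FALSE)
  lo <- floor(min(x$fork_length_cm) / bin_width_cm) * bin_width_cm
  hi <- floor(max(x$fork_length_cm) / bin_width_cm) * bin_width_cm
  starts <- seq(lo, hi, by = bin_width_cm)
  x$length_lo <- starts[findInterval(x$fork_length_cm, starts)]
  months <- if (by_month) sort(unique(x$month)) else NA_integer_
  if (!by_month) x$month <- NA_integer_
  grid <- tidyr::expand_grid(length_lo = starts, month = months)
  tally <- x %>%
    group_by(.data$length_lo, .data$month) %>%
    summarise(n_male = sum(.data$sex == "male"),
              n_female = sum(.data$sex == "female"), .groups = "drop")
  out <- left_join(grid, tally, by = c("length_lo", "month")) %>%
    mutate(across(c("n_male", "n_female"),
                  ~ifelse(is.na(.x), 0L, as.integer(.x))),
           length_hi = .data$length_lo + bin_width_cm,
           p_male = ifelse(.data$n_male + .data$n_female > 0,
                           .data$n_male / (.data$n_male + .data$n_female),
                           NA_real_)) %>%
    select("length_lo", "length_hi", "month", "n_male", "n_female", "p_male")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Mean oocyte diameter for one ovary
#'
#' Arithmetic mean of the measured diameters (typically five per ovary) of
#' the most advanced group of oocytes.
#'
#' @param diameters_um Numeric vector of 1-5 positive diameters (um).
#' @return Mean diameter in um.
#' @export
mean_oocyte_diameter <- function(diameters_um) {
  d <- diameters_um[!is.na(diameters_um)]
  if (!length(d)) stop("no oocyte diameter measurements", call. = FALSE)
  if (length(d) > 5) stop("at most 5 diameters per ovary", call. = FALSE)
  if (any(d <= 0)) stop("diameters must be positive", call. = FALSE)
  mean(d)
}

#' Per-ovary mean oocyte diameters from a histology table
#'
#' Convenience wrapper applying [mean_oocyte_diameter()] to the
#' `oocyte_diam_um_*` columns; rows with no measurements get `NA`.
#'
#' @param histology Histology tibble.
#' @return Numeric vector of per-row mean diameters (um).
#' @export
ovary_mean_diameters <- function(histology) {
  cols <- grep("^oocyte_diam_um_", names(histology), value = TRUE)
  if (!length(cols)) return(rep(NA_real_, nrow(histology)))
  m <- as.matrix(histology[cols])
  out <- rowMeans(m, na.rm = TRUE)
  out[!rowSums(!is.na(m))] <- NA_real_
  out
}
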