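# Shared record schemas, CSV readers with row-level validation, and the
# fish-level join used by every downstream stage.
#
# Conventions fixed here and used everywhere:
#   * latitude is decimal degrees, negative south (the 10-25 degS spawning
#     band is latitude in [-25, -10], bounds inclusive);
#   * longitude is decimal degrees east in [0, 360) so the study region does
#     not straddle the antimeridian;
#   * month (1-12), extracted from the sampling date, is the temporal unit of
#     all models;
#   * empty CSV cells are missing values; "." is the decimal separator.

SEX_LEVELS <- c("female", "male", "unknown")
MAGO_LEVELS <- c("unyolked", "early_yolked", "advanced_yolked",
                 "migratory_nucleus", "hydrated")
POF_LEVELS <- c("absent", "new", "lt12h", "h12_24")
ALPHA_LEVELS <- c("absent", "lt50", "ge50", "all100")
PRESENCE_LEVELS <- c("absent", "present")
LOBE_LEVELS <- c("left", "right")

#' Column levels used by the reproductive-biology tables
#'
#' Returns the controlled vocabularies for the categorical columns of the
#' sample, histology and lobe-subsample tables: sex, MAGO (most advanced
#' group of oocytes) stage, postovulatory-follicle (POF) age stage, alpha
#' atresia level, presence/absence fields and ovary lobe.
#'
#' @return Named list of character vectors.
#' @export
#' @examples
#' field_levels()$pof_stage
field_levels <- function() {
  list(sex = SEX_LEVELS, mago_stage = MAGO_LEVELS, pof_stage = POF_LEVELS,
       alpha_atresia = ALPHA_LEVELS, beta_atresia = PRESENCE_LEVELS,
       maturity_markers = PRESENCE_LEVELS, lobe = LOBE_LEVELS)
}

samples_cols <- function() {
  readr::cols(
    fish_id = readr::col_character(),
    set_id = readr::col_character(),
    region = readr::col_character(),
    date = readr::col_date(format = "%Y-%m-%d"),
    latitude = readr::col_double(),
    longitude = readr::col_double(),
    fork_length_cm = readr::col_double(),
    length_binned = readr::col_logical(),
    whole_weight_kg = readr::col_double(),
    sex = readr::col_character(),
    gonad_weight_g = readr::col_double(),
    sst_c = readr::col_double(),
    age_years = readr::col_integer()
  )
}

histology_cols <- function() {
  readr::cols(
    fish_id = readr::col_character(),
    mago_stage = readr::col_character(),
    pof_stage = readr::col_character(),
    alpha_atresia = readr::col_character(),
    beta_atresia = readr::col_character(),
    maturity_markers = readr::col_character(),
    capture_time = readr::col_character(),
    .default = readr::col_double()
  )
}

subsamples_cols <- function() {
  readr::cols(
    fish_id = readr::col_character(),
    lobe = readr::col_character(),
    subsample_weight_g = readr::col_double(),
    oocyte_count = readr::col_integer(),
    lobe_weight_g = readr::col_double()
  )
}

fail_rows <- function(bad, what) {
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf("invalid %s at row(s): %s", what,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
}

#' Read and validate a fish-sample table
#'
#' One row per sampled fish: identifiers (fish, fishing set, region), date,
#' position, fork length (cm), optional whole weight (kg), sex, optional
#' gonad weight (g), optional SST and age. A `month` column is derived from
#' the date. Validation is per row and never silently drops records.
#'
#' @param path Path to a UTF-8 CSV with the documented header.
#' @return A tibble with one row per input row.
#' @export
read_samples <- function(path) {
  stopifnot(file.exists(path))
  x <- readr::read_csv(path, col_types = samples_cols(),
                       na = c("", "NA"), progress = FALSE)
  validate_samples(x)
}

#' Validate an in-memory fish-sample table
#'
#' Applies the same row-level checks as [read_samples()] (sex levels, positive
#' fork length, latitude range, non-negative gonad weight, longitude wrapped
#' to `[0, 360)`) and derives the `month` column.
#'
#' @param x Data frame shaped like the samples CSV.
#' @return Validated tibble.
#' @export
validate_samples <- function(x) {
  x <- as_tibble(x)
  need <- c("fish_id", "set_id", "date", "latitude", "longitude",
            "fork_length_cm", "sex")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("samples table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  fail_rows(!is.na(x$sex) & !(x$sex %in% SEX_LEVELS), "sex level")
  fail_rows(!is.na(x$fork_length_cm) & x$fork_length_cm <= 0, "fork_length_cm")
  fail_rows(!is.na(x$latitude) & abs(x$latitude) > 90, "latitude")
  if (!is.null(x$gonad_weight_g)) {
    fail_rows(!is.na(x$gonad_weight_g) & x$gonad_weight_g < 0, "gonad_weight_g")
  }
  if (!("length_binned" %in% names(x))) x$length_binned <- FALSE
  x$length_binned[is.na(x$length_binned)] <- FALSE
  x$longitude <- x$longitude %% 360
  x$month <- as.integer(format(x$date, "%m"))
  x
}

#' Read and validate a histology table
#'
#' One row per fish with the five histological criteria (MAGO stage, POF
#' stage, alpha atresia, beta atresia, maturity markers), optional capture
#' time (`"HH:MM"` local) and up to five oocyte diameters (um) in columns
#' `oocyte_diam_um_1` .. `oocyte_diam_um_5`.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per input row.
#' @export
read_histology <- function(path) {
  stopifnot(file.exists(path))
  x <- readr::read_csv(path, col_types = histology_cols(),
                       na = c("", "NA"), progress = FALSE)
  validate_histology(x)
}

#' Validate an in-memory histology table
#' @param x Data frame shaped like the histology CSV.
#' @return Validated tibble.
#' @export
validate_histology <- function(x) {
  x <- as_tibble(x)
  chk <- list(mago_stage = MAGO_LEVELS, pof_stage = POF_LEVELS,
              alpha_atresia = ALPHA_LEVELS, beta_atresia = PRESENCE_LEVELS,
              maturity_markers = PRESENCE_LEVELS)
  for (nm in names(chk)) {
    if (!nm %in% names(x)) stop("histology table missing column: ", nm,
                                call. = FALSE)
    fail_rows(!is.na(x[[nm]]) & !(x[[nm]] %in% chk[[nm]]), nm)
  }
  diam <- grep("^oocyte_diam_um_", names(x), value = TRUE)
  for (nm in diam) fail_rows(!is.na(x[[nm]]) & x[[nm]] <= 0, nm)
  x
}

#' Read and validate an ovary-lobe subsample table
#'
#' One row per weighed ovary-lobe core subsample: fish id, lobe, subsample
#' weight (g, typically 0.05-0.09 g), count of migratory-nucleus/hydrated
#' oocytes in the subsample, and whole lobe weight (g).
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_subsamples <- function(path) {
  stopifnot(file.exists(path))
  x <- readr::read_csv(path, col_types = subsamples_cols(),
                       na = c("", "NA"), progress = FALSE)
  validate_subsamples(x)
}

#' Validate an in-memory lobe-subsample table
#' @param x Data frame shaped like the subsamples CSV.
#' @return Validated tibble.
#' @export
validate_subsamples <- function(x) {
  x <- as_tibble(x)
  need <- c("fish_id", "lobe", "subsample_weight_g", "oocyte_count",
            "lobe_weight_g")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("subsamples table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  fail_rows(!is.na(x$lobe) & !(x$lobe %in% LOBE_LEVELS), "lobe")
  fail_rows(!is.na(x$subsample_weight_g) & x$subsample_weight_g <= 0,
            "subsample_weight_g")
  fail_rows(!is.na(x$oocyte_count) & x$oocyte_count < 0, "oocyte_count")
  fail_rows(!is.na(x$lobe_weight_g) & x$lobe_weight_g <= 0, "lobe_weight_g")
  fail_rows(!is.na(x$subsample_weight_g) & !is.na(x$lobe_weight_g) &
              x$subsample_weight_g > x$lobe_weight_g,
            "subsample heavier than lobe")
  x
}

#' Join sample, histology and subsample tables on fish id
#'
#' Left join of histology onto samples: fish without a histology row are
#' retained with missing histology fields. Histology or subsample rows whose
#' fish id is absent from the sample table are reported as orphans (warning,
#' and returned in the `orphans` attribute) and excluded from the joined
#' table. Duplicate fish ids in the sample table are an error.
#'
#' @param samples Validated samples tibble.
#' @param histology Validated histology tibble, or `NULL`.
#' @param subsamples Validated subsamples tibble, or `NULL`; attached
#'   unmodified as the `subsamples` attribute for fecundity stages.
#' @return Joined tibble with attributes `orphans` (list of tibbles) and
#'   `subsamples`.
#' @export
join_records <- function(samples, histology = NULL, subsamples = NULL) {
  dup <- unique(samples$fish_id[duplicated(samples$fish_id)])
  if (length(dup)) {
    stop("duplicate fish_id in samples: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  orphans <- list()
  out <- as_tibble(samples)
  if (!is.null(histology)) {
    orphan_h <- histology[!histology$fish_id %in% samples$fish_id, ]
    if (nrow(orphan_h)) {
      warning(nrow(orphan_h), " histology row(s) with unmatched fish_id",
              call. = FALSE)
    }
    orphans$histology <- orphan_h
    out <- left_join(out, histology[histology$fish_id %in% samples$fish_id, ],
                     by = "fish_id")
  }
  if (!is.null(subsamples)) {
    orphan_s <- subsamples[!subsamples$fish_id %in% samples$fish_id, ]
    if (nrow(orphan_s)) {
      warning(nrow(orphan_s), " subsample row(s) with unmatched fish_id",
              call. = FALSE)
    }
    orphans$subsamples <- orphan_s
    subsamples <- subsamples[subsamples$fish_id %in% samples$fish_id, ]
  }
  attr(out, "orphans") <- orphans
  attr(out, "subsamples") <- subsamples
  out
}

#' Parse "HH:MM" capture times to decimal hours
#' @param x Character vector of local clock times.
#' @return Numeric hours in `[0, 24)`; `NA` where missing/unparseable.
#' @export
parse_clock_time <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  vapply(m, function(p) {
    if (length(p) != 3) return(NA_real_)
    h <- as.numeric(p[2]) + as.numeric(p[3]) / 60
    if (h >= 24) NA_real_ else h
  }, numeric(1))
}

#' Read a run configuration from YAML
#'
#' Fields mirror [default_run_config()]; unknown fields are an error so typos
#' do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  bad <- setdiff(names(cfg), names(base))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  base[names(cfg)] <- cfg
  validate_run_config(base)
}
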