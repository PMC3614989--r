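# Deterministic decision table mapping the five histological criteria to a
# reproductive development class, with maturity and activity flags.
#
# Classes: 1 immature, 2 developing, 3 spawning capable, 4 spawning,
# 5 regressing, 6a regressed 1, 6b regressed 2, 7 regenerating.
# Mature = {3, 4, 5, 6a, 6b, 7}; active = {3, 4}. Class 2 (developing,
# early-yolked oocytes only) is reported but treated as immature downstream.
#
# Precedence rules:
#   * Any POF stage forces class 4 (a POF is direct evidence of a spawning
#     event within ~24 h), whatever the atresia level.
#   * Migratory-nucleus or hydrated MAGO without POFs is class 4 only while
#     alpha atresia is < 50%; with >= 50% alpha atresia the combination is
#     outside the decision table and is returned as "unclassifiable".
#   * Advanced-yolked MAGO with >= 50% alpha atresia is class 5 on the alpha
#     criterion alone, whether or not beta atresia is recorded (the table
#     lists beta as present in that row; absence is tolerated and the class
#     still assigned).
#   * Maturity markers never exclude a class; they decide only between
#     regenerating (7) and immature/developing (1/2).

MATURE_CLASSES <- c("3", "4", "5", "6a", "6b", "7")
ACTIVE_CLASSES <- c("3", "4")

DEVELOPMENT_LABELS <- c(
  "1" = "immature", "2" = "developing", "3" = "spawning capable",
  "4" = "spawning", "5" = "regressing", "6a" = "regressed 1",
  "6b" = "regressed 2", "7" = "regenerating",
  "unclassifiable" = "unclassifiable")

classify_one <- function(mago, pof, alpha, beta, markers) {
  if (pof != "absent") return("4")
  if (mago %in% c("migratory_nucleus", "hydrated")) {
    if (alpha %in% c("absent", "lt50")) return("4")
    return("unclassifiable")
  }
  if (mago == "advanced_yolked") {
    if (alpha %in% c("absent", "lt50")) return("3")
    return("5")                       # alpha >= 50% (incl. 100%)
  }
  # unyolked / early_yolked from here
  if (alpha == "all100") return("6a")
  if (alpha %in% c("lt50", "ge50")) return("unclassifiable")
  if (beta == "present") return("6b")
  if (markers == "present") return("7")
  if (mago == "unyolked") "1" else "2"
}

#' Classify histology records into reproductive development classes
#'
#' Applies the histological decision table to every row: each combination of
#' MAGO stage, POF stage, alpha/beta atresia and maturity markers maps
#' deterministically to a class code (or `"unclassifiable"` for combinations
#' the table does not define, which are excluded from downstream
#' proportions). The procedure is total over the full
#' 5 x 4 x 4 x 2 x 2 = 320 criteria grid.
#'
#' @param histology Tibble with columns `mago_stage`, `pof_stage`,
#'   `alpha_atresia`, `beta_atresia`, `maturity_markers` (see
#'   [field_levels()]). Extra columns are passed through.
#' @return Input tibble plus `class_code`, `development_label`, `mature`,
#'   `active`. `mature`/`active` are `NA` for unclassifiable rows.
#' @export
#' @examples
#' classify_histology(tibble::tibble(
#'   mago_stage = "advanced_yolked", pof_stage = "absent",
#'   alpha_atresia = "lt50", beta_atresia = "present",
#'   maturity_markers = "absent"))
classify_histology <- function(histology) {
  x <- as_tibble(histology)
  crit <- c("mago_stage", "pof_stage", "alpha_atresia", "beta_atresia",
            "maturity_markers")
  for (nm in crit) {
    if (!nm %in% names(x)) stop("missing criterion field: ", nm, call. = FALSE)
    if (anyNA(x[[nm]])) stop("missing values in criterion field: ", nm,
                             call. = FALSE)
  }
  x <- validate_histology(x)
  code <- mapply(classify_one, x$mago_stage, x$pof_stage, x$alpha_atresia,
                 x$beta_atresia, x$maturity_markers, USE.NAMES = FALSE)
  x$class_code <- code
  x$development_label <- unname(DEVELOPMENT_LABELS[code])
  x$mature <- ifelse(code == "unclassifiable", NA, code %in% MATURE_CLASSES)
  x$active <- ifelse(code == "unclassifiable", NA, code %in% ACTIVE_CLASSES)
  x
}

#' Monthly frequencies of development classes among mature females
#'
#' Tallies classified records by month and latitude zone (north/south of a
#' boundary, default 25 degS) and returns the proportion of each mature
#' class within its group. Immature (1, 2) and unclassifiable records are
#' excluded from both numerator and denominator; groups with no mature fish
#' report `n_mature = 0` and missing proportions.
#'
#' @param classified Output of [classify_histology()] joined to samples, with
#'   `month` and `latitude` columns.
#' @param zone_boundary_lat Latitude (negative south) splitting the two
#'   zones; default -25.
#' @return Tibble with `month`, `zone`, `class_code`, `n_class`, `n_mature`,
#'   `proportion`.
#' @export
class_frequencies <- function(classified, zone_boundary_lat = -25) {
  x <- as_tibble(classified)
  stopifnot(all(c("class_code", "month", "latitude") %in% names(x)))
  x$zone <- ifelse(x$latitude >= zone_boundary_lat,
                   sprintf("north_of_%gS", abs(zone_boundary_lat)),
                   sprintf("south_of_%gS", abs(zone_boundary_lat)))
  mat <- x[x$class_code %in% MATURE_CLASSES, ]
  grid <- tidyr::expand_grid(
    month = sort(unique(x$month)), zone = sort(unique(x$zone)),
    class_code = MATURE_CLASSES)
  tally <- mat %>%
    count(.data$month, .data$zone, .data$class_code, name = "n_class")
  out <- left_join(grid, tally, by = c("month", "zone", "class_code")) %>%
    mutate(n_class = ifelse(is.na(.data$n_class), 0L, .data$n_class)) %>%
    group_by(.data$month, .data$zone) %>%
    mutate(n_mature = sum(.data$n_class),
           proportion = ifelse(.data$n_mature > 0,
                               .data$n_class / .data$n_mature, NA_real_)) %>%
    ungroup()
  out
}
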