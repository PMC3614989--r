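# Tiny deterministic dataset used in unit tests and documentation examples.
# Constructed (not simulated) so it covers every reproductive class, both
# sexes, all twelve months, and at least one fecundity-ready fish in each
# peak spawning month, with hand-checkable fecundity arithmetic.

#' Small deterministic example dataset (~50 fish)
#'
#' Returns the three analysis tables for a constructed population: males in
#' every month; immature, developing and every mature-class female; capture
#' times that exercise the diel POF checks; a two-lobe fecundity fish whose
#' gravimetric batch fecundity is 1,100,000 oocytes by hand
#' (120/0.06 x 300 + 100/0.05 x 250) on a 17.0 kg female; and a length/sex
#' spread giving female-biased small and male-biased large length bins.
#'
#' @return List of tibbles `samples`, `histology`, `subsamples`.
#' @export
#' @examples
#' fx <- fixture_small()
#' table(classify_histology(fx$histology)$class_code)
fixture_small <- function() {
  set_month <- function(id) as.integer(sub("FS", "", id))
  sets <- tibble(
    set_id = sprintf("FS%02d", 1:12),
    region = c("Tonga", "Fiji", "New Caledonia", "American Samoa",
               "New Zealand", "New Zealand", "French Polynesia",
               "Cook Islands", "Tonga", "Fiji", "New Caledonia",
               "American Samoa"),
    latitude = c(-18, -18, -20, -13, -32, -32, -17, -15, -19, -18, -21, -13),
    longitude = c(185, 178, 165, 190, 172, 172, 210, 198, 185, 178, 166, 190))

  mk <- function(fish_id, month, sex, fl, w = NA_real_, gw = NA_real_,
                 age = NA_integer_) {
    tibble(fish_id = fish_id, set_id = sprintf("FS%02d", month),
           fork_length_cm = fl, whole_weight_kg = w, sex = sex,
           gonad_weight_g = gw, age_years = as.integer(age))
  }

  samples <- bind_rows(
    # one male per month
    mk(sprintf("M%02d", 1:12), 1:12, "male", 88 + 1:12, gw = 150),
    # immature / developing females
    mk(sprintf("I%02d", 1:6), 1:6, "female", c(74, 75, 73, 76, 74, 75),
       gw = c(18, 20, 17, 22, 19, 20)),
    mk("I07", 7, "female", 76, gw = 35),
    # mature females covering every class
    mk("A01", 1, "female", 98, 18.2, 320),
    mk("A02", 1, "female", 100, 20.1, 380, age = 7),
    mk("A03", 2, "female", 96, gw = 160),
    mk("A04", 3, "female", 95, gw = 90),
    mk("A05", 4, "female", 97, gw = 85),
    mk("A06", 5, "female", 99, gw = 70),
    mk("A07", 6, "female", 101, gw = 75),
    mk("A08", 8, "female", 94, gw = 65),
    mk("A09", 9, "female", 93, gw = 60),
    mk("A10", 10, "female", 97, 17.8, 290, age = 6),
    mk("A11", 10, "female", 98, 17.5, 400),
    mk("A12", 10, "female", 98, 17.0, 550, age = 8),
    mk("A13", 11, "female", 99, 18.5, 350, age = 9),
    mk("A14", 11, "female", 95, 16.0, 300, age = 5),
    mk("A15", 12, "female", 96, gw = 280),
    mk("A16", 12, "female", 102, 19.0, 420, age = 10),
    # length/sex spread for the sex-ratio bins
    mk(sprintf("X%02d", 1:18), rep(1:6, 3),
       c("female", "female", "male", "female", "female", "male", "female",
         "male", "female", "male", "female", "female", "male", "male",
         "male", "male", "male", "male"),
       c(48, 52, 55, 57, 62, 64, 68, 72, 78, 82, 88, 92, 96, 100, 104, 108,
         112, 116)))

  samples <- samples %>%
    left_join(sets, by = "set_id") %>%
    mutate(date = as.Date(sprintf("2010-%02d-15", set_month(.data$set_id))),
           length_binned = FALSE, sst_c = NA_real_) %>%
    select("fish_id", "set_id", "region", "date", "latitude", "longitude",
           "fork_length_cm", "length_binned", "whole_weight_kg", "sex",
           "gonad_weight_g", "sst_c", "age_years")
  samples <- validate_samples(samples)

  h <- function(fish_id, mago, pof, alpha, beta, markers,
                time = NA_character_, diam = rep(NA_real_, 5)) {
    tibble(fish_id = fish_id, mago_stage = mago, pof_stage = pof,
           alpha_atresia = alpha, beta_atresia = beta,
           maturity_markers = markers, capture_time = time,
           oocyte_diam_um_1 = diam[1], oocyte_diam_um_2 = diam[2],
           oocyte_diam_um_3 = diam[3], oocyte_diam_um_4 = diam[4],
           oocyte_diam_um_5 = diam[5])
  }

  histology <- bind_rows(
    h(sprintf("I%02d", 1:6), "unyolked", "absent", "absent", "absent",
      "absent"),
    h("I07", "early_yolked", "absent", "absent", "absent", "absent"),
    h("A01", "advanced_yolked", "h12_24", "lt50", "present", "absent",
      "15:10"),
    h("A02", "hydrated", "absent", "absent", "absent", "absent", "23:30"),
    h("A03", "advanced_yolked", "absent", "ge50", "present", "present"),
    h("A04", "unyolked", "absent", "all100", "present", "present"),
    h("A05", "early_yolked", "absent", "absent", "present", "absent"),
    h("A06", "unyolked", "absent", "absent", "absent", "present"),
    h("A07", "early_yolked", "absent", "absent", "absent", "present"),
    h("A08", "unyolked", "absent", "absent", "absent", "present"),
    h("A09", "unyolked", "absent", "absent", "absent", "present"),
    h("A10", "advanced_yolked", "absent", "lt50", "present", "absent",
      "10:00", c(400, 420, 440, 460, 480)),
    h("A11", "hydrated", "new", "absent", "absent", "absent", "00:22"),
    h("A12", "hydrated", "absent", "absent", "absent", "absent", "22:45"),
    h("A13", "migratory_nucleus", "lt12h", "absent", "absent", "absent",
      "16:30", c(430, 450, 470, 490, 510)),
    h("A14", "migratory_nucleus", "absent", "absent", "absent", "absent",
      "15:00"),
    h("A15", "advanced_yolked", "absent", "absent", "absent", "absent",
      "09:15"),
    h("A16", "hydrated", "new", "absent", "absent", "absent", "23:55"))
  histology <- validate_histology(histology)

  subsamples <- validate_subsamples(tibble(
    fish_id = c("A02", "A02", "A12", "A12", "A14", "A16", "A16"),
    lobe = c("left", "right", "left", "right", "left", "left", "right"),
    subsample_weight_g = c(0.07, 0.06, 0.06, 0.05, 0.05, 0.08, 0.07),
    oocyte_count = c(180L, 150L, 120L, 100L, 110L, 200L, 170L),
    lobe_weight_g = c(190, 185, 300, 250, 200, 210, 205)))

  list(samples = samples, histology = histology, subsamples = subsamples)
}
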