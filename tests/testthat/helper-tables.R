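# Shared constructors for small in-memory tables.

# A classified mature-female table with k of n fish carrying <24 h POFs.
mature_pof_table <- function(n, k, month = 11, latitude = -15,
                             stage = "lt12h") {
  tibble::tibble(
    fish_id = sprintf("T%03d", seq_len(n)),
    sex = "female", mature = TRUE, latitude = latitude, month = month,
    pof_stage = rep(c(stage, "absent"), c(k, n - k)))
}

# Every cell of the 5 x 4 x 4 x 2 x 2 histological criteria grid.
criteria_grid <- function() {
  lv <- pelagifec::field_levels()
  tidyr::expand_grid(
    mago_stage = lv$mago_stage, pof_stage = lv$pof_stage,
    alpha_atresia = lv$alpha_atresia, beta_atresia = lv$beta_atresia,
    maturity_markers = lv$maturity_markers)
}

# The eight canonical decision-table rows, instantiated with their stated
# criteria, and the class each must map to.
golden_rows <- function() {
  tibble::tribble(
    ~class, ~mago_stage, ~pof_stage, ~alpha_atresia, ~beta_atresia,
    ~maturity_markers,
    "1", "unyolked", "absent", "absent", "absent", "absent",
    "2", "early_yolked", "absent", "absent", "absent", "absent",
    "3", "advanced_yolked", "absent", "lt50", "present", "absent",
    "4", "hydrated", "lt12h", "absent", "absent", "absent",
    "5", "advanced_yolked", "absent", "ge50", "present", "present",
    "6a", "unyolked", "absent", "all100", "present", "present",
    "6b", "early_yolked", "absent", "absent", "present", "present",
    "7", "early_yolked", "absent", "absent", "absent", "present")
}
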