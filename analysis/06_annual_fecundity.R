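#!/usr/bin/env Rscript
# Stage 6: potential annual fecundity by fork length and age.
#
# Predicts batch fecundity and daily spawning fraction over a length x month
# (and age x month) grid from the best supported models, multiplies them
# with days per month, and sums across months. For an indeterminate spawner
# this integrates the seasonal spawning schedule into eggs per year.

library(pelagifec)
suppressMessages(library(dplyr))

samples <- read_samples("results/data/samples.csv")
histology <- read_histology("results/data/histology.csv")
subsamples <- read_subsamples("results/data/subsamples.csv")
data <- join_records(samples, classify_histology(histology), subsamples)

mat <- data %>%
  filter(!is.na(mature) & mature, latitude >= -25, latitude <= -10) %>%
  mutate(pof01 = as.integer(pof_stage %in% c("new", "lt12h", "h12_24")))
fec <- batch_fecundity_table(subsamples, samples) %>%
  mutate(batch_millions = batch_fecundity / 1e6)

months <- as.character(1:12)
surface <- function(frac_fit, batch_fit, grid_var, grid_vals) {
  grid <- tidyr::expand_grid(val = grid_vals, month = 1:12)
  names(grid)[1] <- grid_var
  f <- matrix(predict(frac_fit, grid), nrow = length(grid_vals),
              byrow = TRUE, dimnames = list(NULL, months))
  b <- matrix(pmax(predict(batch_fit, grid), 0) * 1e6,
              nrow = length(grid_vals), byrow = TRUE,
              dimnames = list(NULL, months))
  potential_annual_fecundity(b, f)
}

## by fork length -------------------------------------------------------------
ff <- fit_model(model_spec("pof01", "binomial_logit",
                           list(fork_length_cm = "linear", month = 5)), mat)
bf <- suppressMessages(fit_model(
  model_spec("batch_millions", "gaussian_identity",
             list(fork_length_cm = 2, month = 3)), fec))
fl_grid <- 87:106
by_len <- surface(ff, bf, "fork_length_cm", fl_grid)
cat(sprintf("potential annual fecundity: %.1f million eggs at 87 cm, %.1f million at 106 cm\n",
            by_len$annual[1] / 1e6, by_len$annual[length(fl_grid)] / 1e6))

## by age ---------------------------------------------------------------------
mata <- filter(mat, !is.na(age_years))
feca <- filter(fec, !is.na(age_years))
ffa <- fit_model(model_spec("pof01", "binomial_logit",
                            list(age_years = "linear", month = 4)), mata)
bfa <- suppressMessages(fit_model(
  model_spec("batch_millions", "gaussian_identity",
             list(age_years = 2, month = 3)), feca))
age_grid <- 3:11
by_age <- surface(ffa, bfa, "age_years", age_grid)
cat(sprintf("                            %.1f million at age 3, %.1f million at age 11\n",
            by_age$annual[1] / 1e6, by_age$annual[length(age_grid)] / 1e6))

readr::write_csv(
  tibble::tibble(fork_length_cm = fl_grid, annual_fecundity = by_len$annual),
  "results/annual_fecundity_by_length.csv")
readr::write_csv(
  tibble::tibble(age_years = age_grid, annual_fecundity = by_age$annual),
  "results/annual_fecundity_by_age.csv")
cat("wrote results/annual_fecundity_by_{length,age}.csv\n")
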