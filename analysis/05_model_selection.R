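#!/usr/bin/env Rscript
# Stage 5: AICc model selection for sex ratio, spawning fraction and batch
# fecundity.
#
# Candidate sets follow the structures used for these responses in the
# field: additive combinations of fork length (linear or cubic spline),
# month (spline), latitude/longitude, and age where available, always with
# a random fishing-set intercept. Binomial-logit for the 0/1 responses,
# Gaussian for batch fecundity (in millions of oocytes).

library(pelagifec)
suppressMessages(library(dplyr))

samples <- read_samples("results/data/samples.csv")
histology <- read_histology("results/data/histology.csv")
subsamples <- read_subsamples("results/data/subsamples.csv")
data <- join_records(samples, classify_histology(histology), subsamples)

fit_set <- function(response, family, dat, term_sets) {
  fits <- lapply(term_sets, function(tt)
    suppressMessages(fit_model(model_spec(response, family, tt), dat)))
  rank_models(fits)
}

## sex ratio (probability of being male) ------------------------------------
sr_dat <- samples %>%
  filter(sex %in% c("female", "male"), !is.na(fork_length_cm)) %>%
  mutate(is_male = as.integer(sex == "male"))
sr_tab <- fit_set("is_male", "binomial_logit", sr_dat, list(
  list(fork_length_cm = 3, month = 2),
  list(fork_length_cm = 3),
  list(fork_length_cm = "linear", month = 2),
  list(month = 2),
  list()))
cat("sex ratio model ranking:\n")
print(select(sr_tab, model, aicc, delta_aicc, akaike_weight), width = 100)

## spawning fraction over mature females in the band -------------------------
mat <- data %>%
  filter(!is.na(mature) & mature, latitude >= -25, latitude <= -10) %>%
  mutate(pof01 = as.integer(pof_stage %in% c("new", "lt12h", "h12_24")))
sf_tab <- fit_set("pof01", "binomial_logit", mat, list(
  list(fork_length_cm = "linear", month = 5),
  list(fork_length_cm = "linear", month = 2),
  list(fork_length_cm = "linear", month = 2, latitude = "linear"),
  list(month = 4, latitude = "linear"),
  list(month = 2)))
cat("\nspawning fraction model ranking:\n")
print(select(sf_tab, model, aicc, delta_aicc, akaike_weight), width = 100)

## batch fecundity ------------------------------------------------------------
fec <- batch_fecundity_table(subsamples, samples) %>%
  mutate(batch_millions = batch_fecundity / 1e6)
bf_tab <- fit_set("batch_millions", "gaussian_identity", fec, list(
  list(fork_length_cm = 2, month = 3),
  list(fork_length_cm = "linear", month = 2),
  list(fork_length_cm = 2),
  list(month = 3),
  list()))
cat("\nbatch fecundity model ranking:\n")
print(select(bf_tab, model, aicc, delta_aicc, akaike_weight), width = 100)

readr::write_csv(sr_tab, "results/models_sex_ratio.csv")
readr::write_csv(sf_tab, "results/models_spawning_fraction.csv")
readr::write_csv(bf_tab, "results/models_batch_fecundity.csv")
cat("\nwrote results/models_*.csv\n")
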