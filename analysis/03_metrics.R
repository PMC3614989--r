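#!/usr/bin/env Rscript
# Stage 3: gonad index, sex ratios and oocyte diameters.

library(pelagifec)
suppressMessages(library(dplyr))

samples <- read_samples("results/data/samples.csv")
histology <- read_histology("results/data/histology.csv")
data <- join_records(samples, classify_histology(histology))

# gonad index for mature females and all males, with the screening zones
gi_tab <- data %>%
  filter((sex == "male" | (!is.na(mature) & mature)),
         !is.na(gonad_weight_g)) %>%
  mutate(gi = gonad_index(gonad_weight_g, fork_length_cm),
         gi_zone = gi_maturity_screen(gi)) %>%
  select(fish_id, sex, month, longitude, gi, gi_zone)
cat(sprintf("GI computed for %d fish; mature-female monthly means peak in %s\n",
            nrow(gi_tab),
            month.abb[with(gi_tab[gi_tab$sex == "female", ],
                           which.max(tapply(gi, month, mean)))]))

sr <- sex_ratio_table(samples, bin_width_cm = 5)
small <- sr[sr$length_hi <= 60 & sr$n_male + sr$n_female > 0, ]
large <- sr[sr$length_lo >= 95 & sr$n_male + sr$n_female > 0, ]
cat(sprintf("proportion male: %.2f below 60 cm, %.2f above 95 cm\n",
            sum(small$n_male) / sum(small$n_male + small$n_female),
            sum(large$n_male) / sum(large$n_male + large$n_female)))

diam <- ovary_mean_diameters(data)
cat(sprintf("mean oocyte diameters: %d ovaries, range %.0f-%.0f um\n",
            sum(!is.na(diam)), min(diam, na.rm = TRUE),
            max(diam, na.rm = TRUE)))

readr::write_csv(gi_tab, "results/gonad_index.csv")
readr::write_csv(sr, "results/sex_ratio.csv", na = "")
readr::write_csv(sex_ratio_table(samples, 5, by_month = TRUE),
                 "results/sex_ratio_by_month.csv", na = "")
cat("wrote results/gonad_index.csv, results/sex_ratio*.csv\n")
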