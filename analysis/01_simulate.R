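#!/usr/bin/env Rscript
# Stage 1: generate the study population.
#
# Simulates a set-clustered sampling programme (~3500 fish over 10 regions)
# under the default truth: maturity L50 87 cm, Oct-Dec spawning peak with a
# daily spawning fraction of 0.75 over mature females at 10-25 degS, and
# relative batch fecundity N(64.4, 24.7) truncated at zero. Writes the three
# analysis CSVs plus the latent-truth sidecar under results/data/.

library(pelagifec)

seed <- 2010L
sim <- simulate_population(default_truth(seed))
write_population(sim, "results/data")

cat(sprintf("simulated %d fish in %d sets (%d females, %d males)\n",
            nrow(sim$samples), sim$truth$n_sets,
            sum(sim$samples$sex == "female"),
            sum(sim$samples$sex == "male")))
cat(sprintf("histology for %d females >= %g cm FL; %d fecundity fish\n",
            nrow(sim$histology), sim$truth$hist_min_fl,
            length(unique(sim$subsamples$fish_id))))
cat("wrote results/data/{samples,histology,subsamples,truth_latent}.csv\n")
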