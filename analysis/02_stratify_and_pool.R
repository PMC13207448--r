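#!/usr/bin/env Rscript
# Stratify the simulated gradient fractions into light and heavy pools at
# the 1.7274 g/mL buoyant-density threshold and pool them (DNA-quantity
# weighting) into the four relative-abundance profiles the REF statistic
# consumes. Run analysis/01_simulate_experiment.R first.

library(sipref)

counts <- read_otu_table("results/sim/fraction_counts.tsv")
meta <- read_fraction_metadata("results/sim/fraction_metadata.csv")

strat <- stratify_fractions(meta)
cat("fraction pools (fraction 1 = densest):\n")
print(as.data.frame(strat[, c("sample_id", "fraction_index",
                              "buoyant_density", "dna_quantity", "pool")]),
      digits = 4)
cat(sprintf("heavy fractions: %d of %d\n",
            sum(strat$pool == "heavy"), nrow(strat)))

profiles <- build_profiles(counts, meta)
readr::write_tsv(profiles, "results/pooled_profiles.tsv")
cat("pooled profiles written to results/pooled_profiles.tsv\n")
cat("profile column sums (should all be 1):",
    round(colSums(as.matrix(profiles[, -1])), 12), "\n")
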