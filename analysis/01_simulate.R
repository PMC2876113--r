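#!/usr/bin/env Rscript
## Stage 1 — generate the study-shaped synthetic datasets.
##
## Emulates the five-site, two-region sampling design (153 flies; four
## Niayes sites plus Missira) with 10 microsatellite loci (5 X-linked,
## null alleles at four loci), a 738-bp COI alignment with 9 + 2 regional
## haplotypes and no sharing, and 10-landmark wing configurations.
## Everything downstream reads the files written here.

library(tsetsepop)

seed <- 20100525
cfg <- study_config()
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

panel <- simulate_microsat_panel(cfg, seed = seed)
write_genotypes(panel, "results/data/microsats.gen", "genepop")
write_genotypes(panel, "results/data/microsats.csv", "csv")

coi <- simulate_coi_panel(cfg, seed = seed + 1)
write_alignment(coi, "results/data/coi.fasta")

wings <- simulate_landmarks(cfg, seed = seed + 2)
write_landmarks(wings, "results/data/wings.tps", "tps")

cat("Simulated datasets (seed ", seed, "):\n", sep = "")
print(panel)
print(coi)
cat("wings:", dim(wings$coords)[1], "configurations of", wings$k,
    "landmarks\n")
cat("Sample sizes per site:\n")
print(table(panel$individuals$population, panel$individuals$sex))
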