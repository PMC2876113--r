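#!/usr/bin/env Rscript
## Stage 3 — F-statistics and genetic diversity.
##
## Weir-Cockerham f / theta / F with per-locus jackknife and overall
## bootstrap confidence intervals, hierarchical F-statistics over
## region > population, the four permutation tests, panmixia re-tested
## after dropping the QC-flagged loci, and the paired regional Wilcoxon
## comparison of gene diversity.

library(tsetsepop)

panel <- read_genotypes("results/data/microsats.gen", "genepop")
excl <- readLines("results/tables/exclusion_list.txt")
n_perm <- 10000

wc <- weir_cockerham(panel)
print(wc)
hier <- hierarchical_fstats(panel)
print(hier)

ci <- fstat_confidence_intervals(panel, "f", n_boot = 1000, seed = 31)
write.table(ci$per_locus, "results/tables/fis_per_locus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

t_f <- permutation_test(panel, "alleles_within_subsamples", n_perm = n_perm,
                        seed = 32)
t_st <- permutation_test(panel, "individuals_among_subsamples",
                         n_perm = n_perm, seed = 33)
t_sr <- permutation_test(panel, "individuals_within_region", n_perm = n_perm,
                         seed = 34, region = "Niayes")
t_rt <- permutation_test(panel, "subsamples_between_regions", n_perm = n_perm,
                         seed = 35)
cat(sprintf("F_IS: f = %.3f, P = %.4g\n", wc$f, t_f$p_value))
cat(sprintf("F_ST: theta = %.3f, P = %.4g\n", wc$theta, t_st$p_value))
cat(sprintf("F_SR = %.3f, P = %.4g (individuals within Niayes)\n",
            hier$F_SR, t_sr$p_value))
cat(sprintf("F_RT = %.3f, P = %.4g (subsamples between regions)\n",
            hier$F_RT, t_rt$p_value))

## panmixia re-tested without the artefact loci
clean <- exclude_loci(panel, excl)
wc_clean <- weir_cockerham(clean)
t_clean <- permutation_test(clean, "alleles_within_subsamples",
                            n_perm = n_perm, seed = 36)
cat(sprintf("Without %s: f = %.3f, P = %.4g\n",
            paste(excl, collapse = "/"), wc_clean$f, t_clean$p_value))

div <- nei_gene_diversity(panel)
regs <- unique(panel$individuals$region)
cmp <- compare_region_diversity(div, regs[1], regs[2])
cat(sprintf("Mean Hs %s = %.2f vs %s = %.2f; Wilcoxon P = %.4f\n",
            regs[1], mean(div$per_region[, regs[1]], na.rm = TRUE),
            regs[2], mean(div$per_region[, regs[2]], na.rm = TRUE),
            cmp$p_value))
write.table(round(div$per_population, 3), "results/tables/gene_diversity.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
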