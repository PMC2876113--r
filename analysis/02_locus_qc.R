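#!/usr/bin/env Rscript
## Stage 2 — locus diagnostics.
##
## Estimates per-locus null-allele frequencies from heterozygote deficit
## and observed blanks (within populations, so the Wahlund effect of the
## strong regional structure stays out of the estimates), tests whether
## blanks are rarer than the estimates imply, runs all pairwise linkage-disequilibrium permutation tests with
## the 0.9 major-allele filter, checks the count of significant LD tests
## against its binomial expectation, and writes the exclusion list used by
## the downstream intra-locus analyses.

library(tsetsepop)

panel <- read_genotypes("results/data/microsats.gen", "genepop")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

`%na%` <- function(a, b) if (is.null(a)) b else a
nulls <- lapply(panel$loci$name, function(l)
  brookfield2_null_frequency(panel, l, pooled = FALSE))
null_tab <- do.call(rbind, lapply(nulls, function(x)
  data.frame(locus = x$locus, p_n = round(x$p_n, 3),
             observed_blanks = x$observed_blanks,
             x_missing = round(x$x_missing_proportion %na% NA_real_, 3))))
write.table(null_tab, "results/tables/null_alleles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

blanks <- expected_blanks_test(panel, nulls)
cat(sprintf("Blanks: observed %d vs expected %.1f, one-sided P = %.4g\n",
            blanks$observed, blanks$expected, blanks$p_value))

ld <- ld_pairwise_tests(panel, n_perm = 1000, seed = 7)
write.table(ld$tests, "results/tables/ld_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (nrow(ld$excluded)) {
  cat("Excluded from LD testing:", paste(ld$excluded$locus, collapse = ", "),
      "\n")
}
n_sig <- sum(ld$tests$p_value <= 0.05)
p_global <- significant_count_binomial(n_sig, nrow(ld$tests))
cat(sprintf("LD: %d of %d pairs significant at 5%%; binomial P = %.4f\n",
            n_sig, nrow(ld$tests), p_global))

## loci with substantial estimated null frequency are excluded from the
## intra-locus demographic analyses downstream
excl <- null_tab$locus[!is.na(null_tab$p_n) & null_tab$p_n > 0.1]
writeLines(excl, "results/tables/exclusion_list.txt")
cat("Exclusion list:", if (length(excl)) paste(excl, collapse = ", ")
    else "(empty)", "\n")
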