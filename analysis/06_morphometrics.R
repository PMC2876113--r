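#!/usr/bin/env Rscript
## Stage 6 — wing geometric morphometrics.
##
## Generalized Procrustes alignment of the 10-landmark wing
## configurations, 16 partial-warp shape variables (including the uniform
## component), pairwise Mahalanobis distances with 1000-run permutation
## tests, and per-site reclassification scores.

library(tsetsepop)

wings <- read_landmarks("results/data/wings.tps", "tps")
g <- gpa(wings)
print(g)
sv <- partial_warps(g)
cat("Shape variables:", ncol(sv$scores), "per individual\n")

cva <- mahalanobis_cva(sv, n_perm = 1000, seed = 61)
write_distance_matrix(cva$d, "results/tables/mahalanobis.phylip")
write.table(round(cva$p_values, 4), "results/tables/mahalanobis_p.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
write.table(cva$reclassification, "results/tables/reclassification.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(cva$reclassification)
cat("Pairs not significant at 5%:\n")
pv <- cva$p_values
idx <- which(upper.tri(pv) & pv > 0.05, arr.ind = TRUE)
if (nrow(idx)) {
  for (r in seq_len(nrow(idx))) {
    cat("  ", rownames(pv)[idx[r, 1]], "-", colnames(pv)[idx[r, 2]],
        sprintf("(P = %.3f)\n", pv[idx[r, , drop = FALSE]]))
  }
} else cat("  none\n")
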