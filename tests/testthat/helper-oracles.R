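## Independent oracles, written from the definitional formulas with plain
## loops: a naive Weir-Cockerham evaluation, an Ewens-sampling-formula
## conditional enumeration, and a brute-force mean pairwise difference.

## naive WC84 components, one allele at a time, straight from the printed
## estimator formulas
naive_wc <- function(a1, a2, grp) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]; grp <- as.character(grp[ok])
  pops <- unique(grp)
  r <- length(pops)
  n_i <- sapply(pops, function(g) sum(grp == g))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  alleles <- unique(c(a1, a2))
  A <- B <- C <- 0
  for (al in alleles) {
    p_i <- sapply(pops, function(g) {
      rows <- grp == g
      (sum(a1[rows] == al) + sum(a2[rows] == al)) / (2 * sum(rows))
    })
    h_i <- sapply(pops, function(g) {
      rows <- grp == g
      sum((a1[rows] == al) != (a2[rows] == al)) / sum(rows)
    })
    pbar <- sum(n_i * p_i) / sum(n_i)
    hbar <- sum(n_i * h_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  list(theta = A / (A + B + C), f = 1 - C / (B + C),
       F = 1 - C / (A + B + C))
}

## all partitions of n into exactly k parts (each a non-increasing vector)
partitions_nk <- function(n, k, maxpart = n) {
  if (k == 1) {
    if (n <= maxpart) return(list(n)) else return(list())
  }
  out <- list()
  for (first in seq(min(maxpart, n - k + 1), ceiling(n / k))) {
    for (rest in partitions_nk(n - first, k - 1, first)) {
      out[[length(out) + 1]] <- c(first, rest)
    }
  }
  out
}

## E[unbiased expected heterozygosity | n genes, exactly k alleles] under
## the Ewens sampling formula; the conditional law does not depend on theta.
## Weight of a partition lambda (counts a_j of parts of size j):
## n! / prod_j (j^a_j a_j!)
ewens_conditional_het <- function(n, k) {
  parts <- partitions_nk(n, k)
  wsum <- 0; hsum <- 0
  for (lam in parts) {
    aj <- table(lam)
    # log w = log n! - sum_j a_j log j - sum_j log a_j!
    logw <- lgamma(n + 1) -
      sum(as.numeric(aj) * log(as.numeric(names(aj)))) -
      sum(lgamma(as.numeric(aj) + 1))
    w <- exp(logw - lgamma(n + 1))   # common factor cancels in the ratio
    he <- n / (n - 1) * (1 - sum((lam / n)^2))
    wsum <- wsum + w
    hsum <- hsum + w * he
  }
  hsum / wsum
}

## brute-force mean pairwise Hamming difference by double loop
brute_force_k <- function(seqs) {
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(mat[i, ] != mat[j, ])
    }
  }
  tot / (n * (n - 1) / 2)
}
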