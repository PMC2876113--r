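## Locus quality control: null-allele frequency estimation from heterozygote
## deficit and observed blanks, the expected-blanks exact binomial test,
## pairwise linkage-disequilibrium permutation tests with the 0.9
## major-allele filter, the significant-test-count binomial check, and Holm
## step-down correction.

#' Null-allele frequency from heterozygote deficit and blanks
#'
#' Fits the null-allele model in which a non-amplifying allele of frequency
#' p_n turns genotypes into blanks (two null genes) or apparent homozygotes
#' (one null gene). Given the expected visible heterozygosity He (from
#' apparent allele frequencies), the three observable categories have
#' probabilities het = He (1-p_n)^2, visible homozygote =
#' (1-He)(1-p_n)^2 + 2 p_n (1-p_n), blank = p_n^2; p_n is the maximum
#' likelihood solution using the observed blank count (the estimator that
#' uses non-amplifying individuals rather than deficit alone). Males are
#' excluded at X-linked loci; their missing-call proportion gives the
#' direct `x_missing_proportion` estimate instead.
#'
#' @param panel a [genotype_panel()].
#' @param locus locus name or index.
#' @param pooled if TRUE (default) the estimate pools individuals across
#'   populations; if FALSE it is computed within each population and
#'   combined by a sample-size-weighted mean, which avoids mistaking the
#'   Wahlund heterozygote deficit of a structured sample for null alleles.
#' @return object of class `null_allele_estimate`: `p_n`, method, observed
#'   and expected blank counts, per-sex usable sample sizes.
#' @export
brookfield2_null_frequency <- function(panel, locus, pooled = TRUE) {
  l <- if (is.character(locus)) match(locus, panel$loci$name) else locus
  if (is.na(l)) stop("unknown locus")
  if (!pooled) {
    pops <- unique(panel$individuals$population)
    ests <- lapply(pops, function(pp)
      brookfield2_null_frequency(
        subset_panel(panel, panel$individuals$population == pp), l,
        pooled = TRUE))
    w <- vapply(ests, function(x) x$n, 0)
    pn <- vapply(ests, function(x) x$p_n, 0)
    ok <- !is.na(pn)
    out <- ests[[which.max(w)]]
    out$p_n <- if (any(ok)) sum(w[ok] * pn[ok]) / sum(w[ok]) else NA_real_
    out$method <- "brookfield2_by_population"
    out$n <- sum(w)
    out$observed_blanks <- sum(vapply(ests, function(x) x$observed_blanks, 0L))
    out$per_population <- stats::setNames(pn, pops)
    return(out)
  }
  ind <- panel$individuals
  xl <- panel$loci$x_linked[l]
  use <- if (xl) ind$sex == "F" else rep(TRUE, nrow(ind))
  a1 <- panel$a1[use, l]; a2 <- panel$a2[use, l]
  n <- length(a1)
  blank <- is.na(a1) & is.na(a2)
  typed <- !blank
  if (!any(typed)) {
    # every genotype blank: the null is fixed; no data at all is undefined
    return(structure(list(locus = panel$loci$name[l],
                          p_n = if (n > 0) 1 else NA_real_,
                          method = "brookfield2", undefined = n == 0,
                          observed_blanks = sum(blank), n = n),
                     class = "null_allele_estimate"))
  }
  genes <- c(a1[typed], a2[typed])
  p <- table(genes) / length(genes)
  he <- 1 - sum(p^2)
  ho <- mean(a1[typed] != a2[typed])
  nh <- sum(a1[typed] != a2[typed]); nm <- sum(typed) - nh; nb <- sum(blank)
  if (all(blank)) {
    pn <- 1
  } else if (he <= 0) {
    pn <- if (nb > 0) sqrt(nb / n) else 0
  } else {
    negll <- function(r) {
      ph <- he * (1 - r)^2
      pm <- (1 - he) * (1 - r)^2 + 2 * r * (1 - r)
      pb <- r^2
      -(nh * log(max(ph, 1e-300)) + nm * log(max(pm, 1e-300)) +
          nb * log(max(pb, 1e-300)))
    }
    if (nb == 0 && ho >= he) {
      pn <- 0
    } else {
      pn <- stats::optimize(negll, c(1e-9, 1 - 1e-9))$minimum
      if (negll(0 + 1e-12) <= negll(pn)) pn <- 0
    }
  }
  pn <- min(max(pn, 0), 1)
  # direct estimate from male missing proportion at X loci
  xmiss <- NA_real_
  if (xl) {
    mrow <- ind$sex == "M"
    xmiss <- mean(is.na(panel$a1[mrow, l]) & is.na(panel$a2[mrow, l]))
  }
  structure(list(locus = panel$loci$name[l], p_n = pn,
                 method = "brookfield2", x_missing_proportion = xmiss,
                 observed_blanks = nb,
                 expected_blanks = n * pn^2,
                 he = he, ho = ho, n = n, undefined = FALSE),
            class = "null_allele_estimate")
}

#' Exact binomial test of observed versus expected blanks
#'
#' One-sided (H1: fewer blanks than expected) exact binomial test pooling
#' individuals over loci: each diploid cell contributes expected blank
#' probability p_n^2 and each hemizygous male X cell p_n, using the supplied
#' per-locus null-frequency estimates.
#'
#' @param panel a [genotype_panel()].
#' @param estimates list of [brookfield2_null_frequency()] results (one per
#'   locus to include).
#' @return list with observed blanks, expected blanks, pooled expected
#'   probability and the lower-tail exact binomial P.
#' @export
expected_blanks_test <- function(panel, estimates) {
  ind <- panel$individuals
  probs <- numeric(0); obs <- 0L
  for (est in estimates) {
    l <- match(est$locus, panel$loci$name)
    pn <- est$p_n
    if (is.na(pn)) next
    xl <- panel$loci$x_linked[l]
    for (i in seq_len(nrow(ind))) {
      hemi <- xl && ind$sex[i] == "M"
      probs <- c(probs, if (hemi) pn else pn^2)
      obs <- obs + (is.na(panel$a1[i, l]) && is.na(panel$a2[i, l]))
    }
  }
  n <- length(probs)
  pbar <- mean(probs)
  p <- if (n == 0 || pbar == 0) {
    if (obs == 0) 1 else 0
  } else {
    stats::pbinom(obs, n, pbar)
  }
  list(observed = as.integer(obs), expected = sum(probs), n_cells = n,
       pooled_prob = pbar, p_value = p)
}

#' Pairwise linkage-disequilibrium permutation tests
#'
#' For every pair of informative loci (major-allele frequency <= 0.9), the
#' genotype-association G statistic summed over subsamples is compared with
#' its permutation null obtained by shuffling one locus's genotypes among
#' individuals within each subsample (free recombination). Males are coded
#' pseudodiploid at X-linked loci.
#'
#' @param panel a [genotype_panel()].
#' @param n_perm permutations per pair.
#' @param seed integer seed.
#' @param max_major_freq exclusion threshold on the overall major-allele
#'   frequency (default 0.9).
#' @return list with `tests` (data.frame locus_a, locus_b, G, p_value) and
#'   `excluded` (data.frame locus, reason).
#' @export
ld_pairwise_tests <- function(panel, n_perm = 1000, seed = 1,
                              max_major_freq = 0.9) {
  set.seed(seed)
  md <- genotype_matrices(panel, "pseudodiploid")
  grp <- panel$individuals$population
  L <- nrow(panel$loci)
  major <- vapply(seq_len(L), function(l) {
    genes <- c(md$a1[, l], md$a2[, l])
    genes <- genes[!is.na(genes)]
    if (!length(genes)) return(1)
    max(table(genes)) / length(genes)
  }, 0)
  keep <- which(major <= max_major_freq)
  excluded <- data.frame(
    locus = panel$loci$name[setdiff(seq_len(L), keep)],
    reason = sprintf("major allele frequency %.3f > %.2f",
                     major[setdiff(seq_len(L), keep)], max_major_freq),
    stringsAsFactors = FALSE)
  if (length(keep) < 2) {
    return(list(tests = data.frame(), excluded = excluded,
                note = "fewer than 2 informative loci"))
  }
  pairs <- utils::combn(keep, 2)
  res <- data.frame(locus_a = panel$loci$name[pairs[1, ]],
                    locus_b = panel$loci$name[pairs[2, ]],
                    G = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  ld_g <- function(g1a, g1b, g2a, g2b, grp) {
    s <- 0
    for (g in unique(grp)) {
      rows <- grp == g & !is.na(g1a) & !is.na(g2a)
      if (sum(rows) < 2) next
      t1 <- paste(pmin(g1a[rows], g1b[rows]), pmax(g1a[rows], g1b[rows]))
      t2 <- paste(pmin(g2a[rows], g2b[rows]), pmax(g2a[rows], g2b[rows]))
      tab <- table(t1, t2)
      if (nrow(tab) < 2 || ncol(tab) < 2) next
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      O <- as.numeric(tab); E <- as.numeric(E)
      s <- s + 2 * sum(O[O > 0] * log(O[O > 0] / E[O > 0]))
    }
    s
  }
  for (pp in seq_len(ncol(pairs))) {
    i <- pairs[1, pp]; j <- pairs[2, pp]
    obs <- ld_g(md$a1[, i], md$a2[, i], md$a1[, j], md$a2[, j], grp)
    reps <- replicate(n_perm, {
      ord <- seq_along(grp)
      for (g in unique(grp)) {
        rows <- which(grp == g)
        ord[rows] <- rows[sample.int(length(rows))]
      }
      ld_g(md$a1[, i], md$a2[, i], md$a1[ord, j], md$a2[ord, j], grp)
    })
    res$G[pp] <- obs
    res$p_value[pp] <- (sum(reps >= obs - 1e-12) + 1) / (n_perm + 1)
  }
  list(tests = res, excluded = excluded, n_perm = n_perm, seed = seed)
}

#' Exact binomial check on the count of significant tests
#'
#' Upper-tail exact binomial P for observing at least `n_significant`
#' rejections in `n_tests` tests when each rejects with probability `alpha`
#' under the null.
#'
#' @param n_significant number of tests significant at `alpha`.
#' @param n_tests total number of tests.
#' @param alpha nominal level (default 0.05).
#' @return the one-sided exact binomial P-value.
#' @export
significant_count_binomial <- function(n_significant, n_tests, alpha = 0.05) {
  stopifnot(n_significant >= 0, n_significant <= n_tests)
  if (n_significant == 0) return(1)
  stats::pbinom(n_significant - 1, n_tests, alpha, lower.tail = FALSE)
}

#' Holm step-down multiple-testing correction
#'
#' Sequential-rejective Bonferroni: monotone adjusted P-values via
#' `p.adjust(method = "holm")` and the rejection decisions at family level
#' `alpha`.
#'
#' @param p_values vector of P-values in (0, 1].
#' @param alpha family-wise level.
#' @return data.frame with raw `p`, `p_adjusted` and logical `reject`.
#' @export
holm_correction <- function(p_values, alpha = 0.05) {
  adj <- stats::p.adjust(p_values, method = "holm")
  data.frame(p = p_values, p_adjusted = adj, reject = adj <= alpha)
}
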