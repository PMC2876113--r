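## Effective population size: linkage-disequilibrium (Burrows composite)
## method and the heterozygote-excess method for dioecious populations.

#' Burrows composite disequilibrium for a pair of loci
#'
#' Phase-free composite digenic disequilibrium per allele pair from
#' genotype dosages: Delta_AB = n/(n-1) * (mean(X_A * X_B)/2 - 2 p_A p_B),
#' where X is the 0/1/2 allele dosage (the n/(n-1) factor is the standard
#' small-sample correction), and the correlation
#' r = Delta / sqrt((p(1-p) + D_A)(q(1-q) + D_B)) with D_A, D_B the
#' within-locus Hardy-Weinberg disequilibria (so |r| reaches 1 at complete
#' association). Males are taken pseudodiploid at X-linked loci.
#'
#' @param panel a [genotype_panel()].
#' @param locus_a,locus_b locus names or indices.
#' @param population population to use (default: all individuals).
#' @return data.frame per allele pair: allele_a, allele_b, delta, r, plus
#'   attribute `n` (individuals complete at both loci); a zero-row frame
#'   with a `reason` attribute when a locus is monomorphic or data are
#'   insufficient.
#' @export
burrows_composite <- function(panel, locus_a, locus_b, population = NULL) {
  md <- genotype_matrices(panel, "pseudodiploid")
  la <- if (is.character(locus_a)) match(locus_a, panel$loci$name) else locus_a
  lb <- if (is.character(locus_b)) match(locus_b, panel$loci$name) else locus_b
  rows <- if (is.null(population)) seq_len(nrow(panel$individuals)) else
    which(panel$individuals$population == population)
  a1 <- md$a1[rows, la]; a2 <- md$a2[rows, la]
  b1 <- md$a1[rows, lb]; b2 <- md$a2[rows, lb]
  ok <- !is.na(a1) & !is.na(b1)
  a1 <- a1[ok]; a2 <- a2[ok]; b1 <- b1[ok]; b2 <- b2[ok]
  n <- length(a1)
  skipped <- function(why) {
    structure(data.frame(allele_a = integer(), allele_b = integer(),
                         delta = numeric(), r = numeric()),
              reason = why, n = n)
  }
  if (n < 2) return(skipped("fewer than 2 complete individuals"))
  al_a <- sort(unique(c(a1, a2))); al_b <- sort(unique(c(b1, b2)))
  if (length(al_a) < 2 || length(al_b) < 2) {
    return(skipped("monomorphic locus in pair"))
  }
  res <- expand.grid(allele_a = al_a, allele_b = al_b)
  res$delta <- NA_real_; res$r <- NA_real_
  for (i in seq_len(nrow(res))) {
    xa <- (a1 == res$allele_a[i]) + (a2 == res$allele_a[i])
    xb <- (b1 == res$allele_b[i]) + (b2 == res$allele_b[i])
    p <- mean(xa) / 2; q <- mean(xb) / 2
    delta <- (mean(xa * xb) / 2 - 2 * p * q) * n / (n - 1)
    da <- mean(xa == 2) - p^2
    db <- mean(xb == 2) - q^2
    denom <- (p * (1 - p) + da) * (q * (1 - q) + db)
    res$delta[i] <- delta
    # the small-sample factor can push |r| past its attainable bound of 1
    res$r[i] <- if (denom > 0) max(-1, min(1, delta / sqrt(denom))) else NA_real_
  }
  attr(res, "n") <- n
  res
}

#' Linkage-disequilibrium effective size
#'
#' Squared Burrows correlations are averaged over allele pairs within each
#' locus pair, then arithmetically over locus pairs, giving rbar2; with
#' S the harmonic mean of the pairwise-complete sample sizes,
#' Ne = 1 / (3 (rbar2 - 1/S)) (the drift expectation
#' E[r^2] = 1/S + 1/(3 Ne)). rbar2 <= 1/S is reported as an infinite
#' estimate rather than a negative one.
#'
#' @param panel a [genotype_panel()].
#' @param population population label (default: all individuals pooled).
#' @param exclude loci to drop (QC exclusion list).
#' @return object of class `ne_estimate` with fields `ne`, `rbar2`,
#'   `s_harmonic`, `n_pairs`, `method`, `infinite`.
#' @export
ld_ne <- function(panel, population = NULL, exclude = character()) {
  if (length(exclude)) panel <- exclude_loci(panel, exclude)
  L <- nrow(panel$loci)
  r2s <- c(); ns <- c()
  if (L >= 2) {
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        bc <- burrows_composite(panel, i, j, population)
        if (is.null(bc) || nrow(bc) == 0) next
        r2 <- mean(bc$r^2, na.rm = TRUE)
        if (is.nan(r2)) next
        r2s <- c(r2s, r2)
        ns <- c(ns, attr(bc, "n"))
      }
    }
  }
  if (length(r2s) < 1) {
    return(structure(list(ne = NA_real_, rbar2 = NA_real_,
                          s_harmonic = NA_real_, n_pairs = 0L,
                          method = "ld_burrows", infinite = FALSE,
                          undefined = TRUE, population = population),
                     class = "ne_estimate"))
  }
  rbar2 <- mean(r2s)
  s_h <- 1 / mean(1 / ns)
  denom <- 3 * (rbar2 - 1 / s_h)
  inf <- denom <= 0
  structure(list(ne = if (inf) Inf else 1 / denom,
                 rbar2 = rbar2, s_harmonic = s_h, n_pairs = length(r2s),
                 method = "ld_burrows", infinite = inf, undefined = FALSE,
                 population = population),
            class = "ne_estimate")
}

#' Heterozygote-excess effective size
#'
#' In a dioecious population the excess of heterozygotes over
#' Hardy-Weinberg expectation reflects the finite number of parents:
#' Ne = 1/(-2 F_IS) - F_IS/(1 + F_IS), evaluated with the Weir-Cockerham f
#' of the subsample. Only applicable when f < 0; otherwise the estimate is
#' undefined (never negative).
#'
#' @param panel a [genotype_panel()].
#' @param population population label (default: all individuals).
#' @param exclude loci to drop (QC exclusion list).
#' @return object of class `ne_estimate` with fields `ne`, `f_is`,
#'   `applicable`.
#' @export
het_excess_ne <- function(panel, population = NULL, exclude = character()) {
  if (length(exclude)) panel <- exclude_loci(panel, exclude)
  sub <- if (is.null(population)) panel else
    subset_panel(panel, panel$individuals$population == population)
  f <- weir_cockerham(sub)$f
  applicable <- !is.na(f) && f < 0
  ne <- if (applicable) 1 / (-2 * f) - f / (1 + f) else NA_real_
  structure(list(ne = ne, f_is = f, method = "het_excess",
                 applicable = applicable, population = population),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne [%s]%s: %s\n", x$method,
              if (!is.null(x$population)) paste0(" (", x$population, ")") else "",
              if (isTRUE(x$infinite)) "infinite" else format(x$ne)))
  invisible(x)
}
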