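## Weir-Cockerham (1984) variance-component F-statistics, hierarchical
## (nested ANOVA) F-statistics, permutation tests with the four
## randomisation schemes, jackknife/bootstrap confidence intervals, and
## Nei-Chesser unbiased gene diversity with the paired regional Wilcoxon
## comparison.
##
## X-linked loci follow the field convention: males are excluded (coded
## missing) for inbreeding-based quantities (f, Ho, Hs), and coded as
## pseudodiploid homozygotes for differentiation and linkage quantities.

## ---- WC84 variance components ----

## per-locus WC84 components for every allele, from a1/a2 matrices and a
## grouping factor; returns list(a, b, c) of per-allele component vectors.
wc_components_locus <- function(a1, a2, grp) {
  ok <- !is.na(a1) & !is.na(a2)
  grp <- factor(grp[ok])
  a1 <- a1[ok]; a2 <- a2[ok]
  r <- nlevels(grp)
  if (length(a1) == 0 || r == 0) return(NULL)
  gi <- as.integer(grp)
  n_i <- tabulate(gi, r)
  alleles <- sort(unique(c(a1, a2)))
  A <- length(alleles)
  nbar <- mean(n_i)
  n_c <- if (r > 1) (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1) else nbar
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  # per-group allele dose sums and heterozygote-carrier counts, r x A
  dose <- matrix(0, r, A)
  hetm <- matrix(0, r, A)
  for (ai in seq_len(A)) {
    dose[, ai] <- tabulate(gi[i1 == ai], r) + tabulate(gi[i2 == ai], r)
    hetm[, ai] <- tabulate(gi[(i1 == ai | i2 == ai) & i1 != i2], r)
  }
  p_i <- dose / (2 * n_i)
  h_i <- hetm / n_i
  pbar <- colSums(n_i * p_i) / (r * nbar)
  hbar <- colSums(n_i * h_i) / (r * nbar)
  s2 <- if (r > 1) {
    colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  } else {
    numeric(A)
  }
  av <- if (r > 1) {
    (nbar / n_c) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  } else {
    numeric(A)
  }
  bv <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cv <- hbar / 2
  list(a = av, b = bv, c = cv, alleles = alleles)
}

#' Weir-Cockerham F-statistics
#'
#' Multiallelic WC84 moment estimators f (F_IS), theta (F_ST) and F (F_IT)
#' from variance components a (among groups), b (among individuals within
#' groups) and c (within individuals). Components are summed over alleles
#' and loci; overall statistics are ratios of summed components, never means
#' of per-locus ratios. Missing genotypes are dropped locus-wise. f is
#' computed with males excluded at X-linked loci; theta and F with males
#' coded pseudodiploid, following the study convention.
#'
#' @param panel a [genotype_panel()].
#' @param grouping column of `panel$individuals` defining the subsamples
#'   ("population" or "region").
#' @return object of class `fstat_estimates`: per-locus and overall `f`,
#'   `theta`, `F`, plus the summed components.
#' @export
weir_cockerham <- function(panel, grouping = "population") {
  grp <- panel$individuals[[grouping]]
  md <- genotype_matrices(panel, "pseudodiploid")   # theta, F
  mf <- genotype_matrices(panel, "females_only_x")  # f
  L <- nrow(panel$loci)
  per <- data.frame(locus = panel$loci$name, f = NA_real_, theta = NA_real_,
                    F = NA_real_, stringsAsFactors = FALSE)
  sums_d <- c(a = 0, b = 0, c = 0)
  sums_f <- c(a = 0, b = 0, c = 0)
  for (l in seq_len(L)) {
    cd <- wc_components_locus(md$a1[, l], md$a2[, l], grp)
    cf <- wc_components_locus(mf$a1[, l], mf$a2[, l], grp)
    if (!is.null(cd)) {
      A <- sum(cd$a); B <- sum(cd$b); C <- sum(cd$c)
      if (A + B + C != 0) {
        per$theta[l] <- A / (A + B + C)
        per$F[l] <- 1 - C / (A + B + C)
        sums_d <- sums_d + c(A, B, C)
      }
    }
    if (!is.null(cf)) {
      B <- sum(cf$b); C <- sum(cf$c)
      if (B + C != 0) {
        per$f[l] <- 1 - C / (B + C)
        sums_f <- sums_f + c(sum(cf$a), B, C)
      }
    }
  }
  tot <- sum(sums_d)
  structure(list(
    per_locus = per,
    f = if (sums_f["b"] + sums_f["c"] != 0)
      unname(1 - sums_f["c"] / (sums_f["b"] + sums_f["c"])) else NA_real_,
    theta = if (tot != 0) unname(sums_d["a"] / tot) else NA_real_,
    F = if (tot != 0) unname(1 - sums_d["c"] / tot) else NA_real_,
    components = list(differentiation = sums_d, inbreeding = sums_f),
    grouping = grouping), class = "fstat_estimates")
}

#' @export
print.fstat_estimates <- function(x, ...) {
  cat("Weir-Cockerham estimates over", nrow(x$per_locus), "loci:\n")
  cat(sprintf("  f = %.4f  theta = %.4f  F = %.4f\n", x$f, x$theta, x$F))
  invisible(x)
}

## ---- hierarchical (nested ANOVA) components, Henderson method I ----

## y: response per observation; factors: list of nesting factors from
## coarsest to finest (observations are the implicit finest level).
## Returns variance components c(sigma2_level1, ..., sigma2_resid).
nested_varcomp <- function(y, factors) {
  N <- length(y)
  m <- length(factors)
  # uncrossed nested coding: relabel each level within its parent
  codes <- vector("list", m)
  key <- rep("", N)
  for (j in seq_len(m)) {
    key <- paste(key, as.character(factors[[j]]), sep = "\r")
    codes[[j]] <- factor(key)
  }
  Tj <- numeric(m + 1)
  gsizes <- vector("list", m)
  for (j in seq_len(m)) {
    s <- tapply(y, codes[[j]], sum)
    n <- tapply(rep(1, N), codes[[j]], sum)
    Tj[j] <- sum(s^2 / n)
    gsizes[[j]] <- n
  }
  T0 <- sum(y)^2 / N
  Tobs <- sum(y^2)
  g <- vapply(gsizes, length, 0L)
  # k[j, i]: coefficient of sigma2_i in E[T_j]; k0 for the total line
  kmat <- matrix(0, m + 1, m)   # rows: levels 0..m (0 = total)
  for (i in seq_len(m)) kmat[1, i] <- sum(gsizes[[i]]^2) / N
  for (j in seq_len(m)) {
    for (i in seq_len(m)) {
      if (i <= j) {
        kmat[j + 1, i] <- N
      } else {
        # sum over groups at level j of (sum of squared sizes of level-i
        # subgroups) / group size
        sub <- tapply(gsizes[[i]]^2, sub_parent(codes, i, j), sum)
        kmat[j + 1, i] <- sum(sub / gsizes[[j]])
      }
    }
  }
  SS <- c(Tj[seq_len(m)] - c(T0, Tj[seq_len(m - 1)])[seq_len(m)], Tobs - Tj[m])
  dfs <- c(g - c(1, g[seq_len(m - 1)])[seq_len(m)], N - g[m])
  # E[SS_j] = (coef of sigma_i) sigma2_i + df_j sigma2_e, triangular solve
  Cmat <- matrix(0, m + 1, m + 1)
  for (j in seq_len(m)) {
    Cmat[j, seq_len(m)] <- kmat[j + 1, ] - kmat[j, ]
    Cmat[j, m + 1] <- dfs[j]
  }
  Cmat[m + 1, m + 1] <- dfs[m + 1]
  comp <- solve(Cmat, SS)
  comp
}

## map level-i group sizes to their parent group at level j (j < i)
sub_parent <- function(codes, i, j) {
  # codes[[i]] levels are "\r"-joined keys; the parent key is the first
  # j components
  lev <- levels(codes[[i]])
  parts <- strsplit(lev, "\r", fixed = TRUE)
  vapply(parts, function(p) paste(p[seq_len(j + 1)], collapse = "\r"), "")
}

#' Hierarchical F-statistics (nested moment estimators)
#'
#' Variance components of allele-indicator responses over the nested levels
#' region > population > individual > gene (Henderson method I for
#' unbalanced nested designs), summed over alleles and loci, yield F_RT
#' (regions within total), F_SR (subsamples within regions), F_ST and F_IS.
#' Males are coded pseudodiploid at X-linked loci, as in the study's
#' differentiation analyses.
#'
#' @param panel a [genotype_panel()].
#' @param hierarchy character vector of grouping columns from coarsest to
#'   finest, default `c("region", "population")`.
#' @return object of class `hier_fstats` with the named statistics and the
#'   summed variance components.
#' @export
hierarchical_fstats <- function(panel, hierarchy = c("region", "population")) {
  md <- genotype_matrices(panel, "pseudodiploid")
  ind <- panel$individuals
  L <- nrow(panel$loci)
  m <- length(hierarchy) + 1   # + individual level
  comp_sum <- numeric(m + 1)
  for (l in seq_len(L)) {
    a1 <- md$a1[, l]; a2 <- md$a2[, l]
    ok <- !is.na(a1) & !is.na(a2)
    if (!any(ok)) next
    genes <- c(a1[ok], a2[ok])
    idx <- rep(which(ok), 2)
    facs <- c(lapply(hierarchy, function(h) ind[[h]][idx]),
              list(ind$id[idx]))
    for (al in sort(unique(genes))) {
      y <- as.numeric(genes == al)
      if (all(y == 1) || all(y == 0)) next
      comp_sum <- comp_sum + nested_varcomp(y, facs)
    }
  }
  tot <- sum(comp_sum)
  nm <- c(hierarchy, "individual", "gene")
  names(comp_sum) <- nm
  below <- rev(cumsum(rev(comp_sum)))  # component j + everything finer
  out <- list(
    components = comp_sum,
    F_RT = if ("region" %in% hierarchy) unname(comp_sum["region"] / tot) else NA_real_,
    F_SR = if (all(c("region", "population") %in% hierarchy))
      unname(comp_sum["population"] / below["population"]) else NA_real_,
    F_ST = unname(sum(comp_sum[seq_along(hierarchy)]) / tot),
    F_IS = unname(comp_sum["individual"] / below["individual"]),
    F_IT = unname(sum(comp_sum[seq_len(m)]) / tot),
    hierarchy = hierarchy)
  class(out) <- "hier_fstats"
  out
}

#' @export
print.hier_fstats <- function(x, ...) {
  cat("Hierarchical F-statistics (", paste(x$hierarchy, collapse = " > "), "):\n")
  cat(sprintf("  F_RT = %.4f  F_SR = %.4f  F_ST = %.4f  F_IS = %.4f\n",
              x$F_RT, x$F_SR, x$F_ST, x$F_IS))
  invisible(x)
}

## ---- G statistic ----

## genotype-count likelihood-ratio G for one locus: genotypes x groups table
g_stat_locus <- function(a1, a2, grp) {
  ok <- !is.na(a1) & !is.na(a2)
  if (!any(ok)) return(0)
  geno <- paste(pmin(a1[ok], a2[ok]), pmax(a1[ok], a2[ok]))
  tab <- table(geno, factor(grp[ok]))
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  O <- as.numeric(tab)
  E <- as.numeric(E)
  2 * sum(O[O > 0] * log(O[O > 0] / E[O > 0]))
}

g_stat_panel <- function(a1, a2, grp) {
  s <- 0
  for (l in seq_len(ncol(a1))) s <- s + g_stat_locus(a1[, l], a2[, l], grp)
  s
}

## ---- permutation tests ----

#' Permutation tests for F-statistics
#'
#' The four randomisation schemes of the study design:
#' \describe{
#'   \item{alleles_within_subsamples}{statistic f; alleles shuffled between
#'     individuals within each subsample (tests local panmixia; one-sided
#'     toward homozygote excess, i.e. large f).}
#'   \item{individuals_among_subsamples}{statistic G summed over loci;
#'     individuals shuffled among all subsamples (tests F_ST).}
#'   \item{individuals_within_region}{statistic G restricted to one region's
#'     subsamples; individuals shuffled among them (tests F_SR).}
#'   \item{subsamples_between_regions}{statistic G on region totals; whole
#'     subsamples reassigned between regions (tests F_RT).}
#' }
#' P = (number of replicates >= observed + 1) / (n_perm + 1); ties count as
#' extreme.
#'
#' @param panel a [genotype_panel()].
#' @param scheme one of the four schemes above.
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @param region region whose subsamples are permuted for
#'   `individuals_within_region` (defaults to the region with most
#'   subsamples).
#' @return object of class `perm_test`: observed statistic, statistic kind,
#'   scheme, n_perm, seed, P.
#' @export
permutation_test <- function(panel,
                             scheme = c("alleles_within_subsamples",
                                        "individuals_among_subsamples",
                                        "individuals_within_region",
                                        "subsamples_between_regions"),
                             n_perm = 1000, seed = 1, region = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1)
  set.seed(seed)
  ind <- panel$individuals
  if (scheme == "alleles_within_subsamples") {
    mf <- genotype_matrices(panel, "females_only_x")
    obs <- wc_f_from_matrices(mf$a1, mf$a2, ind$population)
    reps <- replicate(n_perm, {
      sh <- shuffle_alleles_within(mf$a1, mf$a2, ind$population)
      wc_f_from_matrices(sh$a1, sh$a2, ind$population)
    })
    kind <- "f"
  } else if (scheme == "individuals_among_subsamples") {
    md <- genotype_matrices(panel, "pseudodiploid")
    obs <- g_stat_panel(md$a1, md$a2, ind$population)
    reps <- replicate(n_perm,
      g_stat_panel(md$a1, md$a2, sample(ind$population)))
    kind <- "G"
  } else if (scheme == "individuals_within_region") {
    md <- genotype_matrices(panel, "pseudodiploid")
    if (is.null(region)) {
      per_reg <- tapply(ind$population, ind$region,
                        function(p) length(unique(p)))
      region <- names(per_reg)[which.max(per_reg)]
    }
    sel <- ind$region == region
    if (length(unique(ind$population[sel])) < 2) {
      stop("region '", region, "' has fewer than 2 subsamples")
    }
    a1 <- md$a1[sel, , drop = FALSE]; a2 <- md$a2[sel, , drop = FALSE]
    pops <- ind$population[sel]
    obs <- g_stat_panel(a1, a2, pops)
    reps <- replicate(n_perm, g_stat_panel(a1, a2, sample(pops)))
    kind <- "G"
  } else {
    md <- genotype_matrices(panel, "pseudodiploid")
    pops <- unique(ind$population)
    reg_of <- ind$region[match(pops, ind$population)]
    if (length(pops) < 3) {
      stop("subsample permutation space degenerate: need >= 3 subsamples")
    }
    grp_obs <- ind$region
    obs <- g_stat_panel(md$a1, md$a2, grp_obs)
    reps <- replicate(n_perm, {
      newreg <- sample(reg_of)
      g_stat_panel(md$a1, md$a2, newreg[match(ind$population, pops)])
    })
    kind <- "G"
  }
  p <- (sum(reps >= obs - 1e-12) + 1) / (n_perm + 1)
  structure(list(observed = obs, kind = kind, scheme = scheme,
                 n_perm = n_perm, seed = seed, p_value = p),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test [%s], statistic %s = %.4f, P = %.4g (%d perms)\n",
              x$scheme, x$kind, x$observed, x$p_value, x$n_perm))
  invisible(x)
}

## fast overall f from matrices (already in the f view)
wc_f_from_matrices <- function(a1, a2, grp) {
  B <- 0; C <- 0
  for (l in seq_len(ncol(a1))) {
    cf <- wc_components_locus(a1[, l], a2[, l], grp)
    if (!is.null(cf)) { B <- B + sum(cf$b); C <- C + sum(cf$c) }
  }
  if (B + C == 0) return(NA_real_)
  1 - C / (B + C)
}

## shuffle the 2n gene array within each subsample at each locus,
## repairing into new individual genotypes
shuffle_alleles_within <- function(a1, a2, grp) {
  for (l in seq_len(ncol(a1))) {
    for (g in unique(grp)) {
      rows <- which(grp == g & !is.na(a1[, l]) & !is.na(a2[, l]))
      if (length(rows) < 2) next
      genes <- sample(c(a1[rows, l], a2[rows, l]))
      a1[rows, l] <- genes[seq_along(rows)]
      a2[rows, l] <- genes[seq_along(rows) + length(rows)]
    }
  }
  list(a1 = a1, a2 = a2)
}

## ---- confidence intervals ----

#' Jackknife / bootstrap confidence intervals for F-statistics
#'
#' Per-locus CIs by delete-one jackknife over populations (normal
#' approximation on pseudovalues); the overall CI by percentile bootstrap
#' over loci. Degenerate inputs (fewer than 3 populations, fewer than 2
#' loci, n_boot < 2) yield NA bounds rather than fabricated intervals.
#'
#' @param panel a [genotype_panel()].
#' @param statistic "f" or "theta".
#' @param n_boot bootstrap replicates over loci.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `per_locus` (data.frame locus, estimate, lower, upper)
#'   and `overall` (estimate, lower, upper).
#' @export
fstat_confidence_intervals <- function(panel, statistic = c("theta", "f"),
                                       n_boot = 1000, seed = 1, conf = 0.95) {
  statistic <- match.arg(statistic)
  set.seed(seed)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  pops <- unique(panel$individuals$population)
  est <- weir_cockerham(panel)
  per <- est$per_locus[, c("locus", statistic)]
  names(per)[2] <- "estimate"
  per$lower <- NA_real_; per$upper <- NA_real_
  if (length(pops) >= 3) {
    for (l in seq_len(nrow(per))) {
      sub <- subset_panel(panel, loci = l)
      full <- est$per_locus[[statistic]][l]
      if (is.na(full)) next
      jack <- vapply(pops, function(pp) {
        wj <- weir_cockerham(subset_panel(sub, panel$individuals$population != pp))
        wj$per_locus[[statistic]][1]
      }, 0)
      if (anyNA(jack)) next
      r <- length(pops)
      pseudo <- r * full - (r - 1) * jack
      se <- stats::sd(pseudo) / sqrt(r)
      per$lower[l] <- mean(pseudo) - z * se
      per$upper[l] <- mean(pseudo) + z * se
    }
  }
  overall <- c(estimate = est[[statistic]], lower = NA_real_, upper = NA_real_)
  L <- nrow(panel$loci)
  if (L >= 2 && n_boot >= 2) {
    boot <- vapply(seq_len(n_boot), function(b) {
      wb <- weir_cockerham(subset_panel(panel,
                                        loci = sample.int(L, L, replace = TRUE)))
      wb[[statistic]]
    }, 0)
    qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    overall["lower"] <- qs[1]; overall["upper"] <- qs[2]
  }
  list(per_locus = per, overall = overall, statistic = statistic,
       n_boot = n_boot, degenerate = L < 2 || n_boot < 2)
}

## ---- gene diversity ----

#' Nei-Chesser unbiased gene diversity per locus per population
#'
#' Hs = n/(n-1) * (1 - sum p^2 - Ho/(2n)) with n the number of typed
#' individuals, estimated on the females-only view at X-linked loci so that
#' observed heterozygosity is defined.
#'
#' @param panel a [genotype_panel()].
#' @return object of class `diversity_table`: matrix loci x populations of
#'   Hs plus region means.
#' @export
nei_gene_diversity <- function(panel) {
  mf <- genotype_matrices(panel, "females_only_x")
  ind <- panel$individuals
  pops <- unique(ind$population)
  L <- nrow(panel$loci)
  H <- matrix(NA_real_, L, length(pops),
              dimnames = list(panel$loci$name, pops))
  for (l in seq_len(L)) {
    for (pp in pops) {
      rows <- which(ind$population == pp & !is.na(mf$a1[, l]) & !is.na(mf$a2[, l]))
      n <- length(rows)
      if (n < 2) next
      genes <- c(mf$a1[rows, l], mf$a2[rows, l])
      p <- table(genes) / (2 * n)
      ho <- mean(mf$a1[rows, l] != mf$a2[rows, l])
      H[l, pp] <- n / (n - 1) * (1 - sum(p^2) - ho / (2 * n))
    }
  }
  region_of <- ind$region[match(pops, ind$population)]
  regions <- unique(region_of)
  Hreg <- vapply(regions, function(r)
    rowMeans(H[, region_of == r, drop = FALSE], na.rm = TRUE),
    numeric(L))
  structure(list(per_population = H,
                 per_region = matrix(Hreg, L, length(regions),
                                     dimnames = list(panel$loci$name, regions))),
            class = "diversity_table")
}

#' Compare regional gene diversity with a paired Wilcoxon test
#'
#' Two-sided Wilcoxon signed-rank test of per-locus mean Hs between two
#' regions, paired by locus; exact null when there are no ties and at most
#' 25 informative pairs, normal approximation with tie correction otherwise.
#'
#' @param div a [nei_gene_diversity()] result.
#' @param region_a,region_b region labels.
#' @return list with the P-value, per-locus differences and the test used.
#' @export
compare_region_diversity <- function(div, region_a, region_b) {
  ha <- div$per_region[, region_a]
  hb <- div$per_region[, region_b]
  keep <- !is.na(ha) & !is.na(hb)
  d <- ha[keep] - hb[keep]
  if (all(d == 0)) {
    return(list(p_value = 1, differences = d, method = "degenerate"))
  }
  exact <- sum(d != 0) <= 25 && !any(duplicated(abs(d[d != 0])))
  wt <- suppressWarnings(
    stats::wilcox.test(ha[keep], hb[keep], paired = TRUE,
                       alternative = "two.sided", exact = exact))
  list(p_value = wt$p.value, differences = d, method = wt$method)
}
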