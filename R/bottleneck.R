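## Heterozygosity-excess bottleneck detection: equilibrium H_EQ by
## conditional coalescent simulation (IAM/SMM/TPM), the one-tailed Wilcoxon
## summary across loci, and the detection-window arithmetic.

#' Equilibrium heterozygosity conditional on allele count
#'
#' Simulates coalescent samples of `n` genes under the mutation model
#' across an adaptively chosen scaled mutation rate, retains replicates
#' with exactly `k` alleles, and returns the mean unbiased expected
#' heterozygosity of the retained replicates. The scaled rate is calibrated
#' by bisection on the simulated mean allele count (for the IAM the exact
#' E[k] = sum theta/(theta+i-1) seeds the bracket).
#'
#' @param k observed allele count (2 <= k <= n).
#' @param n sample gene count (>= 4).
#' @param model "IAM", "SMM" or "TPM".
#' @param n_reps equilibrium replicates to retain.
#' @param seed integer seed.
#' @param tpm list(p_single, geom_q); the default geometric parameter 1/6
#'   gives a multistep-size variance of 30.
#' @param max_tries simulation budget before giving up.
#' @return list: `heq` (mean), `het` (retained replicate values), `theta`
#'   (calibrated rate), `tries`.
#' @export
heq_simulate <- function(k, n, model = c("IAM", "SMM", "TPM"),
                         n_reps = 1000, seed = 1,
                         tpm = list(p_single = 0.7, geom_q = 1 / 6),
                         max_tries = 200000) {
  model <- match.arg(model)
  stopifnot(k >= 2, k <= n, n >= 4)
  set.seed(seed)
  mcode <- match(model, c("IAM", "SMM", "TPM")) - 1L
  ewens_k <- function(theta) sum(theta / (theta + seq_len(n) - 1))
  # bracket theta so that E[k] straddles the target
  lo <- 0.01; hi <- 1
  while (ewens_k(hi) < k && hi < 1e6) hi <- hi * 2
  # IAM: bisection on the exact Ewens expectation; stepwise models create
  # homoplasy, so calibrate on simulated means starting from the IAM root
  if (model == "IAM") {
    for (it in 1:60) {
      mid <- sqrt(lo * hi)
      if (ewens_k(mid) < k) lo <- mid else hi <- mid
    }
    theta <- sqrt(lo * hi)
  } else {
    for (it in 1:12) {
      mid <- sqrt(lo * hi)
      mk <- coalescent_mean_k(n, mid, mcode, tpm$p_single, tpm$geom_q, 60L)
      if (mk < k) lo <- mid else hi <- mid
      if (hi / lo < 1.05) break
    }
    theta <- sqrt(lo * hi)
  }
  got <- coalescent_heq(n, k, theta, mcode, tpm$p_single, tpm$geom_q,
                        as.integer(n_reps), as.integer(max_tries))
  if (length(got$het) < n_reps && length(got$het) < max(20, n_reps / 5)) {
    stop(sprintf(
      "could not reach k = %d alleles for n = %d genes under %s within budget",
      k, n, model))
  }
  list(heq = mean(got$het), het = got$het, theta = theta,
       tries = got$tries, model = model)
}

#' Heterozygosity-excess bottleneck test for one population
#'
#' For each polymorphic locus the sample's unbiased expected heterozygosity
#' H_E is compared with the equilibrium expectation H_EQ for the same gene
#' count and allele number under the chosen mutation model; a recent
#' bottleneck inflates H_E relative to H_EQ because rare alleles are lost
#' faster than heterozygosity. Because the conditional distribution of H_E
#' given the allele count is strongly skewed, each locus's H_E is first
#' placed on its conditional equilibrium distribution (mid-rank quantile,
#' uniform under equilibrium); the centred quantiles are then summarised by
#' a one-tailed Wilcoxon signed-rank test (H1: H_E above its equilibrium
#' distribution, i.e. heterozygosity excess), exact when 25 or fewer
#' informative loci and no ties. Gene counts at X-linked loci count males
#' once.
#'
#' @param panel a [genotype_panel()].
#' @param population population label.
#' @param model "IAM", "SMM" or "TPM".
#' @param n_reps equilibrium replicates per locus.
#' @param seed integer seed.
#' @param tpm TPM parameters, see [heq_simulate()].
#' @return object of class `bottleneck_test`: per-locus table (k, n, H_E,
#'   H_EQ, sd, standardized difference), model, P-value.
#' @export
bottleneck_test <- function(panel, population, model = c("IAM", "SMM", "TPM"),
                            n_reps = 1000, seed = 1,
                            tpm = list(p_single = 0.7, geom_q = 1 / 6)) {
  model <- match.arg(model)
  sub <- subset_panel(panel, panel$individuals$population == population)
  L <- nrow(sub$loci)
  per <- data.frame(locus = sub$loci$name, k = NA_integer_, n = NA_integer_,
                    he = NA_real_, heq = NA_real_, sd_heq = NA_real_,
                    std_diff = NA_real_, stringsAsFactors = FALSE)
  per$quantile <- NA_real_
  for (l in seq_len(L)) {
    genes <- c(sub$a1[, l], sub$a2[, l])
    genes <- genes[!is.na(genes)]
    n <- length(genes)
    k <- length(unique(genes))
    per$n[l] <- n; per$k[l] <- k
    if (k < 2 || n < 4) next
    p <- table(genes) / n
    per$he[l] <- n / (n - 1) * (1 - sum(p^2))
    sim <- heq_simulate(k, n, model, n_reps = n_reps,
                        seed = seed + l, tpm = tpm)
    per$heq[l] <- sim$heq
    per$sd_heq[l] <- stats::sd(sim$het)
    per$std_diff[l] <- (per$he[l] - per$heq[l]) /
      if (per$sd_heq[l] > 0) per$sd_heq[l] else NA_real_
    # mid-rank position of the observed H_E within its conditional
    # equilibrium distribution; uniform on (0, 1) under equilibrium
    m <- length(sim$het)
    per$quantile[l] <- (sum(sim$het < per$he[l]) +
                          0.5 * sum(sim$het == per$he[l]) + 0.5) / (m + 1)
  }
  use <- !is.na(per$he) & !is.na(per$heq)
  if (sum(use) < 4) stop("need at least 4 polymorphic loci for the Wilcoxon summary")
  # the conditional law of H_E given k is strongly skewed, so the signed
  # rank acts on the centred conditional quantiles (symmetric under
  # equilibrium), one-tailed toward heterozygosity excess
  d <- per$quantile[use] - 0.5
  exact <- sum(d != 0) <= 25 && !any(duplicated(abs(d[d != 0])))
  p <- suppressWarnings(
    stats::wilcox.test(d, alternative = "greater", exact = exact)$p.value)
  structure(list(population = population, model = model, per_locus = per,
                 p_value = p, n_reps = n_reps, seed = seed),
            class = "bottleneck_test")
}

#' @export
print.bottleneck_test <- function(x, ...) {
  cat(sprintf("bottleneck test [%s] %s: one-tailed Wilcoxon P = %.4g over %d loci\n",
              x$model, x$population, x$p_value,
              sum(!is.na(x$per_locus$heq))))
  invisible(x)
}

#' Bottleneck detection window
#'
#' The heterozygosity-excess signature is visible if the crash happened
#' between tau1 * 2 Ne_pb and tau2 * 2 Ne_pb generations before sampling,
#' where Ne_pb is the post-bottleneck effective size (defaults tau1 = 0.1,
#' tau2 = 2.5 for panels of about 10 loci and 10-30 individuals).
#'
#' @param ne_pb post-bottleneck effective size (> 0).
#' @param tau1,tau2 window coefficients.
#' @return list with `lower`, `upper` (generations before sampling) and the
#'   inputs.
#' @export
detection_window <- function(ne_pb, tau1 = 0.1, tau2 = 2.5) {
  stopifnot(ne_pb > 0, tau1 > 0, tau2 > tau1)
  list(lower = tau1 * 2 * ne_pb, upper = tau2 * 2 * ne_pb,
       ne_pb = ne_pb, tau1 = tau1, tau2 = tau2)
}
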