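---
title: "Multi-marker population structure analysis for tsetse control planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-marker population structure analysis for tsetse control planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsetsepop)
```

## The question the package answers

Whether a tsetse (*Glossina*) infestation should be *suppressed* (kept below
the disease-transmission threshold) or *eradicated* (removed once and for
all) hinges on whether the target populations are genetically isolated from
their neighbours: an isolated population, once eliminated, is unlikely to be
re-founded by immigrants. `tsetsepop` implements the analysis chain used to
answer that question from three independent marker systems — nuclear
microsatellites, mitochondrial COI sequences, and wing geometric
morphometrics — for a two-level sampling design (trapping sites nested in
regions), together with a synthetic-data generator that emulates such a
design so every stage can be exercised and calibrated without field data.

## Microsatellite model and estimators

Genotypes live in a `genotype_panel`: diploid allele-size calls with sex,
site and region labels, and per-locus X-linkage. Tsetse males are hemizygous
at X-linked loci and are stored with a single allele; analyses convert on
demand. Following standard practice for this marker panel, males at X-linked
loci are *excluded* from inbreeding-type quantities (f, observed
heterozygosity, gene diversity) and coded as *homozygous pseudodiploids* for
differentiation and linkage quantities; allele frequencies count them once.

`weir_cockerham()` implements the multiallelic variance-component
estimators: per allele and locus the components a (among sites), b (among
individuals within sites) and c (within individuals) are accumulated and the
estimators are formed as ratios of summed components, never as means of
per-locus ratios; f = 1 − c/(b+c), θ = a/(a+b+c), F = 1 − c/(a+b+c).
`hierarchical_fstats()` extends this to region > site > individual > gene by
nested-ANOVA moment estimation (Henderson method I for unbalanced designs),
giving F_RT (regions in total), F_SR (sites within regions), F_ST and F_IS;
with a single region it reduces *exactly* to the two-level estimator (the
test suite checks equality to 1e-10).

Significance testing uses the four randomisation schemes appropriate to the
hierarchy: alleles between individuals within sites (statistic f, one-sided
toward homozygote excess — the direction in which genotyping artefacts and
inbreeding push the data; the opposite direction can be read from the same
null distribution), individuals among sites and individuals among the
focal region's sites (statistic G, the genotype-count likelihood-ratio
summed over loci), and whole sites between regions. Permutation P-values
follow the (hits + 1)/(n + 1) convention with ties counted as extreme, so P
is never 0 and tests on heavily tied statistics are conservative rather
than liberal. Confidence intervals follow the field's convention:
per-locus delete-one jackknife over sites (normal approximation on
pseudovalues — the classical software's choice is undocumented, and the
normal form is the usual default), overall percentile bootstrap over loci.

## Locus diagnostics

Null (non-amplifying) alleles inflate f. `brookfield2_null_frequency()`
estimates the null frequency from both the heterozygote deficit *and* the
observed blank genotypes: given the visible expected heterozygosity He, the
three observable categories (visible heterozygote, visible homozygote,
blank) have probabilities He(1−p)², (1−He)(1−p)² + 2p(1−p) and p², and p is
fitted by maximum likelihood. This is the "use the blanks" estimator: the
closed-form algebra of the classical implementation is not reproduced
verbatim, but the fitted model is the same and the estimator is validated
against the generator (true null frequency 0.2 recovered within ±0.1 across
seeds). The pooled expected blank count (p² per diploid cell, p per
hemizygous male cell) is compared with the observed count by a one-sided
exact binomial test (H1: fewer blanks than expected, which would argue
against nulls as the explanation).

Pairwise linkage disequilibrium uses the G statistic on joint genotype
tables summed over sites, with one locus's genotypes permuted within sites
(free recombination null). Loci with a major-allele frequency above 0.9
carry almost no information and are excluded before testing. The count of
significant pairs is itself tested against Binomial(n_tests, 0.05), upper
tail; the Holm step-down procedure is applied wherever a family of tests
feeds one decision.

## Effective size and bottleneck inference

`ld_ne()` uses the Burrows composite disequilibrium Δ (phase-free, with the
n/(n−1) small-sample factor) normalised by the Hardy-Weinberg-corrected
variances to an allelic correlation r, truncated to |r| ≤ 1. Squared
correlations are averaged over allele pairs within a locus pair, then
arithmetically over locus pairs, and inverted through the drift expectation
E[r²] ≈ 1/S + 1/(3Ne) with S the harmonic mean pairwise-complete sample
size (pairwise- rather than casewise-complete, the more data-efficient
choice). r̄² at or below 1/S is reported as an infinite estimate, never a
negative one. `het_excess_ne()` evaluates Ne = 1/(−2f) − f/(1+f) for
dioecious populations and is only applicable where f < 0.

`bottleneck_test()` compares each locus's unbiased expected heterozygosity
H_E with the equilibrium expectation H_EQ for the *same* gene count and
allele number: after a crash, rare alleles are lost faster than
heterozygosity, so H_E > H_EQ for a window of roughly 0.2 Ne to 5 Ne
generations (`detection_window()`). H_EQ comes from coalescent samples
simulated under IAM, SMM or TPM and retained conditional on the observed
allele count; the scaled mutation rate is calibrated by bisection (for the
IAM the exact Ewens expectation E[k] = Σ θ/(θ+i−1) seeds the bracket; for
the stepwise models the mean simulated allele count is used, since
homoplasy makes fewer distinct alleles per mutation). The TPM draws a
single ±1 step with probability 0.7 and otherwise a geometric multistep of
size 1 + Geometric(q); q = 1/6 makes the multistep-size variance exactly
(1−q)/q² = 30, the conventional setting. The coalescent sampler is
compiled code because conditioning on the allele count discards most
replicates and the calibration suites call it millions of times. Loci are
summarised by a one-tailed Wilcoxon signed-rank test (H1: H_E > H_EQ),
exact for 25 or fewer untied loci. The IAM conditional H_EQ is
cross-checked in the tests against an exact Ewens-sampling-formula
enumeration over partitions (whose conditional law is θ-free), and the
test's operating characteristics are verified by simulation: nominal size
at equilibrium, and ≥60% power at 10 loci for an in-window crash.

One calibration detail matters: conditional on the allele count, the
equilibrium distribution of H_E is strongly skewed, so a signed-rank test
on the raw differences H_E − H_EQ rejects at roughly twice the nominal
rate even at perfect equilibrium (the mean difference is zero but the
median is not). The summary therefore first places each locus's H_E on its
simulated conditional distribution — the mid-rank quantile, which is
uniform under equilibrium — and applies the one-tailed Wilcoxon to the
centred quantiles. The per-locus table still reports H_E, H_EQ, its SD and
the standardized difference.

## Distances, trees, and mitochondrial statistics

`chord_distance()` uses per-locus cos θ_l = Σ_a √(p_a q_a) and combines loci
as D = √((1/L) Σ 2(1 − cos θ_l)). Classical software differs in whether a
2/π prefactor is applied; both conventions are exposed (`prefactor =`,
default off) and both are tested. Neighbour joining is delegated to ape
(Saitou–Nei, standard Q-criterion) behind `neighbor_joining()`, with labels
sorted first so ties break deterministically and negative branch lengths
clamped to zero with a warning.

For COI alignments, sites containing N or a gap in any sequence are removed
alignment-wide before any statistic (the pairwise-deletion alternative is a
deliberate non-feature: the study design assumes a gap-free alignment).
Haplotype diversity uses the unbiased n/(n−1) estimator with its
second-moment sampling variance; K is the mean pairwise Hamming distance
(computed from haplotype frequencies, equal to the brute-force double loop
to 1e-12 in the tests) and Pi = K/L. The variance attached to K is the
total (sampling plus stochastic, no recombination) form
(3n(n+1)K + 2(n²+n+3)K²) / (11(n²−7n+6)) and the variance of Pi the
corresponding per-site form; the diversity point estimates are validated
against worked values, the variance formulas are documented choices.
Differentiation uses Hudson's statistics: F_ST = 1 − Hw/Hb from mean
pairwise differences within and between, H_ST = 1 − H_S/H_T from haplotype
diversities with sample-size weights for H_S and the unbiased pooled H_T,
and K*_ST = 1 − K*_S/K*_T with the log(1+K) correction and C(n_j, 2)
weights (the weighting used in the original derivation; implementations
vary in using n_j weights instead). P-values permute *sequences* between
localities, not haplotype classes. The haplotype network is a minimum
spanning tree on haplotype Hamming distances with edges above the
user-supplied connection limit removed (11 steps reproduces the 95%
parsimony limit for a 738-bp alignment); the parsimony-probability
computation of the limit itself is out of scope, the limit is an input.

## Wing morphometrics

`gpa()` performs classical generalized Procrustes analysis — centre, scale
to unit centroid size, rotate (rotation only; a reflected wing is a
digitisation error and shows up as a large residual, which is flagged
rather than silently absorbed) — iterating the consensus to convergence.
`partial_warps()` builds the thin-plate-spline bending-energy matrix of the
consensus, projects tangent-space residuals onto the principal warps (x and
y), and appends the uniform (affine) component as the orthonormal
complement of the nonuniform subspace within the tangent space, giving
2k − 4 variables (16 for 10 landmarks) that preserve the tangent-space
norm. `mahalanobis_cva()` computes pairwise Mahalanobis distances between
group means under the pooled within-group covariance (spectral
pseudo-inverse with a flag if the covariance is singular), permutes only
the two groups under comparison for each pairwise P, and reports
resubstitution reclassification by default — the convention of the era's
morphometric software; leave-one-out is available (`cross_validate = TRUE`)
and is what the no-signal calibration tests use, because resubstitution is
optimistically biased by construction.

## Integration

`mantel()` correlates the off-diagonal upper triangles of two labelled
distance matrices and permutes rows and columns of one simultaneously;
P is one-sided toward positive association, since the question is whether
the marker systems agree (the classical implementation does not document
its sidedness; one-sided concordance is the reading consistent with how
the results are interpreted). R² = r² is reported as the share of variance
in one distance matrix explained by the other. `run_pipeline()` chains all
stages — simulate, QC, F-statistics, effective sizes, bottleneck, tree,
mtDNA, morphometrics, Mantel — honouring the QC exclusion list downstream,
and writes a plain-text report; rerunning with the same config and seed
reproduces it.

## The synthetic-data generator

The generator is the package's test bed and defines the study conditions:

* **Microsatellites** (`simulate_microsat_panel()`): a hierarchical F-model.
  Ancestral allele frequencies are symmetric-Dirichlet; region frequencies
  are Dirichlet draws around them with concentration (1−F_RT)/F_RT, site
  frequencies around those with (1−F_SR)/F_SR — so the expected fixation
  index at each level *is* the target, which is what makes the
  recovery tests meaningful. The default `study_config()` uses F_RT = 0.12
  and F_SR = 0.07 with one site (Dakar Hann) given extra drift
  (`extra_f = 0.12`) to emulate its bottleneck-driven isolation, the
  published five-site sex-specific sample sizes (153 flies), 10 loci with 5
  X-linked, and null alleles at the four loci flagged as artefact-prone in
  the field data (frequencies 0.15–0.2, the range consistent with their
  reported heterozygote deficits). The F-model was chosen over a coalescent
  island model because the study reports F targets, not migration rates.
* **Wright–Fisher machinery** (`simulate_wright_fisher_locus()`,
  `simulate_population_panel()`): forward gene-pool simulation with IAM,
  SMM or TPM mutation, optionally starting from an equilibrium coalescent
  draw so that bottleneck scenarios need only the short post-crash phase;
  the multilocus individual-based variant generates the drift LD that the
  LD-Ne estimator measures.
* **COI** (`simulate_coi_panel()`): two regional haplotype clusters
  separated by 12 mutational steps (one more than the 11-step connection
  limit, so the network splits as in the field data), star-like
  within-region haplotypes, skewed per-site haplotype frequencies, and
  patched regional coverage so the *observed* haplotype counts match the
  design (9 + 2, no sharing).
* **Wings** (`simulate_landmarks()`): a unit-size decagon plus a
  region-level mean-shape offset (SD 0.015 Procrustes units, shared by the
  region's populations so that wing-shape divergence mirrors the genetic
  hierarchy and the shape-vs-genetics Mantel correlation is positive, as
  in real wings) plus a population offset (SD 0.010) and individual
  landmark noise (SD 0.025), then random rotation, translation and scale.
  The offset/noise ratio was calibrated once so that resubstitution
  reclassification lands in the low-to-mid 80s/70s percent band reported
  for real wings, and left alone.

What the generator does **not** emulate: genuine stepwise allele-frequency
spectra at the microsatellites (frequencies are exchangeable across allele
sizes, so size-based statistics beyond identity are not meaningful for the
F-model panel), stutter artefacts, within-region isolation by distance,
recombination, or allometric shape variation. Passing tests therefore show
that the estimators recover the structure the models encode, not that field
data meet those models' assumptions.

## Numerical choices and degenerate inputs

Monomorphic loci contribute zero variance components and are excluded from
ratio denominators only when all components vanish (avoiding 0/0). WC84
estimates are invariant to locus and site order. Permutation seeds are
explicit arguments everywhere and same-seed reruns are bit-identical.
Exact Wilcoxon nulls are used for ≤25 untied pairs, the tie-corrected
normal approximation otherwise. Jackknife CIs over identical sites have
zero width; too few sites (<3) or loci (<2), or n_boot < 2, yield NA bounds
flagged as degenerate rather than fabricated intervals. The bending-energy
eigenbasis treats eigenvalues below 1e-9 of the maximum as null space;
collinear landmark configurations are rejected. The LD-Ne |r| truncation at
1, the 1/S boundary (infinite estimates), and the het-excess f ≥ 0
inapplicability are all explicit flags, not silent clamps.

## Problem sizes used by the validation suites

The statistical suites run at the study's own scale: 30-individual sites,
5–10 loci with 8 alleles, 99-permutation tests over 400 null replicates for
the size checks; 20 seeds for F-target recovery; 50 seeds for LD-Ne
recovery (true N = 50, 10 loci, 30 sampled); 200 equilibrium and 50
bottlenecked replicates (10 loci, 150 retained equilibrium samples per
locus) for the bottleneck operating characteristics. These sizes keep the
whole suite in the tens of minutes on a single core while leaving the
Monte-Carlo error well inside the asserted tolerance bands.

## Known limitations

The hierarchical permutation scheme for regions permutes whole sites, so
with few sites the null distribution is coarse and P-values are
conservative (the study design itself has only five sites). The Multitest
"count of significant tests" check treats tests as independent, which LD
tests sharing loci are not. The Hudson H_S/K*_S weighting conventions vary
across classical software versions; the implemented weights are documented
above, and pairwise conclusions in the validation suites rest on the
permutation tests rather than the point values. Resubstitution
reclassification overstates separability; treat its percentages as
comparable to the classical reports, not as honest error rates.
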