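test_that("WC84 components equal the naive textbook evaluation", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:6, 1)
    L <- sample(1:2, 1)
    npop <- sample(2:3, 1)
    a1 <- matrix(sample(101:103, n * npop * L, replace = TRUE), n * npop, L)
    a2 <- matrix(sample(101:103, n * npop * L, replace = TRUE), n * npop, L)
    sw <- a1 > a2; tmp <- a1[sw]; a1[sw] <- a2[sw]; a2[sw] <- tmp
    pop <- rep(paste0("P", seq_len(npop)), each = n)
    p <- toy_panel(a1, a2, pop = pop)
    got <- weir_cockerham(p)
    # oracle: loop-based evaluation summed over loci
    A <- B <- C <- 0
    skip <- FALSE
    for (l in seq_len(L)) {
      if (length(unique(c(a1[, l], a2[, l]))) < 2) skip <- TRUE
    }
    if (skip) next
    nv <- lapply(seq_len(L), function(l) naive_wc(a1[, l], a2[, l], pop))
    # compare per-locus theta (ratios) against the naive ratios
    for (l in seq_len(L)) {
      expect_equal(got$per_locus$theta[l], nv[[l]]$theta, tolerance = 1e-12)
      expect_equal(got$per_locus$f[l], nv[[l]]$f, tolerance = 1e-12)
    }
  }
})

test_that("homozygote-only population gives f = 1", {
  a <- matrix(c(101L, 101L, 102L, 102L), 4, 1)
  p <- toy_panel(a, a)
  expect_equal(weir_cockerham(p)$f, 1)
})

test_that("fixed differences between large populations give theta near 1", {
  a1 <- matrix(rep(c(101L, 105L), each = 20), 40, 1)
  p <- toy_panel(a1, a1, pop = rep(c("P1", "P2"), each = 20))
  th <- weir_cockerham(p)$theta
  nv <- naive_wc(a1[, 1], a1[, 1], rep(c("P1", "P2"), each = 20))
  expect_equal(th, nv$theta, tolerance = 1e-12)
  expect_gt(th, 0.97)
})

test_that("WC estimates are invariant to locus and population order", {
  p <- simulate_microsat_panel(study_config(), seed = 3)
  wc <- weir_cockerham(p)
  perm_l <- sample(nrow(p$loci))
  perm_i <- sample(nrow(p$individuals))
  p2 <- subset_panel(p, individuals = perm_i, loci = perm_l)
  wc2 <- weir_cockerham(p2)
  expect_equal(wc$theta, wc2$theta, tolerance = 1e-12)
  expect_equal(wc$f, wc2$f, tolerance = 1e-12)
})

test_that("hierarchical F reduces exactly to two-level WC when regions collapse", {
  p <- simulate_microsat_panel(study_config(), seed = 7)
  p$individuals$region <- "ALL"
  h <- hierarchical_fstats(p, hierarchy = "population")
  wc <- weir_cockerham(p)
  expect_equal(h$F_ST, wc$theta, tolerance = 1e-10)
})

test_that("duplicated populations split into fake regions give F_RT near 0", {
  pops <- data.frame(name = paste0("P", 1:4), region = c("A", "A", "B", "B"),
                     n_females = 40, n_males = 0)
  loci <- data.frame(name = paste0("L", 1:8), x_linked = FALSE,
                     n_alleles = 6L, null_freq = 0)
  # no region-level divergence, some population-level divergence
  cfg <- sim_config(pops, loci, f_sr = 0.08, f_rt = 0)
  frt <- sapply(1:6, function(s)
    hierarchical_fstats(simulate_microsat_panel(cfg, seed = s))$F_RT)
  expect_lt(abs(mean(frt)), 0.03)
})

test_that("permutation tests are deterministic and maximal statistics pin P", {
  p <- simulate_microsat_panel(study_config(), seed = 2)
  t1 <- permutation_test(p, "individuals_among_subsamples", n_perm = 50, seed = 9)
  t2 <- permutation_test(p, "individuals_among_subsamples", n_perm = 50, seed = 9)
  expect_identical(t1$p_value, t2$p_value)
  # two fixed-difference populations: observed G is unbeatable
  a <- matrix(rep(c(101L, 105L), each = 12), 24, 2)
  pf <- toy_panel(a, a, pop = rep(c("P1", "P2"), each = 12))
  tt <- permutation_test(pf, "individuals_among_subsamples", n_perm = 99,
                         seed = 1)
  expect_equal(tt$p_value, 1 / 100)
})

test_that("region permutation scheme rejects a degenerate design", {
  a <- matrix(sample(c(101L, 102L), 40, TRUE), 20, 2)
  p <- toy_panel(a, a, pop = rep(c("P1", "P2"), each = 10),
                 region = rep(c("RA", "RB"), each = 10))
  expect_error(permutation_test(p, "subsamples_between_regions", n_perm = 10,
                                seed = 1),
               "degenerate")
  expect_error(permutation_test(p, "individuals_within_region", n_perm = 10,
                                seed = 1, region = "RA"),
               "fewer than 2")
})

test_that("jackknife CIs collapse to zero width on identical populations", {
  base <- cbind(rep(c(101L, 101L, 102L, 102L, 101L, 102L), 3))
  p <- toy_panel(base, cbind(rep(c(101L, 102L, 102L, 101L, 102L, 101L), 3)),
                 pop = rep(c("P1", "P2", "P3"), each = 6))
  ci <- fstat_confidence_intervals(p, "theta", n_boot = 50, seed = 1)
  expect_equal(ci$per_locus$upper[1] - ci$per_locus$lower[1], 0,
               tolerance = 1e-10)
})

test_that("bootstrap CIs are flagged degenerate for n_boot < 2 or one locus", {
  p <- simulate_microsat_panel(study_config(), seed = 4)
  ci <- fstat_confidence_intervals(p, "theta", n_boot = 1, seed = 1)
  expect_true(ci$degenerate)
  expect_true(is.na(ci$overall["lower"]))
})

test_that("gene diversity and the regional Wilcoxon behave at the edges", {
  # monomorphic locus has Hs = 0
  a <- matrix(101L, 10, 1)
  p <- toy_panel(a, a, pop = rep(c("P1", "P2"), each = 5),
                 region = rep(c("RA", "RB"), each = 5))
  d <- nei_gene_diversity(p)
  expect_equal(unname(d$per_population[1, ]), c(0, 0))
  expect_equal(compare_region_diversity(d, "RA", "RB")$p_value, 1)
})

test_that("uniformly higher diversity in one region gives the exact signed-rank P", {
  set.seed(2)
  L <- 10
  div <- structure(list(per_region = cbind(
    RA = seq(0.55, 0.80, length.out = L) + runif(L, 0, 0.01),
    RB = seq(0.30, 0.52, length.out = L))), class = "diversity_table")
  res <- compare_region_diversity(div, "RA", "RB")
  expect_equal(res$p_value, 2 / 2^10, tolerance = 1e-12)
})
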