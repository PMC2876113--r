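test_that("null-allele estimate is zero without deficit and one when all blank", {
  # balanced heterozygotes: Ho above He, no blanks
  a1 <- matrix(rep(101L, 20)); a2 <- matrix(rep(102L, 20))
  p <- toy_panel(a1, a2)
  expect_equal(brookfield2_null_frequency(p, 1)$p_n, 0)
  # everything blank
  p2 <- toy_panel(matrix(NA_integer_, 10, 1), matrix(NA_integer_, 10, 1))
  est2 <- brookfield2_null_frequency(p2, 1)
  expect_equal(est2$p_n, 1)
})

test_that("null-allele frequency 0.2 is recovered from simulated panels", {
  pops <- data.frame(name = paste0("P", 1:3), region = "A",
                     n_females = 40, n_males = 0)
  loci <- data.frame(name = "L1", x_linked = FALSE, n_alleles = 8L,
                     null_freq = 0.2)
  cfg <- sim_config(pops, loci, f_sr = 0.02, f_rt = 0)
  pn <- sapply(1:8, function(s)
    brookfield2_null_frequency(simulate_microsat_panel(cfg, seed = s), "L1")$p_n)
  expect_true(all(pn >= 0.1 & pn <= 0.3))
})

test_that("the estimate grows with heterozygote deficit", {
  make <- function(nhom) {
    a1 <- c(rep(101L, nhom), rep(101L, 20 - nhom))
    a2 <- c(rep(101L, nhom), rep(102L, 20 - nhom))
    toy_panel(matrix(a1), matrix(a2))
  }
  ests <- sapply(c(8, 12, 16), function(h)
    brookfield2_null_frequency(make(h), 1)$p_n)
  expect_true(all(diff(ests) >= 0))
})

test_that("expected-blanks binomial test matches its closed forms", {
  # expected probability 0.25 per cell over 20 cells, 0 observed blanks
  a <- matrix(c(rep(101L, 10), rep(102L, 10)))
  p <- toy_panel(a, a)
  est <- list(locus = "L01", p_n = 0.5, undefined = FALSE)
  res <- expected_blanks_test(p, list(est))
  expect_equal(res$pooled_prob, 0.25)
  expect_equal(res$p_value, 0.75^20, tolerance = 1e-12)
  # observed equals expected: mid P
  set.seed(1)
  a1 <- matrix(c(rep(NA_integer_, 5), rep(101L, 95)))
  p2 <- toy_panel(a1, a1)
  est2 <- list(locus = "L01", p_n = sqrt(0.05), undefined = FALSE)
  res2 <- expected_blanks_test(p2, list(est2))
  expect_gt(res2$p_value, 0.5)
  # no nulls anywhere and no blanks: P = 1
  res3 <- expected_blanks_test(p, list(list(locus = "L01", p_n = 0,
                                            undefined = FALSE)))
  expect_equal(res3$p_value, 1)
})

test_that("hemizygous males contribute p_n, females p_n^2 to expected blanks", {
  n <- 10
  ind_sex <- rep(c("F", "M"), each = n / 2)
  a1 <- matrix(rep(101L, n))
  a2 <- matrix(c(rep(101L, n / 2), rep(NA_integer_, n / 2)))
  p <- toy_panel(a1, a2, sex = ind_sex, x_linked = TRUE)
  res <- expected_blanks_test(p, list(list(locus = "L01", p_n = 0.2,
                                           undefined = FALSE)))
  expect_equal(res$expected, 5 * 0.04 + 5 * 0.2)
})

test_that("a locus duplicated as its own partner is maximally linked", {
  set.seed(4)
  g <- sample(101:104, 60, replace = TRUE)
  a1 <- matrix(rep(pmin(g[1:30], g[31:60]), 2), 30)
  a2 <- matrix(rep(pmax(g[1:30], g[31:60]), 2), 30)
  p <- toy_panel(a1, a2)
  res <- ld_pairwise_tests(p, n_perm = 99, seed = 1)
  expect_equal(res$tests$p_value[1], 1 / 100)
})

test_that("near-fixed loci are excluded and the pair count shrinks", {
  set.seed(5)
  k <- 4
  mats <- lapply(seq_len(k), function(l) sample(101:105, 40, replace = TRUE))
  a1 <- sapply(mats, function(g) pmin(g[1:20], g[21:40]))
  a2 <- sapply(mats, function(g) pmax(g[1:20], g[21:40]))
  # make locus 3 nearly fixed: 39/40 genes share one allele
  a1[, 3] <- 101L; a2[, 3] <- 101L; a2[1, 3] <- 102L
  p <- toy_panel(a1, a2)
  res <- ld_pairwise_tests(p, n_perm = 20, seed = 2)
  expect_equal(res$excluded$locus, "L03")
  expect_equal(nrow(res$tests), choose(k - 1, 2))
  # the pair list is invariant to locus order
  res2 <- ld_pairwise_tests(subset_panel(p, loci = c(4, 3, 2, 1)),
                            n_perm = 20, seed = 2)
  expect_setequal(paste(pmin(res$tests$locus_a, res$tests$locus_b),
                        pmax(res$tests$locus_a, res$tests$locus_b)),
                  paste(pmin(res2$tests$locus_a, res2$tests$locus_b),
                        pmax(res2$tests$locus_a, res2$tests$locus_b)))
})

test_that("fewer than two informative loci yields an explained empty result", {
  a <- matrix(101L, 10, 2)
  p <- toy_panel(a, a)
  res <- ld_pairwise_tests(p, n_perm = 10, seed = 1)
  expect_equal(nrow(res$tests), 0)
  expect_match(res$note, "fewer than 2")
})

test_that("the significant-count binomial matches exact enumeration", {
  expect_equal(significant_count_binomial(0, 36), 1)
  expect_equal(significant_count_binomial(36, 36), 0.05^36)
  manual <- sum(sapply(4:36, function(kk)
    choose(36, kk) * 0.05^kk * 0.95^(36 - kk)))
  expect_equal(significant_count_binomial(4, 36), manual, tolerance = 1e-12)
  expect_equal(round(significant_count_binomial(4, 36), 4), 0.1037)
})

test_that("Holm correction rejects the study pattern and dominates Bonferroni", {
  res <- holm_correction(c(0.001, 0.001, 0.116))
  expect_equal(res$reject, c(TRUE, TRUE, FALSE))
  expect_equal(holm_correction(0.03)$p_adjusted, 0.03)
  expect_false(any(holm_correction(rep(1, 5))$reject))
  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(8)^2
    holm <- holm_correction(p)$reject
    bonf <- p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(holm[bonf]))   # Holm rejects a superset
  }
})
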