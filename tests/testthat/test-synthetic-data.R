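test_that("generators are bit-identical for the same seed", {
  cfg <- study_config()
  expect_identical(simulate_microsat_panel(cfg, seed = 5),
                   simulate_microsat_panel(cfg, seed = 5))
  expect_identical(simulate_coi_panel(cfg, seed = 5),
                   simulate_coi_panel(cfg, seed = 5))
  expect_identical(simulate_landmarks(cfg, seed = 5),
                   simulate_landmarks(cfg, seed = 5))
  expect_identical(
    simulate_wright_fisher_locus(50, 1e-3, "SMM", 5, sample_n = 20, seed = 5),
    simulate_wright_fisher_locus(50, 1e-3, "SMM", 5, sample_n = 20, seed = 5))
  expect_false(identical(simulate_microsat_panel(cfg, seed = 5),
                         simulate_microsat_panel(cfg, seed = 6)))
})

test_that("zero F targets give no detectable structure", {
  pops <- data.frame(name = paste0("P", 1:4), region = c("A", "A", "B", "B"),
                     n_females = 40, n_males = 0)
  loci <- data.frame(name = paste0("L", 1:6), x_linked = FALSE,
                     n_alleles = 6L, null_freq = 0)
  cfg <- sim_config(pops, loci, f_sr = 0, f_rt = 0)
  th <- sapply(1:5, function(s)
    weir_cockerham(simulate_microsat_panel(cfg, seed = s))$theta)
  expect_lt(max(abs(th)), 0.05)
})

test_that("the study configuration reproduces the sampling design", {
  p <- simulate_microsat_panel(study_config(), seed = 1)
  expect_equal(nrow(p$individuals), 153)
  expect_equal(sum(p$individuals$sex == "F"), 102)
  expect_equal(sum(p$loci$x_linked), 5)
  # hemizygous storage for males at X loci
  male <- p$individuals$sex == "M"
  xl <- which(p$loci$x_linked)
  called <- !is.na(p$a1[male, xl])
  expect_true(all(is.na(p$a2[male, xl][called])))
})

test_that("null alleles produce blanks and apparent homozygote excess", {
  pops <- data.frame(name = "P1", region = "A", n_females = 300, n_males = 0)
  loci <- data.frame(name = c("clean", "nulled"), x_linked = FALSE,
                     n_alleles = 6L, null_freq = c(0, 0.3))
  cfg <- sim_config(pops, loci, f_sr = 0, f_rt = 0)
  p <- simulate_microsat_panel(cfg, seed = 2)
  blanks <- colSums(is.na(p$a1) & is.na(p$a2))
  expect_equal(unname(blanks["clean"]), 0)
  expect_gt(blanks["nulled"], 0.3^2 * 300 * 0.3)  # near n p_n^2
  f <- weir_cockerham(p)$per_locus
  expect_gt(f$f[f$locus == "nulled"], f$f[f$locus == "clean"])
})

test_that("Wright-Fisher forward simulation respects degenerate inputs", {
  g <- simulate_wright_fisher_locus(30, 0, "IAM", generations = 20,
                                    sample_n = 20, seed = 3,
                                    init = "monomorphic")
  expect_equal(length(unique(g)), 1)
  expect_error(simulate_wright_fisher_locus(10, 0, "IAM", 0, sample_n = 50,
                                            seed = 1),
               "sample_n")
})

test_that("IAM equilibrium heterozygosity matches theta/(1+theta)", {
  N <- 25; mu <- 5e-3
  theta <- 4 * N * mu
  het <- sapply(1:200, function(s) {
    g <- simulate_wright_fisher_locus(N, mu, "IAM", generations = 300,
                                      sample_n = 30, seed = s,
                                      init = "monomorphic")
    n <- length(g)
    p <- table(g) / n
    n / (n - 1) * (1 - sum(p^2))
  })
  expect_equal(mean(het), theta / (1 + theta), tolerance = 0.12)
})

test_that("COI panels honour the regional haplotype design", {
  cfg <- study_config()
  sp <- simulate_coi_panel(cfg, seed = 4)
  ht <- collapse_haplotypes(sp)
  by_region <- ht$counts
  niayes_pops <- cfg$populations$name[cfg$populations$region == "Niayes"]
  in_n <- rowSums(by_region[, niayes_pops, drop = FALSE]) > 0
  in_s <- by_region[, "Missira"] > 0
  expect_false(any(in_n & in_s))                 # no sharing between regions
  expect_equal(sum(in_s), 9)
  expect_lte(sum(in_n), 2)
  expect_equal(sp$length, 738)
  # one haplotype per population means zero diversity
  cfg1 <- cfg
  cfg1$coi$skew <- 1e-6
  sp1 <- simulate_coi_panel(cfg1, seed = 9)
  tab <- sequence_diversity_table(sp1)
  expect_true(all(tab$hd[tab$haplotypes == 1] == 0, na.rm = TRUE))
  cfg_bad <- cfg
  cfg_bad$coi$length <- 10
  expect_error(simulate_coi_panel(cfg_bad, seed = 1), "sites")
})

test_that("noise-free identical landmark shapes align exactly", {
  cfg <- study_config()
  cfg$landmarks$offset_sd <- 0
  cfg$landmarks$region_offset_sd <- 0
  cfg$landmarks$noise_sd <- 0
  lp <- simulate_landmarks(cfg, seed = 6,
                           n_per_group = c(A = 5, B = 5))
  g <- gpa(lp)
  expect_lt(max(g$residual_ss), 1e-12)
})

test_that("pure-noise landmarks reclassify near chance under leave-one-out", {
  # resubstitution is optimistically biased by construction, so the
  # no-signal check uses cross-validated assignment
  cfg <- study_config()
  cfg$landmarks$offset_sd <- 0
  cfg$landmarks$region_offset_sd <- 0
  cfg$landmarks$noise_sd <- 0.03
  acc <- sapply(1:4, function(s) {
    lp <- simulate_landmarks(cfg, seed = s,
                             n_per_group = c(A = 25, B = 25, C = 25))
    cva <- mahalanobis_cva(partial_warps(gpa(lp)), n_perm = 1, seed = 1,
                           cross_validate = TRUE)
    sum(cva$reclassification$correct) / sum(cva$reclassification$n)
  })
  expect_lt(mean(acc), 1 / 3 + 0.15)
  expect_gt(mean(acc), 1 / 3 - 0.15)
})
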