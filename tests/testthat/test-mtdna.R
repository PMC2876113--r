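seq_of <- function(base, subs = list()) {
  s <- strsplit(base, "")[[1]]
  for (sub in subs) s[sub[[1]]] <- sub[[2]]
  paste(s, collapse = "")
}

test_that("haplotype collapsing counts haplotypes and segregating sites", {
  base <- paste(rep("A", 50), collapse = "")
  recs <- function(n, pop) data.frame(id = paste0(pop, 1:n), population = pop,
                                      region = "R")
  # 30 identical sequences: one haplotype, no polymorphism
  sp <- sequence_panel(recs(30, "X"), rep(base, 30))
  ht <- collapse_haplotypes(sp)
  expect_equal(length(ht$haplotypes), 1)
  expect_equal(length(ht$segregating_sites), 0)
  # two sequences differing at one site
  sp2 <- sequence_panel(recs(2, "X"),
                        c(base, seq_of(base, list(list(7, "T")))))
  ht2 <- collapse_haplotypes(sp2)
  expect_equal(length(ht2$haplotypes), 2)
  expect_equal(ht2$segregating_sites, 7)
  # case-insensitive input collapses identically
  sp3 <- sequence_panel(recs(2, "X"), c(base, tolower(base)))
  expect_equal(length(collapse_haplotypes(sp3)$haplotypes), 1)
  # sites with N or gaps are removed alignment-wide
  sp4 <- sequence_panel(recs(2, "X"),
                        c(seq_of(base, list(list(3, "N"))), base))
  ht4 <- collapse_haplotypes(sp4)
  expect_equal(ht4$length, 49)
  expect_equal(length(ht4$haplotypes), 1)
})

test_that("haplotype diversity reproduces the published worked values", {
  h <- haplotype_diversity(c(19, 6))
  expect_equal(round(h$hd, 3), 0.380)
  expect_equal(h$variance, 8.33e-3, tolerance = 0.001)
  h2 <- haplotype_diversity(c(25, 2))
  expect_equal(round(h2$hd, 3), 0.142)
  expect_equal(h2$variance, 7.43e-3, tolerance = 0.001)
  expect_equal(haplotype_diversity(c(30))$hd, 0)
  expect_error(haplotype_diversity(c(1)), "at least 2")
})

test_that("frequency-weighted K equals the brute-force double loop", {
  set.seed(6)
  base <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    seqs <- sapply(seq_len(n), function(i) {
      nmut <- sample(0:3, 1)
      seq_of(base, lapply(sample(40, nmut), function(s)
        list(s, sample(c("A", "C", "G", "T"), 1))))
    })
    sp <- sequence_panel(data.frame(id = paste0("s", 1:n), population = "X",
                                    region = "R"), seqs)
    pd <- pairwise_differences(sp)
    expect_equal(pd$k, brute_force_k(toupper(seqs)), tolerance = 1e-12)
    expect_equal(pd$pi, pd$k / 40, tolerance = 1e-12)
  }
})

test_that("the Pout configuration reproduces the published K and Pi", {
  base <- paste(rep("A", 738), collapse = "")
  alt <- seq_of(base, list(list(1, "C")))
  sp <- sequence_panel(data.frame(id = paste0("s", 1:25), population = "Pout",
                                  region = "N"),
                       c(rep(base, 19), rep(alt, 6)))
  pd <- pairwise_differences(sp)
  expect_equal(pd$k, 114 / 300, tolerance = 1e-12)
  expect_equal(round(pd$k, 3), 0.380)
  expect_equal(pd$pi, 0.00051, tolerance = 0.01)
})

test_that("completely sorted populations give Fst = Hst = 1", {
  base <- paste(rep("A", 30), collapse = "")
  alt <- seq_of(base, list(list(5, "G")))
  recs <- data.frame(id = paste0("s", 1:12),
                     population = rep(c("X", "Y"), each = 6), region = "R")
  sp <- sequence_panel(recs, c(rep(base, 6), rep(alt, 6)))
  hd <- hudson_differentiation(sp, "X", "Y", n_perm = 99, seed = 1)
  expect_equal(hd$fst, 1)
  expect_equal(hd$hst, 1)
  expect_lte(hd$p_kst, 0.05)
})

test_that("Hudson statistics are invariant to sequence order and deterministic", {
  cfg <- study_config()
  sp <- simulate_coi_panel(cfg, seed = 2)
  h1 <- hudson_differentiation(sp, "Missira", "Pout", n_perm = 60, seed = 3)
  o <- sample(length(sp$seqs))
  sp2 <- sequence_panel(sp$records[o, ], sp$seqs[o])
  h2 <- hudson_differentiation(sp2, "Missira", "Pout", n_perm = 60, seed = 3)
  expect_equal(h1$kst_star, h2$kst_star, tolerance = 1e-12)
  expect_equal(h1$hst, h2$hst, tolerance = 1e-12)
  h3 <- hudson_differentiation(sp, "Missira", "Pout", n_perm = 60, seed = 3)
  expect_identical(h1$p_kst, h3$p_kst)
})

test_that("unshared regional haplotype pools give strong Hudson Fst", {
  for (seed in 1:3) {
    sp <- simulate_coi_panel(study_config(), seed = seed)
    pops_n <- c("Sebikotan", "Pout", "DakarHann", "DiacsawPeul")
    fst <- sapply(pops_n, function(pp)
      hudson_differentiation(sp, "Missira", pp, n_perm = 1, seed = 1)$fst)
    expect_true(all(fst > 0.8))
    # no-sharing means Hst strictly positive
    expect_true(all(sapply(pops_n, function(pp)
      hudson_differentiation(sp, "Missira", pp, n_perm = 1,
                             seed = 1)$hst) > 0))
  }
})

test_that("monomorphic pooled samples are rejected", {
  base <- paste(rep("A", 20), collapse = "")
  recs <- data.frame(id = paste0("s", 1:8),
                     population = rep(c("X", "Y"), each = 4), region = "R")
  sp <- sequence_panel(recs, rep(base, 8))
  expect_error(hudson_differentiation(sp, "X", "Y", n_perm = 10, seed = 1),
               "monomorphic")
})

test_that("the haplotype network is a minimum spanning structure", {
  base <- paste(rep("A", 40), collapse = "")
  s1 <- seq_of(base, list(list(1, "C")))
  s2 <- seq_of(base, list(list(1, "C"), list(2, "C")))
  recs <- function(seqs) data.frame(id = paste0("s", seq_along(seqs)),
                                    population = "X", region = "R")
  # two haplotypes one step apart: single edge of weight 1
  sp <- sequence_panel(recs(c(base, s1)), c(base, s1))
  net <- parsimony_network(collapse_haplotypes(sp))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$steps, 1)
  # three haplotypes on a line: path, not triangle
  sp2 <- sequence_panel(recs(c(base, s1, s2)), c(base, s1, s2))
  net2 <- parsimony_network(collapse_haplotypes(sp2))
  expect_equal(nrow(net2$edges), 2)
  expect_equal(sort(net2$edges$steps), c(1L, 1L))
  expect_equal(max(net2$components), 1)
})

test_that("clusters beyond the connection limit split into components", {
  base <- paste(rep("A", 40), collapse = "")
  far <- seq_of(base, lapply(1:12, function(s) list(s, "G")))
  near <- seq_of(far, list(list(20, "C")))
  seqs <- c(base, seq_of(base, list(list(30, "T"))), far, near)
  recs <- data.frame(id = paste0("s", 1:4), population = "X", region = "R")
  ht <- collapse_haplotypes(sequence_panel(recs, seqs))
  net <- parsimony_network(ht, connection_limit = 11)
  expect_equal(net$n_components, 2)
  expect_true(all(net$edges$steps <= 11))
  # with a permissive limit everything connects, intermediates recorded
  net2 <- parsimony_network(ht, connection_limit = 15)
  expect_equal(net2$n_components, 1)
  expect_equal(max(net2$edges$inferred_intermediates), 11)
})

test_that("the study-shaped COI panel yields the two-cluster network", {
  sp <- simulate_coi_panel(study_config(), seed = 8)
  ht <- collapse_haplotypes(sp)
  net <- parsimony_network(ht, connection_limit = 11)
  expect_equal(net$n_components, 2)
})
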