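## Synthetic data generators emulating the five-site, two-region tsetse
## study design: a hierarchical-F microsatellite panel generator, forward
## Wright-Fisher single-locus simulation, a COI haplotype panel generator,
## and a wing-landmark generator. All are deterministic given `seed`.

#' Simulation configuration
#'
#' Declarative description of the study design a synthetic dataset should
#' emulate: populations nested in regions with per-sex sample sizes, loci
#' with X-linkage, mutation model and null-allele frequency, hierarchical F
#' targets, and an optional bottlenecked population.
#'
#' The hierarchical F-model draws region allele frequencies around ancestral
#' frequencies with Dirichlet concentration (1-F_RT)/F_RT, and population
#' frequencies around their region's with concentration (1-F_SR)/F_SR; an F
#' target of 0 means frequencies are shared exactly.
#'
#' @param populations data.frame with columns `name`, `region`, `n_females`,
#'   `n_males`.
#' @param loci data.frame with columns `name`, `x_linked`, `n_alleles`,
#'   `null_freq`.
#' @param f_sr target F of populations within regions, in [0, 1).
#' @param f_rt target F of regions within total, in [0, 1).
#' @param bottleneck optional list(population, extra_f) adding drift to one
#'   population (extra Dirichlet concentration shrinkage emulating a recent
#'   crash); or NULL.
#' @param coi list describing the mtDNA panel: `length` (alignment sites),
#'   `haplotypes_per_region` named integer vector, `divergence_steps`
#'   (mutational steps separating the two regional clusters), `skew`
#'   (Dirichlet concentration for within-population haplotype frequencies;
#'   small values give one dominant haplotype per population).
#' @param landmarks list for the wing generator: `k` landmarks,
#'   `offset_sd` (per-population mean-shape displacement, Procrustes
#'   units), `region_offset_sd` (region-level displacement shared within a
#'   region), `noise_sd` (isotropic individual landmark noise).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(populations, loci, f_sr = 0.07, f_rt = 0.12,
                       bottleneck = NULL,
                       coi = list(length = 738,
                                  haplotypes_per_region = NULL,
                                  divergence_steps = 12, skew = 0.35),
                       landmarks = list(k = 10, offset_sd = 0.010,
                                        region_offset_sd = 0.015,
                                        noise_sd = 0.025)) {
  stopifnot(f_sr >= 0, f_sr < 1, f_rt >= 0, f_rt < 1,
            all(populations$n_females + populations$n_males >= 1),
            all(loci$null_freq >= 0), all(loci$null_freq <= 1))
  structure(list(populations = populations, loci = loci,
                 f_sr = f_sr, f_rt = f_rt, bottleneck = bottleneck,
                 coi = coi, landmarks = landmarks),
            class = "sim_config")
}

#' Default study-shaped configuration
#'
#' Emulates the Senegal design: five populations, four in the Niayes region
#' and one (Missira) in the southern belt, sex-specific sample sizes
#' totalling 153 flies; 10 microsatellite loci of which 5 are X-linked, with
#' null alleles at the four loci that show technical artefacts in field
#' data; between-region differentiation target 0.12 and within-region 0.07
#' with Dakar Hann as a bottlenecked outlier; a COI panel with 9 + 2
#' regional haplotypes and no sharing; and 10-landmark wings with
#' group-level mean-shape offsets.
#'
#' @return a [sim_config()].
#' @export
study_config <- function() {
  pops <- data.frame(
    name = c("DiacsawPeul", "DakarHann", "Sebikotan", "Pout", "Missira"),
    region = c("Niayes", "Niayes", "Niayes", "Niayes", "Southern"),
    n_females = c(22L, 23L, 21L, 13L, 23L),
    n_males = c(8L, 6L, 11L, 14L, 12L),
    stringsAsFactors = FALSE)
  loci <- data.frame(
    name = c("X55.3", "XPgp11", "Pgp1", "XPgp13", "Pgp24",
             "A10", "XB104", "XB110", "C102", "GPCAG"),
    x_linked = c(TRUE, TRUE, FALSE, TRUE, FALSE,
                 FALSE, TRUE, TRUE, FALSE, FALSE),
    n_alleles = c(8L, 8L, 8L, 8L, 8L, 8L, 8L, 3L, 8L, 8L),
    null_freq = c(0, 0, 0.2, 0, 0.2, 0.2, 0, 0.15, 0, 0),
    stringsAsFactors = FALSE)
  sim_config(pops, loci,
             f_sr = 0.07, f_rt = 0.12,
             bottleneck = list(population = "DakarHann", extra_f = 0.12),
             coi = list(length = 738,
                        haplotypes_per_region = c(Niayes = 2L, Southern = 9L),
                        divergence_steps = 12, skew = 0.35),
             landmarks = list(k = 10, offset_sd = 0.010,
                              region_offset_sd = 0.015, noise_sd = 0.025))
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1
  x / sum(x)
}

## draw frequencies centred on `p` with target fixation index f
draw_around <- function(p, f) {
  if (f <= 0) return(p)
  conc <- (1 - f) / f
  rdirichlet1(p * conc)
}

#' Simulate a microsatellite genotype panel under the hierarchical F-model
#'
#' Ancestral allele frequencies per locus are symmetric-Dirichlet; regional
#' frequencies are Dirichlet draws centred on the ancestral vector with
#' concentration (1-F_RT)/F_RT, population frequencies likewise with
#' (1-F_SR)/F_SR (a bottlenecked population uses the compounded
#' F_SR + extra_f). Genotypes are binomial draws from population
#' frequencies: two genes for females and autosomal males, one gene for
#' hemizygous males at X-linked loci. A null allele of locus-wide frequency
#' `null_freq` hides genes: two null genes give a missing genotype, one
#' leaves an apparent homozygote (or a missing hemizygous call).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a [genotype_panel()].
#' @export
simulate_microsat_panel <- function(config, seed = 1) {
  set.seed(seed)
  pops <- config$populations
  loci <- config$loci
  ind <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    n_f <- pops$n_females[i]; n_m <- pops$n_males[i]
    data.frame(
      id = sprintf("%s_%02d", pops$name[i], seq_len(n_f + n_m)),
      sex = c(rep("F", n_f), rep("M", n_m)),
      population = pops$name[i], region = pops$region[i],
      stringsAsFactors = FALSE)
  }))
  n <- nrow(ind)
  L <- nrow(loci)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  male <- ind$sex == "M"
  regions <- unique(pops$region)
  bn <- config$bottleneck
  for (l in seq_len(L)) {
    k <- loci$n_alleles[l]
    sizes <- as.integer(seq(150, by = 2, length.out = k))
    anc <- rdirichlet1(rep(1, k))
    reg_freq <- lapply(regions, function(r) draw_around(anc, config$f_rt))
    names(reg_freq) <- regions
    p_null <- loci$null_freq[l]
    for (pi in seq_len(nrow(pops))) {
      f_pop <- config$f_sr
      if (!is.null(bn) && pops$name[pi] == bn$population) {
        f_pop <- min(0.999, f_pop + bn$extra_f)
      }
      pf <- draw_around(reg_freq[[pops$region[pi]]], f_pop)
      rows <- which(ind$population == pops$name[pi])
      for (i in rows) {
        hemi <- male[i] && loci$x_linked[l]
        ng <- if (hemi) 1L else 2L
        g <- sample.int(k, ng, replace = TRUE, prob = pf)
        isnull <- stats::runif(ng) < p_null
        vis <- g[!isnull]
        if (length(vis) == 0) {
          # all genes null: blank genotype
        } else if (hemi) {
          a1[i, l] <- sizes[vis[1]]
        } else if (length(vis) == 1) {
          a1[i, l] <- sizes[vis[1]]   # apparent homozygote
          a2[i, l] <- sizes[vis[1]]
        } else {
          a1[i, l] <- sizes[min(g)]
          a2[i, l] <- sizes[max(g)]
        }
      }
    }
  }
  genotype_panel(ind, loci[, c("name", "x_linked")], a1, a2)
}

#' Forward Wright-Fisher simulation of one locus
#'
#' Gene-level forward simulation of 2N genes with mutation under IAM, SMM or
#' TPM, an optional instantaneous size crash, and terminal sampling without
#' replacement. The initial state is either monomorphic or an equilibrium
#' configuration drawn with the package's coalescent sampler (so bottleneck
#' scenarios only need the short post-crash forward phase).
#'
#' @param N diploid population size before any crash.
#' @param mu per-gene per-generation mutation rate.
#' @param model "IAM", "SMM" or "TPM".
#' @param generations forward generations to simulate.
#' @param bottleneck_spec optional list(at, N_post): crash to `N_post`
#'   diploids `at` generations before sampling.
#' @param sample_n genes to sample at the end.
#' @param seed integer seed.
#' @param init "equilibrium" (coalescent draw at theta = 4 N mu) or
#'   "monomorphic".
#' @param tpm list(p_single, geom_q) for the TPM: single-step probability
#'   and geometric parameter of the multistep size (q = 1/6 gives the
#'   conventional multistep variance of 30).
#' @return integer vector of sampled allele identities/sizes.
#' @export
simulate_wright_fisher_locus <- function(N, mu, model = c("IAM", "SMM", "TPM"),
                                         generations = 0,
                                         bottleneck_spec = NULL,
                                         sample_n, seed = 1,
                                         init = c("equilibrium", "monomorphic"),
                                         tpm = list(p_single = 0.7, geom_q = 1 / 6)) {
  model <- match.arg(model)
  init <- match.arg(init)
  stopifnot(N >= 2, sample_n >= 2)
  set.seed(seed)
  mcode <- match(model, c("IAM", "SMM", "TPM")) - 1L
  genes <- if (init == "equilibrium") {
    coalescent_config(2L * N, 4 * N * mu, mcode, tpm$p_single, tpm$geom_q)
  } else {
    integer(2L * N)
  }
  label <- max(genes) + 1L  # next fresh IAM label
  n_genes <- length(genes)
  for (g in seq_len(generations)) {
    if (!is.null(bottleneck_spec) && g == generations - bottleneck_spec$at + 1L) {
      n_genes <- 2L * bottleneck_spec$N_post
      genes <- genes[sample.int(length(genes), n_genes)]
    }
    genes <- genes[sample.int(n_genes, n_genes, replace = TRUE)]
    nm <- stats::rbinom(1L, n_genes, mu)
    if (nm > 0) {
      at <- sample.int(n_genes, nm)
      if (model == "IAM") {
        genes[at] <- label + seq_len(nm) - 1L
        label <- label + nm
      } else {
        single <- model == "SMM" | stats::runif(nm) < tpm$p_single
        step <- ifelse(single, 1L, 1L + stats::rgeom(nm, tpm$geom_q))
        genes[at] <- genes[at] + step * sample(c(-1L, 1L), nm, replace = TRUE)
      }
    }
  }
  if (sample_n > length(genes)) stop("sample_n exceeds surviving gene count")
  genes[sample.int(length(genes), sample_n)]
}

#' Individual-based multilocus Wright-Fisher population
#'
#' Simulates N diploids with `n_loci` unlinked loci through random-mating
#' generations, so that drift generates the transient inter-locus
#' associations the linkage-disequilibrium Ne estimator measures. Initial
#' allele states per locus are equilibrium coalescent draws.
#'
#' @param N diploid population size.
#' @param n_loci number of unlinked loci.
#' @param mu per-gene mutation rate (SMM mutation keeps loci polymorphic).
#' @param generations generations of random mating to run.
#' @param sample_n individuals to sample at the end.
#' @param seed integer seed.
#' @return a [genotype_panel()] with one population, all-female autosomal
#'   codings (sex is irrelevant for autosomal loci).
#' @export
simulate_population_panel <- function(N, n_loci = 10, mu = 5e-3,
                                      generations = 60, sample_n = 30,
                                      seed = 1) {
  stopifnot(sample_n <= N)
  set.seed(seed)
  G <- matrix(0L, 2L * N, n_loci)   # rows 2i-1, 2i = individual i
  for (l in seq_len(n_loci)) {
    G[, l] <- coalescent_config(2L * N, 4 * N * mu, 1L, 0.7, 1 / 6)
  }
  off <- matrix(rep((seq_len(n_loci) - 1L) * 2L * N, each = N), N, n_loci)
  for (g in seq_len(generations)) {
    Gn <- matrix(0L, 2L * N, n_loci)
    for (par in 1:2) {
      parents <- sample.int(N, N, replace = TRUE)
      pick <- matrix(sample.int(2L, N * n_loci, replace = TRUE), N, n_loci)
      rows <- 2L * (parents - 1L) + pick
      Gn[seq(par, 2L * N, by = 2L), ] <- G[as.vector(rows + off)]
    }
    G <- Gn
    nm <- stats::rbinom(1L, length(G), mu)
    if (nm > 0) {
      at <- sample.int(length(G), nm)
      G[at] <- G[at] + sample(c(-1L, 1L), nm, replace = TRUE)
    }
  }
  take <- sample.int(N, sample_n)
  ind <- data.frame(id = sprintf("sim_%03d", seq_len(sample_n)),
                    sex = "F", population = "simpop", region = "simregion",
                    stringsAsFactors = FALSE)
  loci <- data.frame(name = sprintf("L%02d", seq_len(n_loci)),
                     x_linked = FALSE, stringsAsFactors = FALSE)
  a1 <- G[2L * take - 1L, , drop = FALSE] + 200L
  a2 <- G[2L * take, , drop = FALSE] + 200L
  swap <- a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  genotype_panel(ind, loci, a1, a2)
}

#' Simulate a COI sequence panel
#'
#' Builds two regional haplotype clusters separated by
#' `coi$divergence_steps` mutations, derives the within-region haplotypes by
#' single mutations at fresh sites (a star-like intraregional genealogy),
#' assigns per-population haplotype frequencies by a skewed Dirichlet over
#' the region's haplotypes, and samples sequences. No haplotype is shared
#' between regions.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a [sequence_panel()].
#' @export
simulate_coi_panel <- function(config, seed = 1) {
  set.seed(seed)
  L <- config$coi$length
  pops <- config$populations
  regions <- unique(pops$region)
  nh <- config$coi$haplotypes_per_region
  if (is.null(nh)) {
    nh <- stats::setNames(rep(2L, length(regions)), regions)
  }
  div <- config$coi$divergence_steps
  total_mut <- div + sum(nh - 1L)
  if (total_mut > L) stop("requested haplotypes need more sites than the alignment has")
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  free_sites <- sample.int(L, total_mut)   # all mutations at distinct sites
  site_i <- 0L
  mutate_at <- function(seqv, n_sites) {
    for (j in seq_len(n_sites)) {
      site_i <<- site_i + 1L
      s <- free_sites[site_i]
      seqv[s] <- sample(setdiff(c("A", "C", "G", "T"), seqv[s]), 1L)
    }
    seqv
  }
  cluster_anc <- list(root, mutate_at(root, div))
  names(cluster_anc) <- regions[seq_len(min(2, length(regions)))]
  haps <- list()
  for (r in regions) {
    anc <- cluster_anc[[r]] %||% root
    hs <- list(anc)
    for (h in seq_len(nh[[r]] - 1L)) hs[[h + 1L]] <- mutate_at(anc, 1L)
    haps[[r]] <- vapply(hs, paste, "", collapse = "")
  }
  recs <- list(); draws <- list()
  for (pi in seq_len(nrow(pops))) {
    r <- pops$region[pi]
    n_i <- pops$n_females[pi] + pops$n_males[pi]
    hp <- haps[[r]]
    w <- rdirichlet1(rep(config$coi$skew, length(hp)))
    draws[[pi]] <- sample.int(length(hp), n_i, replace = TRUE, prob = w)
    recs[[pi]] <- data.frame(
      id = sprintf("%s_%02d", pops$name[pi], seq_len(n_i)),
      population = pops$name[pi], region = r, stringsAsFactors = FALSE)
  }
  # the design fixes the number of OBSERVED haplotypes per region: patch
  # unsampled pool members into the region's largest sample
  for (r in regions) {
    pis <- which(pops$region == r)
    seen <- unique(unlist(draws[pis]))
    missing <- setdiff(seq_len(nh[[r]]), seen)
    if (length(missing)) {
      big <- pis[which.max(vapply(draws[pis], length, 0L))]
      for (h in missing) {
        dup <- which(duplicated(draws[[big]]) |
                       draws[[big]] %in% draws[[big]][duplicated(draws[[big]])])
        slot <- dup[length(dup)]
        draws[[big]][slot] <- h
      }
    }
  }
  seqs <- unlist(lapply(seq_len(nrow(pops)), function(pi)
    haps[[pops$region[pi]]][draws[[pi]]]))
  sequence_panel(do.call(rbind, recs), seqs)
}

#' Simulate wing landmark configurations
#'
#' Group mean shapes are a unit-size base decagon (k points on a circle)
#' plus a region-level mean-shape offset (SD `landmarks$region_offset_sd`,
#' shared by the region's populations, so that shape divergence mirrors the
#' genetic hierarchy) plus a population-specific offset (SD
#' `landmarks$offset_sd`); individuals add isotropic Gaussian landmark
#' noise `landmarks$noise_sd`, and each configuration is then pushed
#' through a random rotation, translation and scale so the generator
#' produces raw digitisations for GPA to align.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param n_per_group optional named integer vector of wings per population;
#'   defaults to the genotyped sample sizes. Names not matching a
#'   configured population are treated as their own region.
#' @return a [landmark_panel()].
#' @export
simulate_landmarks <- function(config, seed = 1, n_per_group = NULL) {
  set.seed(seed)
  k <- config$landmarks$k
  offs <- config$landmarks$offset_sd
  roffs <- config$landmarks$region_offset_sd
  if (is.null(roffs)) roffs <- 0
  noise <- config$landmarks$noise_sd
  pops <- config$populations
  if (is.null(n_per_group)) {
    n_per_group <- stats::setNames(pops$n_females + pops$n_males, pops$name)
  }
  region_of <- pops$region[match(names(n_per_group), pops$name)]
  region_of[is.na(region_of)] <- names(n_per_group)[is.na(region_of)]
  reg_shift <- lapply(unique(region_of), function(r)
    matrix(stats::rnorm(2 * k, 0, roffs), k, 2))
  names(reg_shift) <- unique(region_of)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  base <- cbind(cos(ang), sin(ang))
  base <- base / sqrt(sum(scale(base, scale = FALSE)^2))
  coords <- array(NA_real_, c(sum(n_per_group), k, 2))
  grp <- character(sum(n_per_group)); ids <- character(sum(n_per_group))
  row <- 0L
  for (g in names(n_per_group)) {
    mean_shape <- base + reg_shift[[region_of[match(g, names(n_per_group))]]] +
      matrix(stats::rnorm(2 * k, 0, offs), k, 2)
    for (i in seq_len(n_per_group[[g]])) {
      row <- row + 1L
      cfg <- mean_shape + matrix(stats::rnorm(2 * k, 0, noise), k, 2)
      th <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      s <- exp(stats::rnorm(1, 0, 0.2))
      tr <- stats::rnorm(2, 0, 2)
      coords[row, , ] <- sweep(s * cfg %*% R, 2, tr, "+")
      grp[row] <- g
      ids[row] <- sprintf("%s_w%02d", g, i)
    }
  }
  landmark_panel(coords, grp, ids)
}
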