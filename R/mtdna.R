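## Mitochondrial sequence statistics: haplotype collapsing, diversity with
## variances, mean pairwise differences, Hudson differentiation statistics
## (Fst, Hst, Kst*) with sequence-permutation tests, and a simplified
## statistical-parsimony haplotype network.

## complete deletion: drop alignment columns containing N or a gap in any
## sequence (the statistics then see a gap-free alignment)
clean_alignment <- function(panel) {
  seqs <- toupper(panel$seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  bad <- apply(mat, 2, function(col) any(!col %in% c("A", "C", "G", "T")))
  if (any(bad)) mat <- mat[, !bad, drop = FALSE]
  list(mat = mat, seqs = apply(mat, 1, paste, collapse = ""),
       length = ncol(mat), removed_sites = sum(bad))
}

#' Collapse aligned sequences into a haplotype table
#'
#' Identical sequences (case-insensitive; sites with N or gaps removed
#' alignment-wide beforehand) are collapsed; per-population counts and
#' segregating sites are recorded.
#'
#' @param panel a [sequence_panel()].
#' @return object of class `haplotype_table`: haplotype sequences, counts
#'   matrix (haplotypes x populations), segregating site positions (in the
#'   cleaned alignment), cleaned length.
#' @export
collapse_haplotypes <- function(panel) {
  if (length(panel$seqs) == 0) stop("empty sequence panel")
  cl <- clean_alignment(panel)
  hap_of <- match(cl$seqs, unique(cl$seqs))
  haps <- unique(cl$seqs)
  pops <- factor(panel$records$population)
  counts <- table(factor(hap_of, levels = seq_along(haps)), pops)
  hm <- do.call(rbind, strsplit(haps, ""))
  seg <- if (nrow(hm) > 1) {
    which(apply(hm, 2, function(col) length(unique(col)) > 1))
  } else integer(0)
  rownames(counts) <- paste0("H", seq_along(haps))
  structure(list(haplotypes = haps, counts = unclass(counts),
                 segregating_sites = seg, length = cl$length,
                 removed_sites = cl$removed_sites,
                 region = panel$records$region[match(levels(pops),
                                                     panel$records$population)]),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$haplotypes), "haplotypes,",
      length(x$segregating_sites), "segregating sites,",
      sum(x$counts), "sequences\n")
  invisible(x)
}

#' Haplotype diversity with its sampling variance
#'
#' Unbiased haplotype (gene) diversity Hd = n/(n-1) (1 - sum p_i^2) and its
#' sampling variance
#' V = 2/(n(n-1)) * (2(n-2) (sum p^3 - (sum p^2)^2) + sum p^2 - (sum p^2)^2).
#'
#' @param counts integer vector of haplotype counts (one entry per distinct
#'   haplotype).
#' @return list `hd`, `variance`, `n`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 sequences")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(hd = hd, variance = v, n = n)
}

## Hamming distance matrix between haplotype strings
hap_dist_matrix <- function(haps) {
  H <- length(haps)
  hm <- do.call(rbind, strsplit(haps, ""))
  d <- matrix(0L, H, H)
  if (H > 1) {
    for (i in seq_len(H - 1)) {
      for (j in (i + 1):H) {
        d[i, j] <- d[j, i] <- sum(hm[i, ] != hm[j, ])
      }
    }
  }
  d
}

#' Mean pairwise nucleotide differences K and nucleotide diversity Pi
#'
#' K is the mean Hamming distance over all sequence pairs (computed from
#' haplotype frequencies; a brute-force double loop gives the identical
#' value). Pi = K / L for the gap-free alignment. The variance of K is the
#' total (sampling plus stochastic, no recombination) variance
#' V(K) = (3n(n+1)K + 2(n^2+n+3)K^2) / (11(n^2-7n+6)), and the variance of
#' Pi is V(Pi) = ((n+1) Pi)/(3(n-1)L) + (2(n^2+n+3) Pi^2)/(9n(n-1)).
#'
#' @param panel a [sequence_panel()].
#' @return list `k`, `k_variance`, `pi`, `pi_variance`, `n`, `length`, `s`
#'   (segregating sites).
#' @export
pairwise_differences <- function(panel) {
  ht <- collapse_haplotypes(panel)
  if (ht$length == 0) stop("alignment has length 0 after site cleaning")
  cnt <- rowSums(ht$counts)
  n <- sum(cnt)
  if (n < 2) stop("need at least 2 sequences")
  d <- hap_dist_matrix(ht$haplotypes)
  npairs <- n * (n - 1) / 2
  tot <- 0
  for (i in seq_along(cnt)) {
    for (j in seq_len(i)) {
      tot <- tot + if (i == j) cnt[i] * (cnt[i] - 1) / 2 * d[i, j] else
        cnt[i] * cnt[j] * d[i, j]
    }
  }
  k <- unname(tot / npairs)
  pi <- k / ht$length
  kv <- (3 * n * (n + 1) * k + 2 * (n^2 + n + 3) * k^2) /
    (11 * (n^2 - 7 * n + 6))
  piv <- (n + 1) * pi / (3 * (n - 1) * ht$length) +
    2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  list(k = k, k_variance = kv, pi = pi, pi_variance = piv,
       n = n, length = ht$length, s = length(ht$segregating_sites))
}

## mean pairwise difference within a set of sequences given hap indices
mean_pairwise <- function(d, hap_idx) {
  n <- length(hap_idx)
  if (n < 2) return(0)
  sum(d[hap_idx, hap_idx]) / (n * (n - 1))
}

#' Hudson differentiation statistics for a pair of populations
#'
#' Computes, for two populations of aligned sequences:
#' \itemize{
#'   \item Fst = 1 - Hw/Hb, with Hw the (pair-count weighted) mean number
#'     of differences within populations and Hb the mean between;
#'   \item Hst = 1 - Hs/Ht, with Hs the sample-size-weighted mean haplotype
#'     diversity and Ht the pooled unbiased haplotype diversity;
#'   \item Kst* = 1 - Ks*/Kt*, with Ks* the C(n_j, 2)-weighted mean of
#'     log(1 + K_j) within populations and Kt* = log(1 + K_T) for the
#'     pooled sample.
#' }
#' Significance of Hst and Kst* is assessed by permuting sequences (not
#' haplotype classes) between the two localities.
#'
#' @param panel a [sequence_panel()].
#' @param pop_a,pop_b population labels.
#' @param n_perm permutations (study default 10000).
#' @param seed integer seed.
#' @return object of class `seq_differentiation` with the statistics,
#'   components and permutation P-values.
#' @export
hudson_differentiation <- function(panel, pop_a, pop_b, n_perm = 1000,
                                   seed = 1) {
  set.seed(seed)
  sel <- panel$records$population %in% c(pop_a, pop_b)
  sub <- sequence_panel(panel$records[sel, , drop = FALSE], panel$seqs[sel])
  cl <- clean_alignment(sub)
  haps <- unique(cl$seqs)
  hap_of <- match(cl$seqs, haps)
  d <- hap_dist_matrix(haps)
  grp <- sub$records$population == pop_a
  n1 <- sum(grp); n2 <- sum(!grp)
  if (n1 < 2 || n2 < 2) stop("both populations need n >= 2")
  if (length(haps) < 2) {
    stop("pooled sample monomorphic: differentiation undefined")
  }
  stat_all <- function(grp) {
    i1 <- hap_of[grp]; i2 <- hap_of[!grp]
    k1 <- mean_pairwise(d, i1); k2 <- mean_pairwise(d, i2)
    kb <- mean(d[i1, i2, drop = FALSE])
    w <- c(n1 * (n1 - 1), n2 * (n2 - 1))
    hw <- sum(w * c(k1, k2)) / sum(w)
    fst <- 1 - hw / kb
    # haplotype-frequency statistics
    h1 <- haplotype_diversity(tabulate(i1, length(haps)))$hd
    h2 <- haplotype_diversity(tabulate(i2, length(haps)))$hd
    hs <- (n1 * h1 + n2 * h2) / (n1 + n2)
    ht <- haplotype_diversity(tabulate(hap_of, length(haps)))$hd
    hst <- 1 - hs / ht
    kt <- mean_pairwise(d, hap_of)
    wk <- c(choose(n1, 2), choose(n2, 2))
    ks_star <- sum(wk * log(1 + c(k1, k2))) / sum(wk)
    kst_star <- 1 - ks_star / log(1 + kt)
    c(fst = fst, hst = hst, kst_star = kst_star, hs = hs, ht = ht,
      ks_star = ks_star, kt = kt, hw = hw, hb = kb)
  }
  obs <- stat_all(grp)
  ge_h <- 0L; ge_k <- 0L
  for (b in seq_len(n_perm)) {
    pg <- sample(grp)
    st <- stat_all(pg)
    if (st["hst"] >= obs["hst"] - 1e-12) ge_h <- ge_h + 1L
    if (st["kst_star"] >= obs["kst_star"] - 1e-12) ge_k <- ge_k + 1L
  }
  structure(list(pop_a = pop_a, pop_b = pop_b,
                 fst = unname(obs["fst"]), hst = unname(obs["hst"]),
                 kst_star = unname(obs["kst_star"]),
                 components = obs, n_perm = n_perm, seed = seed,
                 p_hst = (ge_h + 1) / (n_perm + 1),
                 p_kst = (ge_k + 1) / (n_perm + 1)),
            class = "seq_differentiation")
}

#' @export
print.seq_differentiation <- function(x, ...) {
  cat(sprintf("%s vs %s: Fst = %.3f, Hst = %.3f (P = %.4g), Kst* = %.3f (P = %.4g)\n",
              x$pop_a, x$pop_b, x$fst, x$hst, x$p_hst, x$kst_star, x$p_kst))
  invisible(x)
}

#' Simplified statistical-parsimony haplotype network
#'
#' Minimum spanning network on haplotype Hamming distances: a minimum
#' spanning tree is built, edges longer than the user-supplied connection
#' limit (mutational steps; 11 reproduces the study setting for 738 nt at
#' the 95 percent parsimony limit) are removed, and intermediate
#' (unsampled) node counts are recorded on multi-step edges. The parsimony
#' probability computation of the limit itself is not performed; the limit
#' is an input.
#'
#' @param ht a [haplotype_table()].
#' @param connection_limit maximum steps for a retained edge.
#' @return object of class `haplotype_network`: edge data.frame (from, to,
#'   steps, inferred_intermediates), component membership, the limit.
#' @export
parsimony_network <- function(ht, connection_limit = 11) {
  stopifnot(connection_limit >= 1)
  H <- length(ht$haplotypes)
  labels <- rownames(ht$counts)
  if (H == 1) {
    return(structure(list(edges = data.frame(), components = stats::setNames(1L, labels),
                          connection_limit = connection_limit),
                     class = "haplotype_network"))
  }
  d <- hap_dist_matrix(ht$haplotypes)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- labels
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_data_frame(mst, what = "edges")
  keep <- el$weight <= connection_limit
  edges <- data.frame(from = el$from[keep], to = el$to[keep],
                      steps = as.integer(el$weight[keep]),
                      inferred_intermediates = pmax(as.integer(el$weight[keep]) - 1L, 0L),
                      stringsAsFactors = FALSE)
  g2 <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                      vertices = data.frame(name = labels))
  comp <- igraph::components(g2)$membership
  structure(list(edges = edges, components = comp,
                 connection_limit = connection_limit,
                 n_components = max(comp)),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$edges), "edges, limit",
      x$connection_limit, "steps,", x$n_components %||% 1L, "component(s)\n")
  invisible(x)
}

#' Per-population diversity summary table
#'
#' Convenience wrapper producing, per population and for the pooled total:
#' sequences, haplotype count, polymorphic sites, Hd (variance), Pi
#' (variance) and K (variance).
#'
#' @param panel a [sequence_panel()].
#' @return data.frame, one row per population plus "Total".
#' @export
sequence_diversity_table <- function(panel) {
  pops <- unique(panel$records$population)
  rows <- lapply(c(pops, "Total"), function(pp) {
    sel <- if (pp == "Total") rep(TRUE, length(panel$seqs)) else
      panel$records$population == pp
    sub <- sequence_panel(panel$records[sel, , drop = FALSE], panel$seqs[sel])
    ht <- collapse_haplotypes(sub)
    cnt <- rowSums(ht$counts)
    n <- sum(cnt)
    if (n >= 2) {
      hd <- haplotype_diversity(cnt)
      pd <- pairwise_differences(sub)
      data.frame(population = pp, n = n, haplotypes = sum(cnt > 0),
                 polymorphic_sites = length(ht$segregating_sites),
                 hd = hd$hd, hd_variance = hd$variance,
                 pi = pd$pi, pi_variance = pd$pi_variance,
                 k = pd$k, k_variance = pd$k_variance,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(population = pp, n = n, haplotypes = sum(cnt > 0),
                 polymorphic_sites = 0L, hd = NA_real_, hd_variance = NA_real_,
                 pi = NA_real_, pi_variance = NA_real_, k = NA_real_,
                 k_variance = NA_real_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
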