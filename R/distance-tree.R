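## Cavalli-Sforza & Edwards chord distances between population
## allele-frequency profiles and the neighbour-joining population tree.

#' Population allele-frequency table
#'
#' Missing-aware per-population allele frequencies for every locus, with
#' hemizygous males single-counted at X-linked loci.
#'
#' @param panel a [genotype_panel()].
#' @return list per locus of allele x population frequency matrices (class
#'   `frequency_table`).
#' @export
frequency_table <- function(panel) {
  structure(allele_frequencies(panel, by = "population"),
            class = "frequency_table")
}

#' Cavalli-Sforza & Edwards chord distance between two populations
#'
#' Per locus, cos(theta_l) = sum_a sqrt(p_a q_a) measures the angular
#' separation of the square-root frequency vectors; distances are combined
#' as D = sqrt((1/L) * sum_l 2 (1 - cos theta_l)). The classic 2/pi
#' normalising prefactor (inside the square root as (2/pi)^2 is NOT applied
#' by default; `prefactor = TRUE` multiplies D by 2/pi for compatibility
#' with software using that convention.
#'
#' @param ft a [frequency_table()].
#' @param pop_a,pop_b population labels.
#' @param prefactor logical; apply the 2/pi convention.
#' @return the chord distance (>= 0; 0 iff identical frequencies at all
#'   shared loci).
#' @export
chord_distance <- function(ft, pop_a, pop_b, prefactor = FALSE) {
  terms <- c()
  for (l in seq_along(ft)) {
    pa <- ft[[l]][, pop_a]; pb <- ft[[l]][, pop_b]
    if (anyNA(pa) || anyNA(pb)) next
    cosd <- sum(sqrt(pa * pb))
    terms <- c(terms, 2 * (1 - min(cosd, 1)))
  }
  if (!length(terms)) stop("no shared scored loci between ", pop_a, " and ", pop_b)
  d <- sqrt(mean(terms))
  if (prefactor) d <- (2 / pi) * d
  d
}

#' Chord distance matrix over all populations
#'
#' @param panel a [genotype_panel()].
#' @param prefactor see [chord_distance()].
#' @return a [dist_matrix()] tagged "chord".
#' @export
chord_distance_matrix <- function(panel, prefactor = FALSE) {
  ft <- frequency_table(panel)
  pops <- unique(panel$individuals$population)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1)) {
      m[i, j] <- m[j, i] <- chord_distance(ft, pops[i], pops[j], prefactor)
    }
  }
  dist_matrix(m, "chord")
}

#' Neighbour-joining population tree
#'
#' Saitou-Nei neighbour joining on a labelled distance matrix (standard
#' Q-criterion, via ape), with negative branch lengths clamped to zero and
#' flagged. Label order is made deterministic before the call so ties break
#' reproducibly.
#'
#' @param m a [dist_matrix()] (or symmetric labelled matrix).
#' @return list with `tree` (ape `phylo`), `clamped` (count of negative
#'   branches clamped).
#' @export
neighbor_joining <- function(m) {
  m <- dist_matrix(unclass(as.matrix(m)), attr(m, "statistic") %||% "generic")
  if (nrow(m) < 3) stop("need at least 3 labels for neighbour joining")
  ord <- order(rownames(m))
  m2 <- unclass(m)[ord, ord]
  tree <- ape::nj(stats::as.dist(m2))
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  if (any(neg)) warning(sum(neg), " negative NJ branch length(s) clamped to 0")
  list(tree = tree, clamped = sum(neg))
}

#' Newick text for a tree
#' @param tree an ape `phylo` or a [neighbor_joining()] result.
#' @return single Newick string.
#' @export
to_newick <- function(tree) {
  if (is.list(tree) && !inherits(tree, "phylo") && !is.null(tree$tree)) {
    tree <- tree$tree
  }
  ape::write.tree(tree)
}
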