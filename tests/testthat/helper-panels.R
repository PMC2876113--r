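## Small builders shared across the test files.

## genotype panel straight from allele matrices (single region by default)
toy_panel <- function(a1, a2, pop = NULL, sex = NULL, region = NULL,
                      x_linked = NULL) {
  n <- nrow(a1)
  L <- ncol(a1)
  ind <- data.frame(
    id = sprintf("i%02d", seq_len(n)),
    sex = if (is.null(sex)) rep("F", n) else sex,
    population = if (is.null(pop)) rep("P1", n) else pop,
    region = if (is.null(region)) rep("R1", n) else region,
    stringsAsFactors = FALSE)
  loci <- data.frame(name = sprintf("L%02d", seq_len(L)),
                     x_linked = if (is.null(x_linked)) rep(FALSE, L) else x_linked,
                     stringsAsFactors = FALSE)
  genotype_panel(ind, loci, a1, a2)
}

## panel from a list of gene vectors (one per locus), paired into diploids
gene_panel <- function(genes_list, pop = "P", region = "R") {
  n <- length(genes_list[[1]]) / 2
  a1 <- sapply(genes_list, function(g) g[seq_len(n)]) + 500L
  a2 <- sapply(genes_list, function(g) g[n + seq_len(n)]) + 500L
  sw <- a1 > a2
  tmp <- a1[sw]; a1[sw] <- a2[sw]; a2[sw] <- tmp
  toy_panel(matrix(a1, n), matrix(a2, n), pop = rep(pop, n),
            region = rep(region, n))
}

## random valid panel for IO round-trip property tests
random_panel <- function(seed, n = 12, L = 4) {
  set.seed(seed)
  pops <- sample(c("north", "south"), n, replace = TRUE)
  region <- ifelse(pops == "north", "NR", "SR")
  sex <- sample(c("F", "M"), n, replace = TRUE)
  xl <- seq_len(L) <= 2
  a1 <- matrix(sample(c(NA, 101:109), n * L, replace = TRUE), n, L)
  a2 <- matrix(sample(c(NA, 101:109), n * L, replace = TRUE), n, L)
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA; a2[miss] <- NA
  sw <- !miss & a1 > a2
  tmp <- a1[sw]; a1[sw] <- a2[sw]; a2[sw] <- tmp
  # males hemizygous at X loci
  for (l in which(xl)) {
    m <- sex == "M" & !is.na(a1[, l])
    a2[m, l] <- NA
  }
  ind <- data.frame(id = sprintf("f%02d", seq_len(n)), sex = sex,
                    population = pops, region = region,
                    stringsAsFactors = FALSE)
  loci <- data.frame(name = c("XA", "XB", "C1", "C2")[seq_len(L)],
                     x_linked = xl, stringsAsFactors = FALSE)
  genotype_panel(ind, loci, a1, a2)
}

## equality up to individual order (the genotype formats group rows by
## population, so a round trip may reorder individuals)
panels_equal <- function(p, q) {
  op <- order(p$individuals$id); oq <- order(q$individuals$id)
  identical(unname(as.matrix(p$individuals[op, c("id", "sex", "population",
                                                 "region")])),
            unname(as.matrix(q$individuals[oq, c("id", "sex", "population",
                                                 "region")]))) &&
    identical(p$loci$name, q$loci$name) &&
    identical(p$loci$x_linked, q$loci$x_linked) &&
    identical(unname(p$a1[op, , drop = FALSE]),
              unname(q$a1[oq, , drop = FALSE])) &&
    identical(unname(p$a2[op, , drop = FALSE]),
              unname(q$a2[oq, , drop = FALSE]))
}
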