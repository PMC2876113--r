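#' Diploid/hemizygous microsatellite genotype panel
#'
#' A `genotype_panel` holds allele-size calls for a set of individuals at a
#' set of microsatellite loci, together with the two-level sampling design
#' (populations nested in regions), individual sex, and per-locus X-linkage.
#' Males carry a single allele (hemizygous) at X-linked loci; that single
#' call is stored once in `a1` with `a2 = NA`. A fully missing genotype has
#' both `a1` and `a2` missing. Allele codes are integer fragment sizes, so
#' stepwise mutation distances between alleles are meaningful.
#'
#' @param individuals data.frame with columns `id`, `sex` ("F"/"M"),
#'   `population`, `region`.
#' @param loci data.frame with columns `name` and logical `x_linked`.
#' @param a1,a2 integer matrices (individuals x loci) of allele codes;
#'   `NA` marks a missing allele.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(individuals, loci, a1, a2) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  dimnames(a1) <- dimnames(a2) <- list(individuals$id, loci$name)
  p <- structure(
    list(individuals = individuals, loci = loci, a1 = a1, a2 = a2),
    class = "genotype_panel"
  )
  validate_genotype_panel(p)
  p
}

#' Validate a genotype panel
#'
#' Checks structural invariants: matching dimensions, one population per
#' individual, one region per population, no male heterozygote at an
#' X-linked locus, hemizygous storage normalised (a2 missing when a1 holds a
#' male X call). Males stored as X-linked "homozygotes" are normalised to
#' single calls rather than rejected.
#'
#' @param p a `genotype_panel`.
#' @return `p`, invisibly (possibly with normalised hemizygous storage).
#' @export
validate_genotype_panel <- function(p) {
  ind <- p$individuals
  stopifnot(
    is.data.frame(ind),
    all(c("id", "sex", "population", "region") %in% names(ind)),
    all(c("name", "x_linked") %in% names(p$loci)),
    nrow(p$a1) == nrow(ind), ncol(p$a1) == nrow(p$loci),
    identical(dim(p$a1), dim(p$a2))
  )
  if (anyDuplicated(ind$id)) stop("duplicated individual ids")
  if (!all(ind$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  reg_per_pop <- tapply(ind$region, ind$population, function(r) length(unique(r)))
  if (any(reg_per_pop > 1)) {
    stop("population assigned to more than one region: ",
         paste(names(reg_per_pop)[reg_per_pop > 1], collapse = ", "))
  }
  male <- ind$sex == "M"
  xl <- which(p$loci$x_linked)
  for (l in xl) {
    het <- male & !is.na(p$a1[, l]) & !is.na(p$a2[, l]) & p$a1[, l] != p$a2[, l]
    if (any(het)) {
      stop("male heterozygote at X-linked locus '", p$loci$name[l], "': ",
           paste(ind$id[het], collapse = ", "))
    }
  }
  # single-allele call only legal for hemizygous males at X loci
  half <- (!is.na(p$a1) & is.na(p$a2)) | (is.na(p$a1) & !is.na(p$a2))
  legal <- outer(male, seq_len(nrow(p$loci)) %in% xl, "&")
  if (any(half & !legal)) stop("single-allele call outside male/X-linked cells")
  invisible(p)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$individuals), "individuals,",
      nrow(x$loci), "loci (", sum(x$loci$x_linked), "X-linked ),",
      length(unique(x$individuals$population)), "populations in",
      length(unique(x$individuals$region)), "regions\n")
  invisible(x)
}

#' Normalise male X-linked homozygote calls to hemizygous storage
#' @keywords internal
normalise_hemizygous <- function(p) {
  male <- p$individuals$sex == "M"
  for (l in which(p$loci$x_linked)) {
    hom <- male & !is.na(p$a1[, l]) & !is.na(p$a2[, l]) & p$a1[, l] == p$a2[, l]
    p$a2[hom, l] <- NA_integer_
    # call may have arrived only in a2
    only2 <- male & is.na(p$a1[, l]) & !is.na(p$a2[, l])
    p$a1[only2, l] <- p$a2[only2, l]
    p$a2[only2, l] <- NA_integer_
  }
  p
}

#' Analysis views of the allele-call matrices
#'
#' X-linked loci are handled differently by different analyses, so the raw
#' hemizygous storage is converted on demand:
#' \describe{
#'   \item{raw}{hemizygous males keep their single call (gene counting,
#'     allele frequencies: males counted once).}
#'   \item{pseudodiploid}{males at X-linked loci are coded homozygous for
#'     their single allele (differentiation and linkage analyses).}
#'   \item{females_only_x}{males at X-linked loci are set missing
#'     (inbreeding / heterozygosity analyses).}
#' }
#'
#' @param p a `genotype_panel`.
#' @param x_mode one of "raw", "pseudodiploid", "females_only_x".
#' @return list with integer matrices `a1`, `a2`.
#' @export
genotype_matrices <- function(p, x_mode = c("raw", "pseudodiploid", "females_only_x")) {
  x_mode <- match.arg(x_mode)
  a1 <- p$a1; a2 <- p$a2
  male <- p$individuals$sex == "M"
  for (l in which(p$loci$x_linked)) {
    if (x_mode == "pseudodiploid") {
      hemi <- male & !is.na(a1[, l]) & is.na(a2[, l])
      a2[hemi, l] <- a1[hemi, l]
    } else if (x_mode == "females_only_x") {
      a1[male, l] <- NA_integer_
      a2[male, l] <- NA_integer_
    }
  }
  list(a1 = a1, a2 = a2)
}

#' Per-locus gene counts by group
#'
#' Gene counting respects hemizygosity: at X-linked loci a male contributes
#' one gene, a female two.
#'
#' @param p a `genotype_panel`.
#' @param by grouping column ("population" or "region").
#' @return named list per locus of matrices (alleles x groups) of gene counts.
#' @export
allele_counts <- function(p, by = "population") {
  grp <- factor(p$individuals[[by]])
  out <- vector("list", nrow(p$loci))
  names(out) <- p$loci$name
  for (l in seq_len(nrow(p$loci))) {
    genes <- c(p$a1[, l], p$a2[, l])
    g2 <- factor(c(as.character(grp), as.character(grp)), levels = levels(grp))
    keep <- !is.na(genes)
    tab <- table(allele = factor(genes[keep]), group = g2[keep])
    out[[l]] <- unclass(tab)
  }
  out
}

#' Allele frequencies per population per locus
#'
#' Missing-aware; X-linked males are single-counted (raw view). Populations
#' with no scored genes at a locus get an all-NA column.
#'
#' @param p a `genotype_panel`.
#' @param by grouping column.
#' @return list per locus of allele x group frequency matrices.
#' @export
allele_frequencies <- function(p, by = "population") {
  cnt <- allele_counts(p, by = by)
  lapply(cnt, function(tab) {
    n <- colSums(tab)
    f <- sweep(tab, 2, n, "/")
    f[, n == 0] <- NA_real_
    f
  })
}

#' Subset a genotype panel by individuals and/or loci
#' @param p a `genotype_panel`.
#' @param individuals logical/integer/character index into individuals.
#' @param loci logical/integer/character index into loci.
#' @return a `genotype_panel`.
#' @export
subset_panel <- function(p, individuals = NULL, loci = NULL) {
  ii <- seq_len(nrow(p$individuals))
  if (!is.null(individuals)) {
    ii <- if (is.character(individuals)) match(individuals, p$individuals$id) else ii[individuals]
  }
  ll <- seq_len(nrow(p$loci))
  if (!is.null(loci)) {
    ll <- if (is.character(loci)) match(loci, p$loci$name) else ll[loci]
  }
  genotype_panel(p$individuals[ii, , drop = FALSE], p$loci[ll, , drop = FALSE],
                 p$a1[ii, ll, drop = FALSE], p$a2[ii, ll, drop = FALSE])
}

#' Drop loci by name (QC exclusion lists)
#' @param p a `genotype_panel`.
#' @param exclude character vector of locus names to drop.
#' @return a `genotype_panel`.
#' @export
exclude_loci <- function(p, exclude) {
  keep <- !(p$loci$name %in% exclude)
  if (!any(keep)) stop("exclusion list removes every locus")
  subset_panel(p, loci = keep)
}
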