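## Mantel tests between marker distance matrices and the pipeline
## orchestrator.

#' Mantel test between two labelled distance matrices
#'
#' Pearson correlation of the off-diagonal upper-triangle entries, with a
#' null distribution generated by simultaneous row/column permutation of
#' the second matrix. One-sided P toward positive association (the study
#' tests concordance among marker systems). R^2 = r^2 is the share of
#' variance in one matrix explained by the other.
#'
#' @param mat_a,mat_b [dist_matrix()] objects (or labelled symmetric
#'   matrices) with identical labels.
#' @param n_perm permutations (study default 10000).
#' @param seed integer seed.
#' @return object of class `mantel_result`: `r`, `r_squared`, `p_value`,
#'   `n_perm`, `seed`, matrix tags.
#' @export
mantel <- function(mat_a, mat_b, n_perm = 1000, seed = 1) {
  a <- as.matrix(mat_a); b <- as.matrix(mat_b)
  if (!identical(dim(a), dim(b))) stop("matrix sizes differ")
  if (nrow(a) < 4) stop("need at least 4 labels for a Mantel test")
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b))) stop("matrix labels differ")
    b <- b[rownames(a), rownames(a)]
  }
  ut <- upper.tri(a)
  if (stats::sd(a[ut]) == 0 || stats::sd(b[ut]) == 0) {
    stop("zero-variance distance matrix: Mantel r undefined")
  }
  set.seed(seed)
  r_obs <- stats::cor(a[ut], b[ut])
  n <- nrow(a)
  ge <- 0L
  for (i in seq_len(n_perm)) {
    o <- sample.int(n)
    bp <- b[o, o]
    if (stats::cor(a[ut], bp[ut]) >= r_obs - 1e-12) ge <- ge + 1L
  }
  structure(list(r = r_obs, r_squared = r_obs^2,
                 p_value = (ge + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed,
                 tags = c(attr(mat_a, "statistic") %||% "generic",
                          attr(mat_b, "statistic") %||% "generic")),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel %s ~ %s: r = %.3f (R2 = %.3f), one-sided P = %.4g\n",
              x$tags[1], x$tags[2], x$r, x$r_squared, x$p_value))
  invisible(x)
}

#' Kst* pairwise distance matrix between populations
#'
#' Convenience builder for the integration stage: pairwise Kst* values from
#' [hudson_differentiation()], with negative estimates kept (the matrix is
#' offset to be non-negative only on request).
#'
#' @param panel a [sequence_panel()].
#' @param n_perm permutations per pair (P-values recorded as an attribute).
#' @param seed integer seed.
#' @param clamp_negative set tiny negative estimates to zero so the result
#'   is a valid distance matrix (default TRUE).
#' @return a [dist_matrix()] tagged "kst".
#' @export
kst_distance_matrix <- function(panel, n_perm = 100, seed = 1,
                                clamp_negative = TRUE) {
  pops <- unique(panel$records$population)
  G <- length(pops)
  m <- matrix(0, G, G, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, G, G, dimnames = list(pops, pops))
  for (i in seq_len(G)) {
    for (j in seq_len(i - 1)) {
      # two populations fixed for the same haplotype carry no signal of
      # differentiation: Kst* = 0, P = 1
      hd <- tryCatch(
        hudson_differentiation(panel, pops[i], pops[j],
                               n_perm = n_perm, seed = seed + i * G + j),
        error = function(e) {
          if (grepl("monomorphic", conditionMessage(e))) {
            list(kst_star = 0, p_kst = 1)
          } else {
            stop(e)
          }
        })
      v <- hd$kst_star
      if (clamp_negative) v <- max(v, 0)
      m[i, j] <- m[j, i] <- v
      pv[i, j] <- pv[j, i] <- hd$p_kst
    }
  }
  out <- dist_matrix(m, "kst")
  attr(out, "p_values") <- pv
  out
}

#' Run the full multi-marker pipeline on a simulation config
#'
#' Executes the stages in order: simulate -> locus QC -> F-statistics ->
#' effective sizes -> bottleneck -> chord distance tree -> mtDNA
#' statistics -> morphometrics -> Mantel integration, honouring the QC
#' exclusion list downstream, and optionally writes a plain-text report
#' directory (TSV tables, Newick tree, network edge list, JSON summary).
#'
#' @param config a [sim_config()].
#' @param seed integer seed controlling every stage.
#' @param out_dir optional directory for the report files.
#' @param n_perm permutation count for the genetic tests (morphometric
#'   pairs use 1000 at most).
#' @param bottleneck_reps equilibrium replicates per locus for the
#'   bottleneck stage (0 skips the stage).
#' @return object of class `pipeline_report` (a list of stage outputs).
#' @export
run_pipeline <- function(config, seed = 1, out_dir = NULL, n_perm = 200,
                         bottleneck_reps = 200) {
  report <- list(config = config, seed = seed)
  panel <- simulate_microsat_panel(config, seed = seed)
  coi <- simulate_coi_panel(config, seed = seed + 1)
  wings <- simulate_landmarks(config, seed = seed + 2)
  report$panel <- panel

  # locus QC
  nulls <- lapply(panel$loci$name, function(l)
    brookfield2_null_frequency(panel, l, pooled = FALSE))
  names(nulls) <- panel$loci$name
  blanks <- expected_blanks_test(panel, nulls)
  ld <- ld_pairwise_tests(panel, n_perm = n_perm, seed = seed + 3)
  n_sig <- sum(ld$tests$p_value <= 0.05)
  ld_global <- significant_count_binomial(n_sig, nrow(ld$tests))
  exclusion <- panel$loci$name[vapply(nulls, function(x)
    !isTRUE(x$undefined) && !is.na(x$p_n) && x$p_n > 0.1, TRUE)]
  report$qc <- list(null_alleles = nulls, blanks = blanks, ld = ld,
                    ld_global_p = ld_global, exclusion = exclusion)

  # F-statistics
  wc <- weir_cockerham(panel)
  hier <- hierarchical_fstats(panel)
  f_test <- permutation_test(panel, "alleles_within_subsamples",
                             n_perm = n_perm, seed = seed + 4)
  fst_test <- permutation_test(panel, "individuals_among_subsamples",
                               n_perm = n_perm, seed = seed + 5)
  cis <- fstat_confidence_intervals(panel, "theta", n_boot = 200,
                                    seed = seed + 6)
  div <- nei_gene_diversity(panel)
  regions <- unique(panel$individuals$region)
  reg_div <- if (length(regions) == 2) {
    compare_region_diversity(div, regions[1], regions[2])
  } else NULL
  report$fstats <- list(wc = wc, hierarchical = hier, f_test = f_test,
                        fst_test = fst_test, ci = cis, diversity = div,
                        region_diversity = reg_div)

  # effective sizes (null/stutter loci excluded from intra-locus method)
  pops <- unique(panel$individuals$population)
  keep_panel <- tryCatch(exclude_loci(panel, report$qc$exclusion),
                         error = function(e) panel)
  report$ne <- lapply(pops, function(pp) {
    list(ld = ld_ne(panel, pp),
         het_excess = het_excess_ne(keep_panel, pp))
  })
  names(report$ne) <- pops

  # bottleneck
  if (bottleneck_reps > 0) {
    report$bottleneck <- lapply(pops, function(pp) {
      lapply(c("IAM", "TPM", "SMM"), function(mm) {
        tryCatch(bottleneck_test(keep_panel, pp, mm,
                                 n_reps = bottleneck_reps, seed = seed + 7),
                 error = function(e) list(error = conditionMessage(e)))
      })
    })
    names(report$bottleneck) <- pops
  }

  # distances + tree
  chord <- chord_distance_matrix(panel)
  njt <- neighbor_joining(chord)
  report$tree <- list(chord = chord, nj = njt, newick = to_newick(njt))

  # mtDNA
  ht <- collapse_haplotypes(coi)
  divtab <- sequence_diversity_table(coi)
  kst <- kst_distance_matrix(coi, n_perm = n_perm, seed = seed + 8)
  net <- parsimony_network(ht, connection_limit = 11)
  report$mtdna <- list(haplotypes = ht, diversity = divtab, kst = kst,
                       network = net)

  # morphometrics
  g <- gpa(wings)
  sv <- partial_warps(g)
  cva <- mahalanobis_cva(sv, n_perm = min(n_perm, 1000), seed = seed + 9)
  report$morpho <- list(gpa = g, shape = sv, cva = cva)

  # Mantel integration
  dm <- cva$d
  report$mantel <- list(
    chord_kst = mantel(chord, kst, n_perm = n_perm, seed = seed + 10),
    chord_mahalanobis = mantel(chord, dm, n_perm = n_perm, seed = seed + 11),
    kst_mahalanobis = mantel(kst, dm, n_perm = n_perm, seed = seed + 12))

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' Write a pipeline report to a directory of plain-text artefacts
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  w(report$fstats$wc$per_locus, "fstats_per_locus.tsv")
  w(report$mtdna$diversity, "mtdna_diversity.tsv")
  w(report$morpho$cva$reclassification, "reclassification.tsv")
  if (nrow(report$qc$ld$tests)) w(report$qc$ld$tests, "ld_tests.tsv")
  writeLines(report$tree$newick, file.path(out_dir, "chord_nj.nwk"))
  if (nrow(report$mtdna$network$edges)) {
    w(report$mtdna$network$edges, "haplotype_network_edges.tsv")
  }
  mantel_df <- do.call(rbind, lapply(names(report$mantel), function(nm) {
    m <- report$mantel[[nm]]
    data.frame(pair = nm, r = m$r, r_squared = m$r_squared,
               p_value = m$p_value, n_perm = m$n_perm)
  }))
  w(mantel_df, "mantel.tsv")
  summ <- list(
    seed = report$seed,
    theta = report$fstats$wc$theta,
    f_is = report$fstats$wc$f,
    f_sr = report$fstats$hierarchical$F_SR,
    f_rt = report$fstats$hierarchical$F_RT,
    mantel = stats::setNames(lapply(report$mantel, function(m)
      list(r = m$r, p = m$p_value)), names(report$mantel)))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
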