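## Sequence, landmark, distance-matrix and tree IO.

#' Aligned sequence panel
#'
#' @param records data.frame with columns `id`, `population`, `region`.
#' @param seqs character vector of aligned sequences over A,C,G,T,N,-.
#' @return object of class `sequence_panel` with the alignment length.
#' @export
sequence_panel <- function(records, seqs) {
  seqs <- toupper(as.character(seqs))
  lens <- unique(nchar(seqs))
  if (length(seqs) == 0) stop("empty sequence panel")
  if (length(lens) != 1) {
    stop("ragged alignment: sequence lengths ", paste(sort(lens), collapse = ", "))
  }
  structure(list(records = as.data.frame(records, stringsAsFactors = FALSE),
                 seqs = seqs, length = lens),
            class = "sequence_panel")
}

#' @export
print.sequence_panel <- function(x, ...) {
  cat("sequence_panel:", length(x$seqs), "sequences,", x$length, "sites,",
      length(unique(x$records$population)), "populations\n")
  invisible(x)
}

#' Read an aligned FASTA file into a sequence panel
#'
#' Record names follow the "region|population|id" convention; names without
#' separators become ids in a single population/region.
#'
#' @param path FASTA path.
#' @return a [sequence_panel()].
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nms <- names(ss)
  parts <- lapply(nms, split_name, i = 0)
  records <- data.frame(
    id = vapply(parts, `[[`, "", "id"),
    population = vapply(parts, function(p) if (is.na(p$pop)) "pop_1" else p$pop, ""),
    region = vapply(parts, `[[`, "", "region"),
    stringsAsFactors = FALSE)
  sequence_panel(records, as.character(ss))
}

#' Write a sequence panel to FASTA
#' @param panel a [sequence_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(panel, path) {
  nms <- paste(panel$records$region, panel$records$population,
               panel$records$id, sep = "|")
  ss <- Biostrings::BStringSet(panel$seqs)
  names(ss) <- nms
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Landmark panel
#'
#' @param coords numeric array n x k x 2 of landmark coordinates.
#' @param group character/factor of group labels, length n.
#' @param ids individual identifiers.
#' @return object of class `landmark_panel`.
#' @export
landmark_panel <- function(coords, group, ids = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 2)
  if (dim(coords)[2] < 4) stop("need k >= 4 landmarks for shape variables")
  if (!all(is.finite(coords))) stop("non-finite landmark coordinates")
  n <- dim(coords)[1]
  if (is.null(ids)) ids <- paste0("ind_", seq_len(n))
  stopifnot(length(group) == n, length(ids) == n)
  structure(list(coords = coords, group = as.character(group), ids = ids,
                 k = dim(coords)[2]),
            class = "landmark_panel")
}

#' Read 2D landmark configurations (TPS or CSV)
#'
#' TPS blocks must share the same LM= count; the ID= line may carry the
#' group as "group|id". The CSV mirror has columns
#' `id`, `group`, `x1`, `y1`, ..., `xk`, `yk`.
#'
#' @param path input path.
#' @param format "tps" or "csv".
#' @return a [landmark_panel()].
#' @export
read_landmarks <- function(path, format = c("tps", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    xc <- grep("^x[0-9]+$", names(df)); yc <- grep("^y[0-9]+$", names(df))
    k <- length(xc)
    coords <- array(NA_real_, c(nrow(df), k, 2))
    coords[, , 1] <- as.matrix(df[, xc])
    coords[, , 2] <- as.matrix(df[, yc])
    return(landmark_panel(coords, df$group, df$id))
  }
  lines <- readLines(path, warn = FALSE)
  lm_at <- grep("^LM=", lines)
  if (length(lm_at) == 0) stop("TPS parse error: no LM= record")
  ks <- as.integer(sub("^LM=", "", lines[lm_at]))
  if (length(unique(ks)) != 1) {
    stop("TPS records disagree on landmark count: ", paste(unique(ks), collapse = ", "))
  }
  k <- ks[1]
  n <- length(lm_at)
  coords <- array(NA_real_, c(n, k, 2))
  ids <- character(n); grp <- character(n)
  for (i in seq_len(n)) {
    block <- lines[(lm_at[i] + 1):(lm_at[i] + k)]
    xy <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
    if (nrow(xy) != k || ncol(xy) != 2 || anyNA(xy)) {
      stop("TPS parse error in record ", i, ": expected ", k, " x/y rows")
    }
    coords[i, , ] <- xy
    stop_at <- if (i < n) lm_at[i + 1] - 1 else length(lines)
    idl <- grep("^ID=", lines[(lm_at[i] + k):stop_at], value = TRUE)
    nm <- if (length(idl)) sub("^ID=", "", idl[1]) else paste0("ind_", i)
    bits <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (length(bits) >= 2) {
      grp[i] <- bits[1]; ids[i] <- paste(bits[-1], collapse = "|")
    } else {
      grp[i] <- "G1"; ids[i] <- nm
    }
  }
  landmark_panel(coords, grp, ids)
}

#' Write a landmark panel (TPS or CSV)
#' @param panel a [landmark_panel()].
#' @param path output path.
#' @param format "tps" or "csv".
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(panel, path, format = c("tps", "csv")) {
  format <- match.arg(format)
  n <- dim(panel$coords)[1]; k <- panel$k
  if (format == "csv") {
    m <- matrix(NA_real_, n, 2 * k)
    m[, seq(1, 2 * k, 2)] <- panel$coords[, , 1]
    m[, seq(2, 2 * k, 2)] <- panel$coords[, , 2]
    df <- data.frame(id = panel$ids, group = panel$group, m)
    names(df) <- c("id", "group", as.vector(rbind(paste0("x", 1:k), paste0("y", 1:k))))
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(paste0("LM=", k), con)
    writeLines(paste(format(panel$coords[i, , 1], trim = TRUE),
                     format(panel$coords[i, , 2], trim = TRUE)), con)
    writeLines(paste0("ID=", panel$group[i], "|", panel$ids[i]), con)
  }
  invisible(path)
}

#' Labelled symmetric distance matrix
#'
#' @param m square numeric matrix, symmetric, zero diagonal, labels as
#'   dimnames.
#' @param statistic tag: "chord", "kst", "mahalanobis" or "generic".
#' @return the matrix with class `dist_matrix` and a `statistic` attribute.
#' @export
dist_matrix <- function(m, statistic = "generic") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix not square")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal not zero")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("unit_", seq_len(nrow(m)))
  structure(m, class = c("dist_matrix", "matrix"), statistic = statistic)
}

#' Read/write a PHYLIP square distance matrix
#'
#' @param path file path.
#' @return for the reader, a [dist_matrix()].
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1) stop("phylip parse error: bad header")
  labs <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(f) != n + 1) stop("phylip parse error at row ", i)
    labs[i] <- f[1]
    m[i, ] <- as.numeric(f[-1])
  }
  dimnames(m) <- list(labs, labs)
  dist_matrix(m)
}

#' @rdname read_distance_matrix
#' @param m a [dist_matrix()] (or plain labelled symmetric matrix).
#' @export
write_distance_matrix <- function(m, path) {
  m <- dist_matrix(unclass(m), attr(m, "statistic") %||% "generic")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(format(nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(rownames(m)[i],
                     paste(formatC(m[i, ], format = "g", digits = 10), collapse = " ")), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a phylogenetic tree as Newick text
#' @param tree an ape `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
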