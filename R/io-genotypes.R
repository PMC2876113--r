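## Genotype file IO: Genepop 4.x, FSTAT .dat, and a CSV mirror.
## Individual names carry the design as "region|population|id"; when absent,
## populations are auto-named and assigned to a single region. X-linkage is
## taken from an explicit `x_linked` argument (wins) or the locus-name "X"
## prefix convention.

#' Read a genotype file
#'
#' @param path file path.
#' @param dialect "genepop", "fstat" or "csv".
#' @param x_linked optional character vector of X-linked locus names;
#'   overrides the "X" name-prefix convention.
#' @param meta optional data.frame (or path to a CSV) with columns
#'   `id`, `sex`, `population`, `region` keyed by individual id; needed for
#'   the FSTAT dialect which stores neither ids nor sex.
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, dialect = c("genepop", "fstat", "csv"),
                           x_linked = NULL, meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(meta)) {
    meta <- utils::read.csv(meta, stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  switch(dialect,
    genepop = read_genepop(path, x_linked, meta),
    fstat = read_fstat(path, x_linked, meta),
    csv = read_genotypes_csv(path, x_linked)
  )
}

#' Write a genotype file
#'
#' Hemizygous male calls at X-linked loci are encoded as homozygotes in the
#' diploid dialects (genepop, fstat) and recovered as single calls on read.
#' Missing genotypes are written as all-zero codes.
#'
#' @param p a [genotype_panel()].
#' @param path output path.
#' @param dialect "genepop", "fstat" or "csv".
#' @param digits allele-code width (2 or 3); codes must fit.
#' @return `path`, invisibly. For "fstat" a sidecar `<path>.meta.csv`
#'   carrying ids/sex/region is written alongside.
#' @export
write_genotypes <- function(p, path, dialect = c("genepop", "fstat", "csv"),
                            digits = 3) {
  dialect <- match.arg(dialect)
  validate_genotype_panel(p)
  if (nrow(p$individuals) == 0) stop("panel has no individuals")
  pops <- unique(p$individuals$population)
  if (any(table(p$individuals$population) == 0) || length(pops) == 0) {
    stop("panel has an empty population")
  }
  amax <- suppressWarnings(max(c(p$a1, p$a2), na.rm = TRUE))
  if (!is.finite(amax)) amax <- 0L
  if (amax >= 10^digits) {
    stop("allele code ", amax, " does not fit in ", digits, " digits")
  }
  switch(dialect,
    genepop = write_genepop(p, path, digits),
    fstat = write_fstat(p, path, digits),
    csv = write_genotypes_csv(p, path)
  )
  invisible(path)
}

fmt_code <- function(a, digits) {
  out <- formatC(ifelse(is.na(a), 0L, a), width = digits, flag = "0")
  out
}

## individual-name convention: "region|population|sex|id" (full),
## "region|population|id" (sex defaults to F), "population|id", or bare id.
split_name <- function(nm, i) {
  parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 4 && parts[3] %in% c("F", "M")) {
    list(region = parts[1], pop = parts[2], sex = parts[3],
         id = paste(parts[-(1:3)], collapse = "|"))
  } else if (length(parts) == 3) {
    list(region = parts[1], pop = parts[2], sex = "F", id = parts[3])
  } else if (length(parts) == 2) {
    list(region = "R1", pop = parts[1], sex = "F", id = parts[2])
  } else {
    list(region = "R1", pop = NA_character_, sex = "F", id = nm)
  }
}

infer_x <- function(locus_names, x_linked) {
  if (!is.null(x_linked)) return(locus_names %in% x_linked)
  startsWith(locus_names, "X")
}

## sex inference when no metadata: an individual with any single-allele call
## at an X-linked locus must be male; with metadata the declared sex wins.
finish_panel <- function(ids, sex, pop, region, loci, xl, a1, a2, meta) {
  if (!is.null(meta)) {
    m <- meta[match(ids, meta$id), ]
    if (anyNA(m$id)) stop("metadata missing ids: ",
                          paste(ids[is.na(m$id)], collapse = ", "))
    sex <- m$sex
    if (!is.null(m$population)) pop <- m$population
    if (!is.null(m$region)) region <- m$region
  }
  p <- structure(
    list(individuals = data.frame(id = ids, sex = sex, population = pop,
                                  region = region, stringsAsFactors = FALSE),
         loci = data.frame(name = loci, x_linked = xl, stringsAsFactors = FALSE),
         a1 = a1, a2 = a2),
    class = "genotype_panel")
  p <- normalise_hemizygous(p)
  validate_genotype_panel(p)
  dimnames(p$a1) <- dimnames(p$a2) <- list(ids, loci)
  p
}

## ---- Genepop ----

read_genepop <- function(path, x_linked, meta) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("genepop parse error: file too short")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("genepop parse error: no POP line")
  header <- lines[2:(first_pop - 1)]
  # locus names may be one per line or comma-separated on one line
  loci <- trimws(unlist(strsplit(paste(header, collapse = ","), ",")))
  loci <- loci[nzchar(loci)]
  xl <- infer_x(loci, x_linked)
  ids <- character(); sex <- character(); pop <- character(); region <- character()
  rows1 <- list(); rows2 <- list()
  pop_i <- 0L; width <- NA_integer_
  for (ln in seq(first_pop, length(lines))) {
    line <- lines[ln]
    if (toupper(trimws(line)) == "POP") { pop_i <- pop_i + 1L; next }
    halves <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(halves) < 2) stop("genepop parse error at line ", ln, ": no comma")
    nm <- trimws(halves[1])
    codes <- strsplit(trimws(paste(halves[-1], collapse = ",")), "\\s+")[[1]]
    if (length(codes) != length(loci)) {
      stop("genepop parse error at line ", ln, ": ", length(codes),
           " genotypes for ", length(loci), " loci")
    }
    w <- unique(nchar(codes)) / 2
    if (length(unique(nchar(codes))) != 1 || w != floor(w)) {
      stop("genepop parse error at line ", ln, ": inconsistent code width")
    }
    if (is.na(width)) width <- as.integer(w)
    if (w != width) stop("genepop parse error at line ", ln, ": code width changed")
    g1 <- as.integer(substr(codes, 1, width))
    g2 <- as.integer(substr(codes, width + 1, 2 * width))
    g1[g1 == 0L] <- NA_integer_
    g2[g2 == 0L] <- NA_integer_
    nm3 <- split_name(nm, ln)
    ids <- c(ids, nm3$id)
    sex <- c(sex, nm3$sex)
    pop <- c(pop, if (is.na(nm3$pop)) paste0("pop_", pop_i) else nm3$pop)
    region <- c(region, nm3$region)
    rows1[[length(rows1) + 1L]] <- g1
    rows2[[length(rows2) + 1L]] <- g2
  }
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  finish_panel(ids, sex, pop, region, loci, xl, a1, a2, meta)
}

write_genepop <- function(p, path, digits) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("tsetsepop genotype export", con)
  writeLines(p$loci$name, con)
  ind <- p$individuals
  for (pp in unique(ind$population)) {
    writeLines("POP", con)
    rows <- which(ind$population == pp)
    for (i in rows) {
      a1 <- p$a1[i, ]; a2 <- p$a2[i, ]
      # hemizygous single call -> homozygote in the diploid encoding
      hemi <- !is.na(a1) & is.na(a2)
      a2[hemi] <- a1[hemi]
      codes <- paste0(fmt_code(a1, digits), fmt_code(a2, digits))
      nm <- paste(ind$region[i], ind$population[i], ind$sex[i], ind$id[i], sep = "|")
      writeLines(paste0(nm, " , ", paste(codes, collapse = " ")), con)
    }
  }
}

## ---- FSTAT .dat ----

read_fstat <- function(path, x_linked, meta) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 4 || anyNA(hdr)) stop("fstat parse error: bad header")
  np <- hdr[1]; nl <- hdr[2]; digits <- hdr[4]
  loci <- trimws(lines[2:(1 + nl)])
  xl <- infer_x(loci, x_linked)
  body <- lines[-(1:(1 + nl))]
  ids <- character(); pop <- character()
  rows1 <- list(); rows2 <- list()
  for (ln in seq_along(body)) {
    f <- strsplit(trimws(body[ln]), "\\s+")[[1]]
    if (length(f) != nl + 1) stop("fstat parse error at data line ", ln)
    pi <- as.integer(f[1])
    if (is.na(pi) || pi < 1 || pi > np) stop("fstat parse error at data line ", ln, ": pop index")
    codes <- f[-1]
    g1 <- as.integer(substr(codes, 1, digits))
    g2 <- as.integer(substr(codes, digits + 1, 2 * digits))
    g1[g1 == 0L] <- NA_integer_
    g2[g2 == 0L] <- NA_integer_
    ids <- c(ids, paste0("ind_", ln))
    pop <- c(pop, paste0("pop_", pi))
    rows1[[ln]] <- g1; rows2[[ln]] <- g2
  }
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  if (is.null(meta) && file.exists(paste0(path, ".meta.csv"))) {
    meta <- utils::read.csv(paste0(path, ".meta.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  if (!is.null(meta)) ids <- meta$id[seq_along(ids)]
  finish_panel(ids, rep("F", length(ids)), pop, rep("R1", length(ids)),
               loci, xl, a1, a2, meta)
}

write_fstat <- function(p, path, digits) {
  ind <- p$individuals
  pops <- unique(ind$population)
  amax <- suppressWarnings(max(c(p$a1, p$a2), na.rm = TRUE))
  if (!is.finite(amax)) amax <- 1L
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(length(pops), nrow(p$loci), amax, digits), con)
  writeLines(p$loci$name, con)
  ord <- order(match(ind$population, pops))
  for (i in ord) {
    a1 <- p$a1[i, ]; a2 <- p$a2[i, ]
    hemi <- !is.na(a1) & is.na(a2)
    a2[hemi] <- a1[hemi]
    codes <- paste0(fmt_code(a1, digits), fmt_code(a2, digits))
    writeLines(paste(match(ind$population[i], pops),
                     paste(codes, collapse = " ")), con)
  }
  utils::write.csv(ind[ord, ], paste0(path, ".meta.csv"), row.names = FALSE)
}

## ---- CSV mirror ----
## Columns: id, sex, population, region, then one column per locus with
## "a1/a2" calls ("150/152"), single codes for hemizygous males, "" missing.
## A leading comment line records X-linkage explicitly.

read_genotypes_csv <- function(path, x_linked) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#x_linked=")) {
    xl_names <- strsplit(sub("^#x_linked=", "", first), ",")[[1]]
    xl_names <- xl_names[nzchar(xl_names)]
    if (is.null(x_linked)) x_linked <- xl_names
    df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  fixed <- c("id", "sex", "population", "region")
  if (!all(fixed %in% names(df))) stop("csv parse error: missing design columns")
  loci <- setdiff(names(df), fixed)
  xl <- infer_x(loci, x_linked)
  n <- nrow(df)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (l in seq_along(loci)) {
    cell <- as.character(df[[loci[l]]])
    has <- !is.na(cell) & nzchar(cell)
    parts <- strsplit(cell[has], "/", fixed = TRUE)
    a1[has, l] <- as.integer(vapply(parts, `[`, "", 1))
    a2[has, l] <- as.integer(vapply(parts, function(x) if (length(x) > 1) x[2] else NA_character_, ""))
  }
  finish_panel(df$id, df$sex, df$population, df$region, loci, xl, a1, a2, NULL)
}

write_genotypes_csv <- function(p, path) {
  ind <- p$individuals
  cells <- matrix("", nrow(ind), nrow(p$loci))
  for (l in seq_len(nrow(p$loci))) {
    a1 <- p$a1[, l]; a2 <- p$a2[, l]
    full <- !is.na(a1) & !is.na(a2)
    hemi <- !is.na(a1) & is.na(a2)
    cells[full, l] <- paste0(a1[full], "/", a2[full])
    cells[hemi, l] <- as.character(a1[hemi])
  }
  df <- cbind(ind[, c("id", "sex", "population", "region")],
              as.data.frame(cells, stringsAsFactors = FALSE))
  names(df) <- c("id", "sex", "population", "region", p$loci$name)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#x_linked=", paste(p$loci$name[p$loci$x_linked], collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE)
}
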