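test_that("genotype files round-trip through every dialect", {
  for (seed in 1:8) {
    p <- random_panel(seed)
    for (dialect in c("genepop", "fstat", "csv")) {
      path <- tempfile(fileext = paste0(".", dialect))
      write_genotypes(p, path, dialect)
      q <- read_genotypes(path, dialect)
      expect_true(panels_equal(p, q),
                  label = sprintf("%s round trip, seed %d", dialect, seed))
    }
  }
})

test_that("missing genotypes are written as all-zero codes and recovered", {
  a1 <- matrix(c(101L, NA, 103L, 101L), 2, 2)
  a2 <- matrix(c(102L, NA, 103L, 104L), 2, 2)
  p <- toy_panel(a1, a2)
  path <- tempfile()
  write_genotypes(p, path, "genepop", digits = 3)
  txt <- readLines(path)
  expect_true(any(grepl("000000", txt)))
  expect_true(panels_equal(p, read_genotypes(path, "genepop")))
})

test_that("three-digit allele sizes survive the FSTAT dialect", {
  a <- matrix(c(255L, 103L, 999L, 255L), 2, 2)
  p <- toy_panel(a, a)
  path <- tempfile(fileext = ".dat")
  write_genotypes(p, path, "fstat", digits = 3)
  expect_true(panels_equal(p, read_genotypes(path, "fstat")))
})

test_that("a male X-linked heterozygote is rejected with the culprit named", {
  path <- tempfile()
  writeLines(c("toy", "XA", "POP", "R1|P1|M|bob , 0102"), path)
  expect_error(read_genotypes(path, "genepop"), "bob")
  expect_error(read_genotypes(path, "genepop"), "X-linked")
})

test_that("malformed genotype files raise parse errors naming the line", {
  path <- tempfile()
  writeLines(c("toy", "L1", "L2", "POP", "a , 0101"), path)  # 1 code, 2 loci
  expect_error(read_genotypes(path, "genepop"), "line")
  path2 <- tempfile()
  writeLines("not a header", path2)
  expect_error(read_genotypes(path2, "fstat"), "header|short")
  expect_error(write_genotypes(toy_panel(matrix(1000L), matrix(1000L)),
                               tempfile(), "genepop", digits = 2),
               "does not fit")
})

test_that("an empty panel cannot be written", {
  p <- random_panel(1)
  p$individuals <- p$individuals[0, ]
  p$a1 <- p$a1[0, , drop = FALSE]
  p$a2 <- p$a2[0, , drop = FALSE]
  expect_error(write_genotypes(p, tempfile(), "genepop"), "no individuals")
})

test_that("the study-shaped synthetic file loads with 153 individuals", {
  p <- simulate_microsat_panel(study_config(), seed = 11)
  path <- tempfile()
  write_genotypes(p, path, "genepop")
  q <- read_genotypes(path, "genepop")
  expect_equal(nrow(q$individuals), 153)
  expect_equal(length(unique(q$individuals$population)), 5)
  expect_equal(sum(q$loci$x_linked), 5)
  expect_equal(as.vector(table(q$individuals$population)[
    c("DiacsawPeul", "DakarHann", "Sebikotan", "Missira", "Pout")]),
    c(30, 29, 32, 35, 27))
})

test_that("FASTA alignments round-trip and ragged input errors", {
  recs <- data.frame(id = paste0("s", 1:4), population = c("A", "A", "B", "B"),
                     region = c("R1", "R1", "R2", "R2"))
  sp <- sequence_panel(recs, c("ACGT", "ACGA", "AAAA", "ACCA"))
  expect_equal(sp$length, 4)
  path <- tempfile(fileext = ".fa")
  write_alignment(sp, path)
  sp2 <- read_alignment(path)
  expect_equal(sp2$seqs, sp$seqs)
  expect_equal(sp2$records$population, recs$population)
  expect_equal(sp2$records$region, recs$region)
  expect_error(sequence_panel(recs, c("ACGT", "ACG", "AAAA", "ACCA")),
               "ragged")
})

test_that("TPS and CSV landmark files round-trip with group labels", {
  set.seed(3)
  coords <- array(rnorm(6 * 10 * 2), c(6, 10, 2))
  lp <- landmark_panel(coords, rep(c("g1", "g2"), each = 3))
  for (fmt in c("tps", "csv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_landmarks(lp, path, fmt)
    lp2 <- read_landmarks(path, fmt)
    expect_equal(lp2$k, 10)
    expect_equal(lp2$group, lp$group)
    expect_equal(lp2$coords, lp$coords, tolerance = 1e-6)
  }
  # TPS block with the wrong landmark count
  bad <- tempfile()
  writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=a", "LM=4",
               "0 0", "1 0", "0 1", "1 1", "ID=b"), bad)
  expect_error(read_landmarks(bad, "tps"), "disagree")
})

test_that("PHYLIP distance matrices round-trip with labels and tag", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d <- dist_matrix(m, "chord")
  path <- tempfile()
  write_distance_matrix(d, path)
  d2 <- read_distance_matrix(path)
  expect_equal(unclass(d2), unclass(d), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rownames(d2), rownames(d))
  expect_error(dist_matrix(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(dist_matrix(matrix(c(1, 0, 0, 1), 2)), "diagonal")
})
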