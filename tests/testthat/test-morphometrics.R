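rand_similarity <- function(x) {
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s <- exp(rnorm(1, 0, 0.5))
  sweep(s * x %*% R, 2, rnorm(2, 0, 3), "+")
}

test_that("configurations identical up to similarity align exactly", {
  set.seed(11)
  base <- matrix(rnorm(20), 10, 2)
  coords <- array(NA_real_, c(8, 10, 2))
  for (i in 1:8) coords[i, , ] <- rand_similarity(base)
  g <- gpa(landmark_panel(coords, rep("g", 8)))
  expect_lt(max(g$residual_ss), 1e-15)
})

test_that("GPA output is invariant to pre-applied similarity transforms", {
  set.seed(12)
  cfg <- study_config()
  lp <- simulate_landmarks(cfg, seed = 1, n_per_group = c(A = 10, B = 10))
  g1 <- gpa(lp)
  for (rep in 1:10) {
    lp2 <- lp
    for (i in seq_len(dim(lp$coords)[1])) {
      lp2$coords[i, , ] <- rand_similarity(lp$coords[i, , ])
    }
    g2 <- gpa(lp2)
    # consensus agrees up to rotation: align one onto the other
    d <- sum((tsetsepop:::rotate_onto(g2$consensus, g1$consensus) -
                g1$consensus)^2)
    expect_lt(d, 1e-10)
  }
})

test_that("mirror-image configurations keep a nonzero residual", {
  set.seed(13)
  base <- matrix(rnorm(20), 10, 2)
  mirror <- base %*% diag(c(-1, 1))
  coords <- array(NA_real_, c(2, 10, 2))
  coords[1, , ] <- base
  coords[2, , ] <- mirror
  g <- gpa(landmark_panel(coords, c("a", "b")))
  expect_gt(min(g$residual_ss), 1e-4)
})

test_that("ten landmarks give sixteen shape variables", {
  lp <- simulate_landmarks(study_config(), seed = 2)
  sv <- partial_warps(gpa(lp))
  expect_equal(ncol(sv$scores), 16)
  expect_equal(nrow(sv$scores), dim(lp$coords)[1])
  # basis columns orthonormal
  btb <- crossprod(sv$basis)
  expect_equal(unname(btb), diag(16), tolerance = 1e-10)
})

test_that("the consensus itself scores zero and norms are preserved", {
  lp <- simulate_landmarks(study_config(), seed = 3,
                           n_per_group = c(A = 12, B = 12))
  g <- gpa(lp)
  sv <- partial_warps(g)
  # consensus as an extra configuration: residual zero => scores zero
  v0 <- rep(0, 2 * nrow(g$consensus))
  expect_equal(drop(crossprod(sv$basis, v0)), rep(0, 16))
  # tangent-space norm preservation for every configuration
  for (i in seq_len(6)) {
    v <- c(g$aligned[i, , 1] - g$consensus[, 1],
           g$aligned[i, , 2] - g$consensus[, 2])
    proj <- drop(crossprod(sv$basis, v))
    # v may retain a component along the similarity directions; compare to
    # the tangent projection of v
    tang <- sv$basis %*% proj
    expect_equal(sqrt(sum(sv$scores[i, ]^2)), sqrt(sum(tang^2)),
                 tolerance = 1e-8)
  }
})

test_that("Mahalanobis distance solves the Pythagorean identity-covariance case", {
  p <- 4
  dev <- rbind(diag(p), -diag(p)) * sqrt(7 / 2)  # sample covariance = I
  mu_a <- rep(0, p)
  mu_b <- c(3, 4, 0, 0)
  scores <- rbind(sweep(dev, 2, mu_a, "+"), sweep(dev, 2, mu_b, "+"))
  sv <- list(scores = scores, group = rep(c("A", "B"), each = 2 * p))
  cva <- mahalanobis_cva(sv, n_perm = 19, seed = 1)
  expect_equal(cva$d["A", "B"], 5, tolerance = 1e-10)
})

test_that("D_M is invariant to invertible linear maps of score space", {
  set.seed(14)
  scores <- matrix(rnorm(40 * 6), 40, 6)
  scores[21:40, 1] <- scores[21:40, 1] + 2
  grp <- rep(c("A", "B"), each = 20)
  d1 <- mahalanobis_cva(list(scores = scores, group = grp), n_perm = 1,
                        seed = 1)$d["A", "B"]
  M <- matrix(rnorm(36), 6, 6) + diag(6)
  d2 <- mahalanobis_cva(list(scores = scores %*% M, group = grp), n_perm = 1,
                        seed = 1)$d["A", "B"]
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("reclassification counts sum to group sizes and flags size-1 groups", {
  lp <- simulate_landmarks(study_config(), seed = 4)
  cva <- mahalanobis_cva(partial_warps(gpa(lp)), n_perm = 9, seed = 2)
  expect_equal(sum(cva$reclassification$n), dim(lp$coords)[1])
  expect_true(all(cva$reclassification$correct <= cva$reclassification$n))
  expect_true(all(cva$reclassification$percent >= 0 &
                    cva$reclassification$percent <= 100))
  sv <- list(scores = matrix(rnorm(22), 11, 2),
             group = c(rep("A", 5), rep("B", 5), "C"))
  expect_warning(mahalanobis_cva(sv, n_perm = 9, seed = 1), "size 1")
})

test_that("shape variables are invariant to input ordering", {
  lp <- simulate_landmarks(study_config(), seed = 6)
  sv1 <- partial_warps(gpa(lp))
  o <- sample(dim(lp$coords)[1])
  lp2 <- landmark_panel(lp$coords[o, , , drop = FALSE], lp$group[o],
                        lp$ids[o])
  sv2 <- partial_warps(gpa(lp2))
  # same individuals end with the same tangent norms
  n1 <- sqrt(rowSums(sv1$scores^2))
  n2 <- sqrt(rowSums(sv2$scores^2))
  expect_equal(n1[o], n2, tolerance = 1e-6)
})
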