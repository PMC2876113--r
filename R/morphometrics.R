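## Wing geometric morphometrics: generalized Procrustes alignment,
## partial-warp shape variables from the thin-plate-spline bending-energy
## matrix (plus the uniform component), and Mahalanobis canonical-variate
## analysis with pairwise permutation tests and reclassification scores.

centre_config <- function(x) sweep(x, 2, colMeans(x))
centroid_size <- function(x) sqrt(sum(centre_config(x)^2))

## optimal rotation (no reflection) of x onto y, both centred
rotate_onto <- function(x, y) {
  s <- svd(crossprod(y, x))
  R <- s$v %*% t(s$u)
  if (det(R) < 0) {
    v <- s$v; v[, ncol(v)] <- -v[, ncol(v)]
    R <- v %*% t(s$u)
  }
  x %*% R
}

#' Generalized Procrustes analysis
#'
#' Iterative least-squares alignment of landmark configurations: centre,
#' scale to unit centroid size, rotate to the running consensus (rotation
#' only, no reflection), update the consensus, repeat until the consensus
#' change falls below `tol`. The consensus is centred at the origin with
#' unit centroid size.
#'
#' @param panel a [landmark_panel()].
#' @param tol convergence tolerance on the consensus root-mean-square
#'   change.
#' @param max_iter iteration cap.
#' @return object of class `gpa_result`: `aligned` (n x k x 2 array),
#'   `consensus` (k x 2), `centroid_sizes`, `iterations`, `final_change`,
#'   `residual_ss` per configuration.
#' @export
gpa <- function(panel, tol = 1e-8, max_iter = 100) {
  X <- panel$coords
  n <- dim(X)[1]; k <- dim(X)[2]
  stopifnot(k >= 3)
  sizes <- numeric(n)
  A <- array(NA_real_, dim(X))
  for (i in seq_len(n)) {
    ci <- centre_config(X[i, , ])
    sizes[i] <- sqrt(sum(ci^2))
    if (sizes[i] == 0) stop("degenerate configuration ", panel$ids[i])
    A[i, , ] <- ci / sizes[i]
  }
  cons <- A[1, , ]
  change <- Inf; it <- 0
  while (change > tol && it < max_iter) {
    it <- it + 1
    for (i in seq_len(n)) A[i, , ] <- rotate_onto(A[i, , ], cons)
    newcons <- apply(A, c(2, 3), mean)
    newcons <- centre_config(newcons)
    newcons <- newcons / sqrt(sum(newcons^2))
    change <- sqrt(mean((newcons - cons)^2))
    cons <- newcons
  }
  rss <- vapply(seq_len(n), function(i) sum((A[i, , ] - cons)^2), 0)
  structure(list(aligned = A, consensus = cons, centroid_sizes = sizes,
                 iterations = it, final_change = change,
                 residual_ss = rss, group = panel$group, ids = panel$ids),
            class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat("GPA:", dim(x$aligned)[1], "configurations,", dim(x$aligned)[2],
      "landmarks, converged in", x$iterations, "iterations\n")
  invisible(x)
}

## thin-plate-spline bending-energy matrix for a reference shape (k x 2)
bending_energy <- function(ref) {
  k <- nrow(ref)
  r2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(r2 == 0, 0, r2 * log(r2)) / 2   # U(r) = r^2 log r
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- solve(L)
  Be <- Li[1:k, 1:k]
  (Be + t(Be)) / 2
}

#' Partial-warp shape variables
#'
#' Projects Procrustes tangent-space residuals onto the principal warps
#' (eigenvectors of the consensus bending-energy matrix with nonzero
#' eigenvalue, applied to x and y), and appends the two-dimensional uniform
#' (affine) component computed as the orthonormal complement of the
#' nonuniform subspace within the tangent space. The score vector has
#' length 2k - 4 (16 for 10 landmarks) and preserves the Procrustes tangent
#' distance to the consensus.
#'
#' @param g a [gpa_result()].
#' @return object of class `shape_variables`: `scores` (n x (2k-4) matrix),
#'   `basis` (2k x (2k-4)), `consensus`, group labels.
#' @export
partial_warps <- function(g) {
  cons <- g$consensus
  k <- nrow(cons)
  stopifnot(k >= 4)
  Be <- bending_energy(cons)
  eb <- eigen(Be, symmetric = TRUE)
  nz <- eb$values > max(eb$values) * 1e-9
  if (sum(nz) != k - 3) {
    if (sum(nz) < k - 3) stop("singular bending-energy matrix (collinear landmarks?)")
    nz <- rank(-eb$values) <= (k - 3)
  }
  W <- eb$vectors[, nz, drop = FALSE]         # principal warps, k x (k-3)
  # nonuniform basis in the 2k space: each warp on x and on y
  nonuni <- matrix(0, 2 * k, 2 * (k - 3))
  for (j in seq_len(k - 3)) {
    nonuni[1:k, 2 * j - 1] <- W[, j]
    nonuni[k + 1:k, 2 * j] <- W[, j]
  }
  # tangent space: orthogonal to translations, scale/rotation at consensus
  cvec <- c(cons[, 1], cons[, 2])
  rvec <- c(-cons[, 2], cons[, 1])
  constr <- cbind(c(rep(1, k), rep(0, k)) / sqrt(k),
                  c(rep(0, k), rep(1, k)) / sqrt(k),
                  cvec / sqrt(sum(cvec^2)),
                  rvec / sqrt(sum(rvec^2)))
  # uniform = complement of (constraints + nonuniform) within R^{2k}
  proj <- qr.Q(qr(cbind(constr, nonuni)))
  full <- diag(2 * k) - tcrossprod(proj)
  eu <- eigen((full + t(full)) / 2, symmetric = TRUE)
  U <- eu$vectors[, eu$values > 0.5, drop = FALSE]
  if (ncol(U) != 2) stop("uniform-component extraction failed")
  basis <- cbind(nonuni, U)
  n <- dim(g$aligned)[1]
  scores <- matrix(NA_real_, n, 2 * k - 4)
  for (i in seq_len(n)) {
    v <- c(g$aligned[i, , 1] - cons[, 1], g$aligned[i, , 2] - cons[, 2])
    scores[i, ] <- drop(crossprod(basis, v))
  }
  colnames(scores) <- c(paste0("PW", rep(seq_len(k - 3), each = 2),
                               c("x", "y")), "U1", "U2")
  structure(list(scores = scores, basis = basis, consensus = cons,
                 group = g$group, ids = g$ids),
            class = "shape_variables")
}

## pairwise squared Mahalanobis distance between group means given pooled
## within-group covariance inverse
mahal_d2 <- function(mu_a, mu_b, w_inv) {
  dmu <- mu_a - mu_b
  drop(t(dmu) %*% w_inv %*% dmu)
}

pooled_cov <- function(scores, grp) {
  grp <- factor(grp)
  p <- ncol(scores)
  W <- matrix(0, p, p)
  df <- 0
  for (g in levels(grp)) {
    rows <- grp == g
    if (sum(rows) < 2) next
    W <- W + stats::cov(scores[rows, , drop = FALSE]) * (sum(rows) - 1)
    df <- df + sum(rows) - 1
  }
  W / df
}

safe_inverse <- function(M) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  tolv <- max(ev$values) * 1e-10
  pos <- ev$values > tolv
  flag <- !all(pos)
  inv <- ev$vectors[, pos, drop = FALSE] %*%
    diag(1 / ev$values[pos], sum(pos)) %*% t(ev$vectors[, pos, drop = FALSE])
  attr(inv, "regularized") <- flag
  inv
}

#' Mahalanobis discriminant analysis of shape variables
#'
#' Pairwise Mahalanobis distances between group mean score vectors under
#' the pooled within-group covariance; per-pair significance by permuting
#' the group labels of the two groups under comparison; resubstitution
#' reclassification by assigning every individual to the group whose mean
#' is nearest in Mahalanobis distance (leave-one-out available).
#'
#' @param sv a [shape_variables()] (or any object with `scores` and
#'   `group`).
#' @param n_perm permutations per pair (study default 1000).
#' @param seed integer seed.
#' @param cross_validate logical; leave-one-out instead of resubstitution.
#' @return object of class `cva_result`: `d` (distance [dist_matrix()],
#'   tag "mahalanobis"), `p_values` matrix, `reclassification` data.frame
#'   (group, n, correct, percent).
#' @export
mahalanobis_cva <- function(sv, n_perm = 1000, seed = 1,
                            cross_validate = FALSE) {
  set.seed(seed)
  scores <- sv$scores
  grp <- factor(sv$group)
  sizes <- table(grp)
  if (any(sizes < 2)) {
    keep <- grp %in% names(sizes)[sizes >= 2]
    warning("dropping group(s) of size 1: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    scores <- scores[keep, , drop = FALSE]
    grp <- droplevels(grp[keep])
    sizes <- table(grp)
  }
  gs <- levels(grp)
  W <- pooled_cov(scores, grp)
  Wi <- safe_inverse(W)
  mus <- lapply(gs, function(g) colMeans(scores[grp == g, , drop = FALSE]))
  names(mus) <- gs
  G <- length(gs)
  D <- matrix(0, G, G, dimnames = list(gs, gs))
  P <- matrix(NA_real_, G, G, dimnames = list(gs, gs))
  for (i in seq_len(G)) {
    for (j in seq_len(i - 1)) {
      D[i, j] <- D[j, i] <- sqrt(mahal_d2(mus[[i]], mus[[j]], Wi))
      rows <- which(grp %in% gs[c(i, j)])
      lab <- grp[rows]
      sc <- scores[rows, , drop = FALSE]
      obs <- pair_d2(sc, lab, gs[i], gs[j])
      ge <- 0L
      for (b in seq_len(n_perm)) {
        if (pair_d2(sc, sample(lab), gs[i], gs[j]) >= obs - 1e-12) ge <- ge + 1L
      }
      P[i, j] <- P[j, i] <- (ge + 1) / (n_perm + 1)
    }
  }
  assign_group <- function(x, mus, Wi) {
    gs[which.min(vapply(mus, function(m) mahal_d2(x, m, Wi), 0))]
  }
  pred <- character(nrow(scores))
  for (r in seq_len(nrow(scores))) {
    if (cross_validate) {
      sub <- scores[-r, , drop = FALSE]; g2 <- droplevels(grp[-r])
      W2i <- safe_inverse(pooled_cov(sub, g2))
      m2 <- lapply(levels(g2), function(g) colMeans(sub[g2 == g, , drop = FALSE]))
      names(m2) <- levels(g2)
      pred[r] <- names(m2)[which.min(vapply(m2, function(m)
        mahal_d2(scores[r, ], m, W2i), 0))]
    } else {
      pred[r] <- assign_group(scores[r, ], mus, Wi)
    }
  }
  reclass <- do.call(rbind, lapply(gs, function(g) {
    rows <- grp == g
    data.frame(group = g, n = sum(rows),
               correct = sum(pred[rows] == g),
               percent = 100 * mean(pred[rows] == g),
               stringsAsFactors = FALSE)
  }))
  structure(list(d = dist_matrix(D, "mahalanobis"), p_values = P,
                 reclassification = reclass,
                 regularized = isTRUE(attr(Wi, "regularized")),
                 n_perm = n_perm, seed = seed,
                 cross_validated = cross_validate),
            class = "cva_result")
}

## Mahalanobis distance between the two groups in a two-group subset,
## with covariance pooled over those two groups only (permutation statistic)
pair_d2 <- function(sc, lab, ga, gb) {
  Wi <- safe_inverse(pooled_cov(sc, lab))
  mahal_d2(colMeans(sc[lab == ga, , drop = FALSE]),
           colMeans(sc[lab == gb, , drop = FALSE]), Wi)
}

#' @export
print.cva_result <- function(x, ...) {
  cat("Mahalanobis CVA over", nrow(x$reclassification), "groups; mean correct",
      sprintf("%.1f%%\n", mean(x$reclassification$percent)))
  invisible(x)
}
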