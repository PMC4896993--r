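# Multivariate statistics on aligned shapes: dimension reduction, mean-shape
# tests, classification validation, permutation and Mantel inference,
# regression of shape on covariates, and vector-angle tests.

#' Principal component reduction
#'
#' Projects the rows of `X` onto the leading eigenvectors of the sample
#' covariance (via [stats::prcomp()]).
#'
#' @param X Numeric `N x D` matrix.
#' @param n_components Number of components to retain; at most `min(N-1, D)`.
#' @return A list of class `pca_reduction`: `scores` (`N x n_components`),
#'   `variance_fractions` (all components, descending, summing to 1),
#'   `rotation`, `center`, `sdev`.
#' @export
pca_reduce <- function(X, n_components) {
  X <- as.matrix(X)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(nrow(X) - 1L, ncol(X))) {
    stop("n_components must lie in [1, min(N-1, D)]", call. = FALSE)
  }
  total_var <- sum(apply(X, 2L, stats::var))
  if (!is.finite(total_var) || total_var <= 0) {
    stop("X has zero variance; principal components are undefined", call. = FALSE)
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  fractions <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(scores = fit$x[, seq_len(n_components), drop = FALSE],
         variance_fractions = fractions,
         rotation = fit$rotation, center = fit$center, sdev = fit$sdev),
    class = "pca_reduction"
  )
}

#' Two-sample Hotelling T-squared test
#'
#' Tests equality of two multivariate means using the pooled covariance:
#' `T2 = n1*n2/(n1+n2) * d' S^-1 d`, converted to an F statistic
#' `F = T2 * (n1+n2-p-1) / (p * (n1+n2-2))` on `(p, n1+n2-p-1)` degrees of
#' freedom.
#'
#' @param X1,X2 Numeric matrices with the same number of columns `p`
#'   (typically principal component scores).
#' @return A list of class `hotelling_test`: `t2`, `f_stat`, `df1`, `df2`,
#'   `p_raw`, `p_adjusted` (`NA` until filled by a multiple-testing step).
#' @export
hotelling_two_sample <- function(X1, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) stop("X1 and X2 must have the same variables", call. = FALSE)
  p <- ncol(X1); n1 <- nrow(X1); n2 <- nrow(X2)
  df2 <- n1 + n2 - p - 1L
  if (df2 < 1L) {
    stop("sample too small for p = ", p, " variables (need n1+n2-p-1 >= 1)", call. = FALSE)
  }
  d <- colMeans(X1) - colMeans(X2)
  S <- (crossprod(sweep(X1, 2L, colMeans(X1))) +
        crossprod(sweep(X2, 2L, colMeans(X2)))) / (n1 + n2 - 2L)
  if (rcond(S) < 1e-12) {
    stop("pooled covariance is singular; retain fewer components", call. = FALSE)
  }
  t2 <- (n1 * n2 / (n1 + n2)) * drop(crossprod(d, solve(S, d)))
  f_stat <- t2 * df2 / (p * (n1 + n2 - 2L))
  structure(
    list(t2 = t2, f_stat = f_stat, df1 = p, df2 = df2,
         p_raw = stats::pf(f_stat, p, df2, lower.tail = FALSE),
         p_adjusted = NA_real_, n1 = n1, n2 = n2),
    class = "hotelling_test"
  )
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat(sprintf("Two-sample Hotelling test: T2(%d, %d) = %.4g, F = %.4g, p = %.3g\n",
              x$df1, x$df2, x$t2, x$f_stat, x$p_raw))
  invisible(x)
}

#' Leave-one-out misclassification of a two-group linear discriminant
#'
#' Fits, for each specimen, a linear discriminant (pooled within-class
#' covariance, class-proportional priors, via [MASS::lda()]) on the remaining
#' specimens and classifies the one left out.
#'
#' @param scores Numeric `N x p` matrix (typically PC scores).
#' @param labels Class labels of length `N`; every class needs at least 2
#'   members.
#' @return Fraction of specimens misclassified.
#' @export
lda_loocv <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (any(table(labels) < 2L)) {
    stop("every class needs at least 2 members for leave-one-out validation",
         call. = FALSE)
  }
  W <- Reduce(`+`, lapply(levels(labels), function(g) {
    Xg <- scores[labels == g, , drop = FALSE]
    crossprod(sweep(Xg, 2L, colMeans(Xg)))
  })) / (nrow(scores) - nlevels(labels))
  if (rcond(W) < 1e-12) {
    stop("within-class covariance is singular; retain fewer components", call. = FALSE)
  }
  fit <- suppressWarnings(MASS::lda(x = scores, grouping = labels, CV = TRUE))
  # classify from the cross-validated posteriors with a deterministic
  # tie-break (lda's own class vector breaks exact ties at random)
  cls <- colnames(fit$posterior)[max.col(fit$posterior, ties.method = "first")]
  mean(cls != as.character(labels))
}

#' Holm-Bonferroni adjustment
#'
#' Step-down familywise-error correction (delegates to [stats::p.adjust()]),
#' returned in the input order, monotone and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries of two symmetric distance
#' matrices, with significance from simultaneous row/column permutations of
#' the second matrix. The p-value uses the add-one estimator
#' `(b + 1) / (n_perm + 1)` counting permutations with `|r*| >= |r|`.
#'
#' @param D1,D2 Symmetric, zero-diagonal matrices (or `dist` objects) of the
#'   same size.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed; results are bit-identical under a fixed
#'   seed and leave the global RNG state untouched.
#' @return A list of class `mantel_test`: `r`, `p_perm`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 9999L, seed = NULL) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  check_distance_matrix(D1, "D1")
  check_distance_matrix(D2, "D2")
  if (!all(dim(D1) == dim(D2))) stop("D1 and D2 must have the same size", call. = FALSE)
  n <- nrow(D1)
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  r_obs <- stats::cor(v1, D2[ut])
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      stats::cor(v1, D2[idx, idx][ut])
    }, numeric(1))
  })
  p <- (sum(abs(r_perm) >= abs(r_obs)) + 1) / (n_perm + 1)
  structure(list(r = r_obs, p_perm = p, n_perm = as.integer(n_perm)),
            class = "mantel_test")
}

check_distance_matrix <- function(D, what) {
  if (nrow(D) != ncol(D) || !isSymmetric(unname(D), tol = 1e-8)) {
    stop(what, " must be a symmetric square matrix", call. = FALSE)
  }
  if (any(abs(diag(D)) > 1e-8)) stop(what, " must have a zero diagonal", call. = FALSE)
  invisible(D)
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p_perm, x$n_perm))
  invisible(x)
}

#' Multivariate regression of shape on a covariate with permutation test
#'
#' Least-squares fit of every shape coordinate on a single covariate. The
#' percentage of shape variance explained is `100 * SS_predicted / SS_total`
#' (sums over all coordinates); significance comes from permuting the
#' covariate across individuals and recording the predicted sum of squares,
#' with the add-one p-value estimator. Projection scores — the univariate
#' visualization of the fit — are the centered shapes projected onto the
#' unit-normalized regression vector.
#'
#' @param X Numeric `N x D` shape matrix (rows = specimens).
#' @param z Numeric covariate of length `N` with positive variance.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed (bit-reproducible results).
#' @return A list of class `shape_regression`: `coefficient_vector` (shape
#'   change per unit covariate), `pct_var_explained`, `p_perm`, `n_perm`,
#'   `projection_scores`, `ss_predicted`, `ss_total`.
#' @export
shape_regression_permutation <- function(X, z, n_perm = 9999L, seed = NULL) {
  X <- as.matrix(X)
  z <- as.numeric(z)
  if (length(z) != nrow(X)) stop("length(z) must equal nrow(X)", call. = FALSE)
  if (nrow(X) < 3L) stop("need at least 3 specimens", call. = FALSE)
  if (stats::var(z) <= 0) stop("covariate has zero variance", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  zc <- z - mean(z)
  szz <- sum(zc^2)
  b <- drop(crossprod(Xc, zc)) / szz
  ss_pred <- sum(b^2) * szz
  ss_tot <- sum(Xc^2)
  if (ss_tot <= 0) stop("shapes have zero variance", call. = FALSE)
  exceed <- with_seed(seed, {
    count <- 0L
    block <- 500L
    done <- 0L
    while (done < n_perm) {
      m <- min(block, n_perm - done)
      Zp <- vapply(seq_len(m), function(i) zc[sample.int(length(zc))], numeric(length(zc)))
      ssp <- colSums(crossprod(Xc, Zp)^2) / szz
      count <- count + sum(ssp >= ss_pred)
      done <- done + m
    }
    count
  })
  scores <- drop(Xc %*% (b / sqrt(sum(b^2))))
  names(scores) <- rownames(X)
  structure(
    list(coefficient_vector = b,
         pct_var_explained = 100 * ss_pred / ss_tot,
         p_perm = (exceed + 1) / (n_perm + 1),
         n_perm = as.integer(n_perm),
         projection_scores = scores,
         ss_predicted = ss_pred, ss_total = ss_tot),
    class = "shape_regression"
  )
}

#' @export
print.shape_regression <- function(x, ...) {
  cat(sprintf("Shape-on-covariate regression: %.2f%% of variance explained, p = %.4g (%d permutations)\n",
              x$pct_var_explained, x$p_perm, x$n_perm))
  invisible(x)
}

#' Between-group principal component analysis
#'
#' Principal components of the (unweighted) group mean shapes; individuals
#' are then projected onto the resulting axes, giving an ordination of group
#' means with individual scatter.
#'
#' @param X Numeric `N x D` shape matrix.
#' @param labels Group labels of length `N` (at least 2 groups).
#' @return A list of class `bgpca`: `axes` (`D x m` orthonormal, `m = G - 1`
#'   at most), `eigenvalues`, `group_scores` (`G x m`), `ind_scores`
#'   (`N x m`), `group_means`, `center`.
#' @export
between_group_pca <- function(X, labels) {
  X <- as.matrix(X)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("between-group PCA needs at least 2 groups", call. = FALSE)
  G <- t(vapply(levels(labels), function(g) colMeans(X[labels == g, , drop = FALSE]),
                numeric(ncol(X))))
  center <- colMeans(G)
  Gc <- sweep(G, 2L, center)
  m <- min(nlevels(labels) - 1L, ncol(X))
  sv <- svd(Gc, nu = 0L, nv = m)
  axes <- sv$v
  colnames(axes) <- paste0("PC", seq_len(ncol(axes)))
  eigenvalues <- sv$d[seq_len(m)]^2 / (nlevels(labels) - 1L)
  group_scores <- Gc %*% axes
  ind_scores <- sweep(X, 2L, center) %*% axes
  rownames(group_scores) <- levels(labels)
  rownames(ind_scores) <- rownames(X)
  structure(
    list(axes = axes, eigenvalues = eigenvalues, group_scores = group_scores,
         ind_scores = ind_scores, group_means = G, center = center),
    class = "bgpca"
  )
}

# Null probability that two independent uniformly random directions in `dim`
# dimensions subtend an angle <= theta: the cosine of such an angle has
# density proportional to (1 - t^2)^((dim-3)/2), i.e. (t+1)/2 ~
# Beta((dim-1)/2, (dim-1)/2).
angle_null_cdf <- function(theta_deg, dim) {
  ct <- cos(theta_deg * pi / 180)
  stats::pbeta((ct + 1) / 2, (dim - 1) / 2, (dim - 1) / 2, lower.tail = FALSE)
}

#' Angle between shape-change vectors with a random-direction null
#'
#' Computes the angle subtended by two shape-change vectors and the null
#' probability that two independent uniformly random directions in `dim`
#' dimensions subtend an angle at least as small — small p-values mean the
#' vectors are more nearly parallel than chance directions would be. The null
#' has density proportional to `sin^(dim-2)(theta)` and is evaluated in
#' closed form via the regularized incomplete beta function.
#'
#' @param v1,v2 Nonzero numeric vectors of equal length.
#' @param dim Dimensionality of the shape space used for the null
#'   (defaults to `length(v1)`); pass the symmetric shape-space dimension
#'   (see [shape_space_dim()]) to match the superimposed data.
#' @return A list of class `angle_test`: `angle_deg` in `[0, 180]`, `dim`,
#'   `p_raw`, `p_adjusted` (`NA` until filled by a multiple-testing step).
#' @export
angle_test <- function(v1, v2, dim = length(v1)) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  if (length(v1) != length(v2)) stop("vectors have mismatched lengths", call. = FALSE)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 <= 0 || n2 <= 0) stop("angle is undefined for a zero vector", call. = FALSE)
  if (dim < 2L) stop("dim must be at least 2", call. = FALSE)
  ct <- max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
  angle_deg <- acos(ct) * 180 / pi
  structure(
    list(angle_deg = angle_deg, dim = as.integer(dim),
         p_raw = angle_null_cdf(angle_deg, dim), p_adjusted = NA_real_),
    class = "angle_test"
  )
}

#' @export
print.angle_test <- function(x, ...) {
  cat(sprintf("Angle test: %.2f deg in %d dimensions, p = %.3g\n",
              x$angle_deg, x$dim, x$p_raw))
  invisible(x)
}

#' Pairwise rank-sum tests with Holm correction
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests for all pairs of groups,
#' adjusted for multiple testing by the Holm-Bonferroni method (via
#' [stats::pairwise.wilcox.test()]).
#'
#' @param values Numeric vector of observations.
#' @param labels Group labels of the same length (no empty groups among the
#'   levels compared).
#' @return A list of class `pairwise_rank_test`: `p_adjusted` and `p_raw`
#'   (lower-triangular matrices as returned by the underlying test).
#' @export
pairwise_rank_test <- function(values, labels) {
  values <- as.numeric(values)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(labels) == 0L)) stop("empty group in labels", call. = FALSE)
  adj <- suppressWarnings(stats::pairwise.wilcox.test(values, labels,
                                                      p.adjust.method = "holm"))
  raw <- suppressWarnings(stats::pairwise.wilcox.test(values, labels,
                                                      p.adjust.method = "none"))
  structure(list(p_adjusted = adj$p.value, p_raw = raw$p.value,
                 method = adj$method),
            class = "pairwise_rank_test")
}
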