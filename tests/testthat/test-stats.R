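test_that("PCA reduction rejects constant data and spans the data exactly", {
  expect_error(pca_reduce(matrix(1, 5, 3), 2), "zero variance")
  set.seed(50)
  X <- matrix(rnorm(200), 20, 10)
  fit <- pca_reduce(X, 10)
  expect_equal(sum(fit$variance_fractions), 1)
  expect_true(all(diff(fit$variance_fractions) <= 1e-12))
  # reconstruction from the complete eigenbasis reproduces X
  recon <- sweep(fit$scores %*% t(fit$rotation), 2, fit$center, `+`)
  expect_equal(recon, X, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(pca_reduce(X, 11), "n_components")
})

test_that("Hotelling test returns zero for mirrored samples and the standard df convention", {
  set.seed(51)
  X1 <- matrix(rnorm(60), 20, 3)
  m <- colMeans(X1)
  X2 <- sweep(-sweep(X1, 2, m), 2, m, `+`)  # mirror about the common mean
  ht <- hotelling_two_sample(X1, X2)
  expect_equal(ht$t2, 0, tolerance = 1e-20)
  expect_equal(ht$p_raw, 1)

  # df convention: p = 10 variables, n1 + n2 = 71 -> df (10, 60)
  Y1 <- matrix(rnorm(45 * 10), 45, 10)
  Y2 <- matrix(rnorm(26 * 10), 26, 10)
  ht2 <- hotelling_two_sample(Y1, Y2)
  expect_identical(c(ht2$df1, ht2$df2), c(10L, 60L))

  # duplicated variable -> singular pooled covariance
  Z1 <- matrix(rnorm(10), 5, 2); Z1[, 2] <- Z1[, 1]
  Z2 <- matrix(rnorm(10), 5, 2); Z2[, 2] <- Z2[, 1]
  expect_error(hotelling_two_sample(Z1, Z2), "singular")
})

test_that("Hotelling T2 is invariant under common affine changes of basis", {
  set.seed(52)
  X1 <- matrix(rnorm(80), 20, 4)
  X2 <- matrix(rnorm(60, 0.5), 15, 4)
  ht <- hotelling_two_sample(X1, X2)
  A <- matrix(rnorm(16), 4, 4) + diag(4)
  b <- rnorm(4)
  ht_t <- hotelling_two_sample(sweep(X1 %*% A, 2, b, `+`), sweep(X2 %*% A, 2, b, `+`))
  expect_equal(ht$t2, ht_t$t2, tolerance = 1e-8)
})

test_that("discriminant LOOCV separates distinct clusters and errors on tiny classes", {
  set.seed(53)
  X <- rbind(matrix(rnorm(40 * 3, 0), 40, 3), matrix(rnorm(40 * 3, 50), 40, 3))
  lab <- rep(c("a", "b"), each = 40)
  expect_identical(lda_loocv(X, lab), 0)
  expect_error(lda_loocv(X[c(1:5, 41), ], lab[c(1:5, 41)]), "at least 2")

  # random labels on one homogeneous cloud: misclassification consistent with
  # chance (binomial 99% interval around 0.5 at n = 60)
  mis <- vapply(1:50, function(r) {
    Z <- matrix(rnorm(60 * 4), 60, 4)
    lda_loocv(Z, rep(c("a", "b"), 30))
  }, numeric(1))
  half_band <- 2.576 * sqrt(0.25 / 60)
  expect_gt(mean(mis), 0.5 - half_band)
  expect_lt(mean(mis), 0.5 + half_band)
})

test_that("Holm adjustment matches hand and brute-force step-down values", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(54)
  for (r in 1:20) {
    p <- runif(10)
    expect_identical(holm_adjust(p), brute_holm(p))
  }
})

test_that("Mantel statistic equals the direct vectorized correlation and detects monotone association", {
  set.seed(55)
  pts <- matrix(rnorm(27), 9, 3)
  D1 <- as.matrix(dist(pts))
  D2 <- 2 * D1
  mt <- mantel_test(D1, D2, n_perm = 499, seed = 7)
  expect_equal(mt$r, 1)
  expect_equal(mt$p_perm, 1 / 500)

  Dr <- as.matrix(dist(matrix(rnorm(27), 9, 3)))
  mt2 <- mantel_test(D1, Dr, n_perm = 99, seed = 8)
  # direct-formula oracle for r
  ut <- upper.tri(D1)
  n <- sum(ut)
  v1 <- D1[ut]; v2 <- Dr[ut]
  r_direct <- (sum(v1 * v2) - sum(v1) * sum(v2) / n) /
    sqrt((sum(v1^2) - sum(v1)^2 / n) * (sum(v2^2) - sum(v2)^2 / n))
  expect_equal(mt2$r, r_direct, tolerance = 1e-12)
  # independent library cross-check of the statistic
  expect_equal(mt2$r, unname(vegan::mantel(D1, Dr, permutations = 0)$statistic),
               tolerance = 1e-10)

  # reproducibility under a fixed seed, no global state disturbed
  expect_identical(mantel_test(D1, Dr, n_perm = 199, seed = 3),
                   mantel_test(D1, Dr, n_perm = 199, seed = 3))
  expect_error(mantel_test(D1[, 9:1], Dr), "symmetric")
})

test_that("shape regression recovers exact linear structure and is seed-reproducible", {
  set.seed(56)
  z <- runif(20)
  b <- rnorm(12)
  X <- outer(z, b) + matrix(5, 20, 12)
  fit <- shape_regression_permutation(X, z, n_perm = 299, seed = 1)
  expect_equal(fit$pct_var_explained, 100)
  expect_equal(fit$p_perm, 1 / 300)
  expect_equal(cor(fit$projection_scores, z, method = "spearman"), 1)
  expect_equal(fit$coefficient_vector, b, ignore_attr = TRUE)
  expect_identical(shape_regression_permutation(X, z, n_perm = 99, seed = 2),
                   shape_regression_permutation(X, z, n_perm = 99, seed = 2))
  expect_error(shape_regression_permutation(X, rep(1, 20)), "zero variance")
})

test_that("between-group PCA ordinates group means isometrically", {
  set.seed(57)
  X <- matrix(rnorm(40 * 6), 40, 6)
  lab <- rep(letters[1:4], each = 10)
  bg <- between_group_pca(X, lab)
  # distances among group scores equal direct mean-shape distances
  G <- bg$group_means
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(procrustes_distance(bg$group_scores[i, ], bg$group_scores[j, ]),
                 procrustes_distance(G[i, ], G[j, ]), tolerance = 1e-10)
  }
  # two groups: the single axis is the normalized mean difference (up to sign)
  bg2 <- between_group_pca(X, rep(c("a", "b"), each = 20))
  d <- colMeans(X[1:20, ]) - colMeans(X[21:40, ])
  d <- d / sqrt(sum(d^2))
  expect_equal(abs(sum(bg2$axes[, 1] * d)), 1, tolerance = 1e-10)
  # identical group means: all eigenvalues vanish
  Xc <- rbind(X[1:10, ], X[1:10, ])
  bg3 <- between_group_pca(Xc, rep(c("a", "b"), each = 10))
  expect_lt(max(bg3$eigenvalues), 1e-20)
  expect_error(between_group_pca(X, rep("a", 40)), "2 groups")
})

test_that("angle test matches closed-form nulls and is monotone in the angle", {
  v <- c(1, 2, -1, 0.5)
  same <- angle_test(v, v)
  expect_equal(same$angle_deg, 0)
  expect_lt(same$p_raw, 1e-12)
  orth <- angle_test(c(1, 0, 0), c(0, 1, 0), dim = 17)
  expect_equal(orth$angle_deg, 90)
  expect_equal(orth$p_raw, 0.5)
  # dim = 3 closed form: P(angle <= theta) = (1 - cos theta) / 2
  a60 <- angle_test(c(1, 0, 0), c(cos(pi / 3), sin(pi / 3), 0), dim = 3)
  expect_equal(a60$angle_deg, 60)
  expect_equal(a60$p_raw, 0.25)
  # dim = 2: the angle itself is uniform on [0, 180]
  expect_equal(angle_test(c(1, 0), c(0.5, sqrt(3) / 2), dim = 2)$p_raw, 1 / 3,
               tolerance = 1e-10)
  # p is non-decreasing over the full angle range (it saturates in floating
  # point at the extremes for high dim) and strictly increasing mid-range
  angles <- seq(1, 179, by = 2)
  ps <- vapply(angles, function(th) {
    angle_test(c(1, 0, 0), c(cos(th * pi / 180), sin(th * pi / 180), 0), dim = 32)$p_raw
  }, numeric(1))
  expect_true(all(diff(ps) >= 0))
  mid <- angles > 30 & angles < 150
  expect_true(all(diff(ps[mid]) > 0))
  expect_error(angle_test(c(0, 0, 0), v[1:3]), "zero vector")
})

test_that("pairwise rank tests control familywise error and detect large shifts", {
  set.seed(58)
  # identical value multisets give a raw p at (or near, under ties) 1
  vals <- c(rnorm(10), 0)
  both <- rep(vals, 2)
  pr <- pairwise_rank_test(both, rep(c("a", "b"), each = 11))
  expect_gt(pr$p_raw["b", "a"], 0.95)

  # one group shifted by ~10 pooled SDs: all its comparisons significant
  x <- c(rnorm(20), rnorm(20), rnorm(20) + 10)
  lab <- rep(c("g1", "g2", "g3"), each = 20)
  pa <- pairwise_rank_test(x, lab)$p_adjusted
  expect_lt(pa["g3", "g1"], 0.05)
  expect_lt(pa["g3", "g2"], 0.05)

  # null: 9 groups from one distribution, family-wise clean in >= 93/100 runs
  clean <- vapply(1:100, function(r) {
    y <- rnorm(9 * 20)
    g <- rep(1:9, each = 20)
    all(pairwise_rank_test(y, g)$p_adjusted >= 0.05, na.rm = TRUE)
  }, logical(1))
  expect_gte(sum(clean), 93L)
})
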