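test_that("centroid size matches hand values, scales linearly, and agrees with a distance-identity oracle", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(centroid_size(sq), sqrt(2))
  set.seed(10)
  cfg <- matrix(rnorm(15), 5, 3)
  expect_equal(centroid_size(cfg * 3), 3 * centroid_size(cfg))
  expect_equal(centroid_size(cfg), cs_pairwise_oracle(cfg), tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 4, 3)), "coincide")
})

test_that("superimposition removes similarity transforms and handles single configurations", {
  set.seed(21)
  cfg <- matrix(rnorm(18), 6, 3)
  arr <- array(c(cfg, random_similarity_transform(cfg)), dim = c(6, 3, 2))
  fit <- gpa(arr)
  expect_lt(procrustes_distance(fit$aligned[1, ], fit$aligned[2, ]), 1e-9)

  # single config: consensus is that config centered and scaled to unit size
  one <- gpa(array(cfg, dim = c(6, 3, 1)))
  centered <- sweep(cfg, 2, colMeans(cfg))
  expect_equal(one$mean_shape, as.vector(centered / sqrt(sum(centered^2))))

  # result invariant (to tolerance) under rigid motion + scaling of any input
  base <- array(0, dim = c(6, 3, 10))
  tmpl <- matrix(rnorm(18), 6, 3)
  for (i in 1:10) base[, , i] <- tmpl + matrix(rnorm(18, sd = 0.1), 6, 3)
  moved <- base
  for (i in 1:10) moved[, , i] <- random_similarity_transform(base[, , i])
  f1 <- gpa(base, tol = 1e-14, max_iter = 5000)
  f2 <- gpa(moved, tol = 1e-14, max_iter = 5000)
  al <- align_oracle_to(list(aligned = f2$aligned, consensus = f2$mean_shape),
                        f1$mean_shape)
  expect_lt(max(abs(al - f1$aligned)), 1e-8)
})

test_that("degenerate configurations are rejected", {
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(gpa(array(line, dim = c(5, 3, 1))), "collinear")
  expect_error(gpa(array(1, dim = c(4, 3, 2))), "coincide")
})

test_that("symmetry decomposition zeroes asymmetry for symmetric input and bounds covariance rank", {
  sc <- small_object_scheme()
  # symmetric-only variation: no asymmetric effects in the generator
  d <- quick_object_data(seed = 3, da_vector_scale = 0, fa_sd = 0)
  s <- decompose_symmetry(d$landmarks, sc)
  expect_lt(max(sqrt(rowSums(s$asymmetry^2))), 1e-9)
  # symmetric component of symmetric data is the aligned shape itself: the
  # symmetric rows reproduce all the shape variation
  expect_gt(sum(apply(s$symmetric, 2, var)), 0)

  # rank of the symmetric-component covariance never exceeds 3k + 2l - 4
  d2 <- quick_object_data(n_per_bin = c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3), seed = 4)
  s2 <- decompose_symmetry(d2$landmarks, sc)
  ev <- eigen(stats::cov(s2$symmetric), symmetric = TRUE, only.values = TRUE)$values
  q <- shape_space_dim(sc)
  expect_gt(nrow(s2$symmetric), q)  # enough specimens to exceed the bound
  expect_lt(ev[q + 1], 1e-8 * ev[1])
})

test_that("matching-symmetry decomposition averages sides and reports mean centroid size", {
  fx <- fixture_set(2)$matching
  sc <- fx$params$scheme
  s <- decompose_symmetry(fx$landmarks, sc)
  cs_l <- centroid_size(fx$landmarks$left)
  cs_r <- centroid_size(fx$landmarks$right)
  expect_equal(unname(s$centroid_sizes), unname((cs_l + cs_r) / 2))
  ev <- eigen(stats::cov(s$symmetric), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[shape_space_dim(sc) + 1], 1e-8 * ev[1])

  # a missing side is reported by specimen
  bad <- fx$landmarks
  dimnames(bad$left)[[3]][1] <- "ghost"
  expect_error(decompose_symmetry(bad, sc), "ghost")
})

test_that("FA scores are zero without fluctuating asymmetry and increase with its magnitude", {
  sc <- small_object_scheme()
  # purely directional asymmetry: identical asymmetry (and identical
  # symmetric shape) for every specimen gives exactly zero FA
  d <- quick_object_data(seed = 5, da_vector_scale = 0.01, fa_sd = 0,
                         residual_sd = 0, family_sd = 0,
                         sex_effect_vector_scale = 0, allometry_slope = 0,
                         divergence_vector_scale = 0)
  s <- decompose_symmetry(d$landmarks, sc)
  expect_lt(max(fa_scores(s)$per_specimen), 1e-9)

  # monotonicity in the FA noise level over replicates
  mean_fa <- vapply(c(0.001, 0.005, 0.01), function(sig) {
    mean(vapply(1:20, function(r) {
      dd <- quick_object_data(seed = 100 * r, fa_sd = sig)
      mean(fa_scores(decompose_symmetry(dd$landmarks, sc))$per_specimen)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_fa) > 0))

  # group means are reported per label
  f <- fa_scores(s, groups = rep(c("a", "b"), each = 6))
  expect_named(f$group_means, c("a", "b"))
  expect_error(fa_scores(list(symmetric = s$symmetric)), "aligned_sample")
})

test_that("FA scores are invariant to similarity transforms of the raw input", {
  sc <- small_object_scheme()
  d <- quick_object_data(seed = 6)
  s1 <- fa_scores(decompose_symmetry(d$landmarks, sc))$per_specimen
  set.seed(99)
  moved <- d$landmarks
  for (i in seq_len(dim(moved)[3])) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    moved[, , i] <- sweep(moved[, , i] %*% Q * exp(runif(1, -0.5, 0.5)),
                          2, runif(3, -10, 10), `+`)
  }
  s2 <- fa_scores(decompose_symmetry(moved, sc))$per_specimen
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("procrustes_distance is a metric on shape vectors in a common frame", {
  expect_identical(procrustes_distance(1:5, 1:5), 0)
  set.seed(30)
  a <- rnorm(12); b <- rnorm(12); c_ <- rnorm(12)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a))
  # hand-specified planar 4-landmark shapes: difference (0.3, -0.4) -> 0.5
  u <- c(0.1, 0.2, -0.1, 0.3,  0.0, 0.1, 0.4, -0.2,  0, 0, 0, 0)
  v <- u; v[1] <- u[1] + 0.3; v[5] <- u[5] - 0.4
  expect_equal(procrustes_distance(u, v), 0.5)
  # triangle inequality on random triples
  for (r in 1:10) {
    x <- rnorm(9); y <- rnorm(9); z <- rnorm(9)
    expect_lte(procrustes_distance(x, z),
               procrustes_distance(x, y) + procrustes_distance(y, z) + 1e-12)
  }
  expect_error(procrustes_distance(1:4, 1:5), "mismatched")
})
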