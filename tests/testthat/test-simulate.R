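test_that("parental shapes honor the requested divergence and are exactly symmetric", {
  sc <- small_object_scheme()
  same <- simulate_parental_shapes(sc, seed = 1, divergence_vector_scale = 0)
  expect_identical(same$mus_mean, same$dom_mean)

  par <- simulate_parental_shapes(sc, seed = 2, divergence_vector_scale = 0.026)
  # realized distance after superimposition within 5% of the request
  fit <- gpa(array(c(par$mus_mean, par$dom_mean), dim = c(8, 3, 2)))
  d <- procrustes_distance(fit$aligned[1, ], fit$aligned[2, ])
  expect_lt(abs(d - 0.026) / 0.026, 0.05)
  # both parents superimpose exactly on their reflected-relabeled copies
  for (shape in list(par$mus_mean, par$dom_mean)) {
    f <- gpa(array(c(shape, reflect_relabel(shape, sc)), dim = c(8, 3, 2)))
    expect_lt(procrustes_distance(f$aligned[1, ], f$aligned[2, ]), 1e-9)
  }
})

test_that("the generator is bit-deterministic and leaves no global RNG trace", {
  p <- simulation_params(small_matching_scheme(),
                         group_sizes = c(2, 2, 0, 0, 0, 0, 0, 0, 2, 2),
                         residual_sd = 0.01, fa_sd = 0.01, seed = 42)
  set.seed(1); before <- rnorm(1)
  d1 <- simulate_hybrid_dataset(p)
  d2 <- simulate_hybrid_dataset(p)
  expect_identical(d1, d2)
  set.seed(1)
  expect_identical(rnorm(1), before)
})

test_that("noiseless specimens at the parental end superimpose onto the parental mean", {
  sc <- small_object_scheme()
  p <- simulation_params(sc, group_sizes = c(5, rep(0, 9)),
                         divergence_vector_scale = 0, seed = 8)
  d <- simulate_hybrid_dataset(p)
  tmpl <- d$truth$mus_mean
  arr <- array(0, dim = c(8, 3, 6))
  arr[, , 1:5] <- d$landmarks
  arr[, , 6] <- tmpl
  fit <- gpa(arr)
  for (i in 1:5) {
    expect_lt(procrustes_distance(fit$aligned[i, ], fit$aligned[6, ]), 1e-9)
  }
})

test_that("noiseless additive data put group means on a straight admixture line", {
  sc <- mid_object_scheme()
  p <- simulation_params(sc, group_sizes = c(4, 4, 0, 4, 0, 4, 0, 0, 4, 4),
                         divergence_vector_scale = 0.04, seed = 9)
  d <- simulate_hybrid_dataset(p)
  s <- decompose_symmetry(d$landmarks, sc)
  g <- assign_hybrid_groups(d$covariates)$covariates$group
  means <- t(vapply(sort(unique(g)), function(k) colMeans(s$symmetric[g == k, , drop = FALSE]),
                    numeric(ncol(s$symmetric))))
  ref <- means[nrow(means), ] - means[1, ]
  for (i in 2:(nrow(means) - 1)) {
    expect_lt(angle_test(means[i, ] - means[1, ], ref)$angle_deg, 0.1)
  }
})

test_that("calibration hits the requested admixture variance fraction in expectation", {
  p <- simulation_params(mid_object_scheme(), group_sizes = design_group_sizes(),
                         divergence_vector_scale = 0.03,
                         sex_effect_vector_scale = 0.006, family_sd = 8e-4,
                         allometry_slope = 5e-4, families_per_group = design_families())
  p <- calibrate_residual_sd(p, 10)
  v <- expected_variance_components(p)
  expect_equal(100 * v[["admixture"]] /
                 (v[["admixture"]] + v[["sex"]] + v[["family"]] + v[["residual"]]),
               10, tolerance = 1e-10)
  expect_error(calibrate_residual_sd(p, 99.9), "unattainable")
})

test_that("realized covariate variance fractions match pipeline estimates at full size", {
  p <- skull_sim_params(seed = 31)
  d <- simulate_hybrid_dataset(p)
  rep <- run_full_pipeline(d$landmarks, p$scheme, d$covariates, n_pcs = 10,
                           n_perm = 99, seed = 4)
  # the generator's bookkeeping and the pipeline's estimates agree
  expect_lt(abs(rep$covariate_checks$sex_pct - d$truth$realized_pct[["sex"]]), 1.5)
  expect_lt(abs(rep$allometry$pct_var_explained - d$truth$realized_pct[["allometry"]]), 1.5)
})

test_that("fixture datasets are pipeline-sized and carry both symmetry designs", {
  fx <- fixture_set(1)
  expect_identical(dim(fx$object$landmarks)[3], 12L)
  expect_identical(dim(fx$matching$landmarks$left)[3], 12L)
  expect_identical(fx$object$params$scheme$mode, "object")
  expect_identical(fx$matching$params$scheme$mode, "matching")
  expect_true(all(table(assign_hybrid_groups(fx$object$covariates)$covariates$group) >= 2))
})
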