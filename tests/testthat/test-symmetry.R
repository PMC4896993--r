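test_that("symmetry scheme validation enforces coverage and disjointness", {
  expect_s3_class(small_object_scheme(), "symmetry_scheme")
  # overlapping pair/midline indices
  expect_error(symmetry_scheme("object", pairs = cbind(1:3, 4:6), midline = c(6, 7)),
               "disjoint")
  # incomplete coverage
  expect_error(symmetry_scheme("object", pairs = cbind(1:3, 4:6), midline = 8,
                               n_landmarks = 8), "cover")
  # matching symmetry admits no midline points
  expect_error(symmetry_scheme("matching", n_landmarks = 5, midline = 1), "midline")
})

test_that("shape-space dimensionality follows the symmetry design", {
  expect_identical(shape_space_dim(skull_scheme()), 67L)
  expect_identical(shape_space_dim(mandible_scheme()), 32L)
  # three midline points lie in the symmetry plane: a planar triangle has a
  # 2-dimensional shape space
  expect_identical(shape_space_dim(symmetry_scheme("object", midline = 1:3)), 2L)
})

test_that("reflect_relabel is an exact involution and matches a hand-built case", {
  sc <- small_object_scheme()
  set.seed(41)
  cfg <- matrix(rnorm(24), 8, 3)
  expect_identical(reflect_relabel(reflect_relabel(cfg, sc), sc), cfg)

  # hand-built: pairs (1,4), (2,5), (3,6); midline 7, 8; axis 1 negated and
  # pair labels swapped, midline labels kept
  cfg2 <- rbind(
    c(-1, 0, 0),   # 1 (left of pair 1)
    c(-2, 1, 0),   # 2
    c(-3, 0, 2),   # 3
    c(1, 0, 0),    # 4 (right of pair 1)
    c(2, 1, 0),    # 5
    c(3, 0, 2),    # 6
    c(0, 5, 1),    # 7 midline
    c(0, -4, 2)    # 8 midline
  )
  expected <- rbind(
    c(-1, 0, 0), c(-2, 1, 0), c(-3, 0, 2),
    c(1, 0, 0), c(2, 1, 0), c(3, 0, 2),
    c(0, 5, 1), c(0, -4, 2)
  )
  expect_equal(reflect_relabel(cfg2, sc), expected)

  # a perfectly mirror-symmetric configuration superimposes on its reflection
  fit <- gpa(array(c(cfg2, reflect_relabel(cfg2, sc)), dim = c(8, 3, 2)))
  expect_lt(procrustes_distance(fit$aligned[1, ], fit$aligned[2, ]), 1e-9)

  # scheme/config mismatch
  expect_error(reflect_relabel(cfg2[1:5, ], sc), "fewer landmarks")
})
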