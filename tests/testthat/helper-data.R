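# Shared small schemes and generated datasets for the tests.

small_object_scheme <- function() {
  symmetry_scheme("object", pairs = cbind(1:3, 4:6), midline = 7:8)
}

small_matching_scheme <- function() {
  symmetry_scheme("matching", n_landmarks = 5L)
}

mid_object_scheme <- function() {
  symmetry_scheme("object", pairs = cbind(1:6, 7:12), midline = 13:16)
}

# Decile sizes matching the emulated study design (249 specimens, bin 7 empty).
design_group_sizes <- function() c(6L, 39L, 67L, 23L, 31L, 26L, 31L, 0L, 9L, 17L)

design_families <- function() c(1L, 9L, 17L, 7L, 5L, 12L, 10L, 1L, 3L, 7L)

# A quick noisy object-symmetry dataset for property tests.
quick_object_data <- function(n_per_bin = c(3, 2, 0, 0, 2, 0, 0, 0, 2, 3),
                              seed = 1L, ...) {
  defaults <- list(scheme = small_object_scheme(), group_sizes = n_per_bin,
                   families_per_group = rep(2L, 10L),
                   divergence_vector_scale = 0.05, residual_sd = 0.004,
                   family_sd = 0.002, sex_effect_vector_scale = 0.01,
                   allometry_slope = 1e-3, da_vector_scale = 0.005,
                   fa_sd = 0.003, seed = seed)
  p <- do.call(simulation_params, utils::modifyList(defaults, list(...)))
  simulate_hybrid_dataset(p)
}

# Apply a random rotation + scaling + translation (draws from the current
# RNG state; call set.seed beforehand for reproducibility).
random_similarity_transform <- function(coords) {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  s <- exp(runif(1, -1, 1))
  t_vec <- runif(3, -5, 5)
  sweep(coords %*% Q * s, 2L, t_vec, `+`)
}
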