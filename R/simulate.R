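# Synthetic landmark-data generator. Emulates the statistical structure a
# polygenic additive architecture imposes on craniofacial shape across an
# admixture gradient: two parental mean shapes, per-specimen expected shape
# linear in the admixture proportion h, family, sex and allometric effects,
# directional plus fluctuating asymmetry, and nuisance position / orientation
# / scale applied to the raw output.

#' Default skull-like symmetry scheme (17 pairs + 10 midline landmarks)
#' @return A [symmetry_scheme()] with object symmetry, 44 landmarks.
#' @export
skull_scheme <- function() {
  symmetry_scheme("object", pairs = cbind(1:17, 18:34), midline = 35:44)
}

#' Default mandible-like symmetry scheme (13 landmarks per side)
#' @return A [symmetry_scheme()] with matching symmetry, 13 landmarks.
#' @export
mandible_scheme <- function() {
  symmetry_scheme("matching", n_landmarks = 13L)
}

# Deterministic smooth template: landmarks on low-frequency space curves,
# exactly mirror-symmetric for object schemes; centered, unit centroid size.
# Guarantees non-degenerate (non-collinear, distinct) configurations for any
# k >= 1 (object: k + l >= 3).
template_configuration <- function(scheme) {
  L <- scheme$n_landmarks
  coords <- matrix(0, L, 3L)
  right_point <- function(t) {
    c(0.35 + 0.15 * cos(2 * pi * t),
      0.9 * (t - 0.5),
      0.25 * sin(2 * pi * t) + 0.1 * cos(4 * pi * t))
  }
  if (scheme$mode == "object") {
    k <- scheme$k
    for (j in seq_len(k)) {
      r <- right_point(j / (k + 1))
      coords[scheme$pairs[j, 2L], ] <- r
      lr <- r
      lr[scheme$axis] <- -lr[scheme$axis]
      coords[scheme$pairs[j, 1L], ] <- lr
    }
    l <- scheme$l
    for (j in seq_len(l)) {
      u <- j / (l + 1)
      m <- c(0, 0.55 * cos(pi * u), 0.3 * sin(pi * u) + 0.15 * sin(3 * pi * u))
      m[scheme$axis] <- 0
      # place the in-plane components on the two non-reflected axes
      others <- setdiff(1:3, scheme$axis)
      m[others] <- c(0.55 * cos(pi * u), 0.3 * sin(pi * u) + 0.15 * sin(3 * pi * u))
      coords[scheme$midline[j], ] <- m
    }
  } else {
    for (j in seq_len(L)) {
      t <- j / (L + 1)
      coords[j, ] <- c(0.3 * cos(2 * pi * t) + 0.1 * sin(5 * t),
                       0.9 * (t - 0.5),
                       0.3 * sin(2 * pi * t) + 0.12 * cos(3 * pi * t))
    }
  }
  coords <- sweep(coords, 2L, colMeans(coords))
  coords / sqrt(sum(coords^2))
}

# Orthonormal basis of the similarity-nuisance subspace (3 translations,
# 3 rotations, 1 scale) at a centered unit-size template, in flattened
# coordinates.
nuisance_basis <- function(template) {
  L <- nrow(template)
  gens <- list(
    cbind(rep(1, L), 0, 0), cbind(0, rep(1, L), 0), cbind(0, 0, rep(1, L)),
    template[, c(2, 1, 3)] * rep(c(-1, 1, 0), each = L),
    template[, c(3, 2, 1)] * rep(c(-1, 0, 1), each = L),
    template[, c(1, 3, 2)] * rep(c(0, -1, 1), each = L),
    template
  )
  B <- vapply(gens, flatten_config, numeric(3L * L))
  qr.Q(qr(B))[, seq_len(qr(B)$rank), drop = FALSE]
}

project_out <- function(v, B) drop(v - B %*% crossprod(B, v))

# Draw a unit-norm shape effect in the appropriate subspace: symmetric or
# antisymmetric for object schemes (exact eigenspace projections), and free of
# similarity-nuisance components in all cases.
draw_effect_vector <- function(template, scheme, kind = c("symmetric", "antisymmetric"),
                               basis = nuisance_basis(template)) {
  kind <- match.arg(kind)
  L <- nrow(template)
  v <- stats::rnorm(3L * L)
  if (scheme$mode == "object") {
    v <- if (kind == "symmetric") symmetrize_config(unflatten_config(v, L), scheme)
         else antisymmetrize_config(unflatten_config(v, L), scheme)
    v <- flatten_config(v)
  }
  v <- project_out(v, basis)
  v / sqrt(sum(v^2))
}

# Projection of iid noise into the effect subspace (keeps the per-coordinate
# noise level interpretable; the projections are orthogonal).
draw_noise_vector <- function(sd, template, scheme, kind, basis) {
  if (sd <= 0) return(numeric(3L * nrow(template)))
  L <- nrow(template)
  v <- stats::rnorm(3L * L, sd = sd)
  if (scheme$mode == "object") {
    v <- if (kind == "symmetric") symmetrize_config(unflatten_config(v, L), scheme)
         else antisymmetrize_config(unflatten_config(v, L), scheme)
    v <- flatten_config(v)
  }
  project_out(v, basis)
}

# Haar-distributed proper rotation.
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Variance of the admixture proportion implied by a group design
#'
#' The admixture proportion h is drawn uniformly within each decile bin, with
#' bins weighted by the group sizes; this returns the variance of that
#' mixture distribution (used to calibrate effect magnitudes).
#'
#' @param group_sizes Length-10 vector of per-decile specimen counts.
#' @return Variance of h (on the 0-1 scale).
#' @export
admixture_variance <- function(group_sizes) {
  stopifnot(length(group_sizes) == 10L, all(group_sizes >= 0))
  w <- group_sizes / sum(group_sizes)
  mids <- (0:9) / 10 + 0.05
  m <- sum(w * mids)
  sum(w * (mids^2 + 1 / 1200)) - m^2
}

#' Simulation parameters for a hybrid-zone landmark dataset
#'
#' Bundles the generator's settings. The defaults describe the study design
#' the generator emulates: 249 specimens in decile admixture bins with counts
#' `c(6, 39, 67, 23, 31, 26, 31, 0, 9, 17)` (bin 7 empty), an additive
#' admixture effect, family, sex and allometric shape effects, directional
#' plus fluctuating asymmetry, and nuisance position/orientation/scale on the
#' raw coordinates. [skull_sim_params()] and [mandible_sim_params()] supply
#' magnitudes calibrated for the two craniofacial traits.
#'
#' @param scheme A [symmetry_scheme()].
#' @param group_sizes Length-10 vector of per-decile specimen counts.
#' @param divergence_vector_scale Procrustes-units norm of the shape
#'   difference between the two parental means (h = 0 vs h = 1).
#' @param additive If `FALSE`, a dominance-like quadratic term
#'   `h(1-h) * dominance_scale` along its own direction is added.
#' @param dominance_scale Norm of the quadratic term at its maximum
#'   (`h = 0.5` gives a quarter of this).
#' @param family_sd Per-coordinate standard deviation of the family-shared
#'   shape deviation.
#' @param families_per_group Length-10 integer vector; specimens within a
#'   group are assigned round-robin to this many families.
#' @param residual_sd Per-coordinate standard deviation of the individual
#'   symmetric shape noise.
#' @param allometry_slope Norm of the shape change per unit centroid size.
#' @param cs_mean,cs_sd Mean and standard deviation of centroid size (device
#'   units).
#' @param sex_effect_vector_scale Norm of the male-female mean shape
#'   difference.
#' @param da_vector_scale Norm of the directional-asymmetry vector.
#' @param fa_sd Per-coordinate standard deviation of the fluctuating-
#'   asymmetry noise.
#' @param nuisance List with `translation` (uniform range, device units) and
#'   `jitter_sd` (per-coordinate digitization noise in device units; the
#'   default 0 reflects that digitization error is already subsumed in
#'   `residual_sd`/`fa_sd`); random orientation is always applied.
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(scheme,
                              group_sizes = c(6, 39, 67, 23, 31, 26, 31, 0, 9, 17),
                              divergence_vector_scale = 0.026,
                              additive = TRUE,
                              dominance_scale = 0,
                              family_sd = 0,
                              families_per_group = c(1, 9, 17, 7, 5, 12, 10, 0, 3, 7),
                              residual_sd = 0,
                              allometry_slope = 0,
                              cs_mean = 100,
                              cs_sd = 5,
                              sex_effect_vector_scale = 0,
                              da_vector_scale = 0,
                              fa_sd = 0,
                              nuisance = list(translation = 50, jitter_sd = 0),
                              seed = 1L) {
  stopifnot(inherits(scheme, "symmetry_scheme"),
            length(group_sizes) == 10L, all(group_sizes >= 0),
            length(families_per_group) == 10L,
            divergence_vector_scale >= 0, family_sd >= 0, residual_sd >= 0,
            fa_sd >= 0, cs_sd >= 0, cs_mean > 0)
  structure(
    list(scheme = scheme, group_sizes = as.integer(group_sizes),
         divergence_vector_scale = divergence_vector_scale,
         additive = isTRUE(additive), dominance_scale = dominance_scale,
         family_sd = family_sd,
         families_per_group = pmax(as.integer(families_per_group), 1L),
         residual_sd = residual_sd, allometry_slope = allometry_slope,
         cs_mean = cs_mean, cs_sd = cs_sd,
         sex_effect_vector_scale = sex_effect_vector_scale,
         da_vector_scale = da_vector_scale, fa_sd = fa_sd,
         nuisance = utils::modifyList(list(translation = 50, jitter_sd = 0), nuisance),
         seed = as.integer(seed)),
    class = "simulation_params"
  )
}

#' Expected variance components of the symmetric shape
#'
#' Closed-form expectations, in squared Procrustes units, of the symmetric
#' shape variance contributed by each generator term: admixture
#' (`var(h) * divergence^2`), sex (`0.25 * scale^2`), allometry
#' (`slope^2 * cs_sd^2`), family (`family_sd^2 * q`) and residual noise
#' (`residual_sd^2 * q`), where `q` is the symmetric shape-space dimension.
#'
#' @param params A [simulation_params()].
#' @return Named numeric vector of variance components.
#' @export
expected_variance_components <- function(params) {
  q <- shape_space_dim(params$scheme)
  c(admixture = admixture_variance(params$group_sizes) * params$divergence_vector_scale^2,
    sex = 0.25 * params$sex_effect_vector_scale^2,
    allometry = params$allometry_slope^2 * params$cs_sd^2,
    family = params$family_sd^2 * q,
    residual = params$residual_sd^2 * q)
}

#' Calibrate residual noise for a target admixture variance fraction
#'
#' Solves for the `residual_sd` that makes the admixture term account for
#' `target_pct` percent of the size-corrected symmetric shape variance (the
#' quantity the pipeline's shape-on-admixture regression estimates;
#' allometric variance is excluded because the pipeline removes it before
#' regressing).
#'
#' @param params A [simulation_params()].
#' @param target_pct Target percentage in (0, 100).
#' @return `params` with `residual_sd` replaced.
#' @export
calibrate_residual_sd <- function(params, target_pct) {
  stopifnot(inherits(params, "simulation_params"), target_pct > 0, target_pct < 100)
  v <- expected_variance_components(params)
  q <- shape_space_dim(params$scheme)
  res_var <- v[["admixture"]] * (100 / target_pct - 1) - v[["sex"]] - v[["family"]]
  if (res_var <= 0) {
    stop("target fraction unattainable: fixed effects already exceed the implied total variance",
         call. = FALSE)
  }
  params$residual_sd <- sqrt(res_var / q)
  params
}

#' Skull-like simulation parameters
#'
#' Defaults calibrated so the symmetric-shape variance decomposes roughly as
#' 8.4\% admixture, 5.4\% allometry, 1.9\% sex, 12\% family and the rest
#' individual noise, with a parental divergence of 0.026 Procrustes units and
#' mean fluctuating asymmetry near 0.01 — magnitudes representative of mouse
#' skull data across a subspecies hybrid zone.
#'
#' @param ... Overrides passed to [simulation_params()].
#' @return A [simulation_params()].
#' @export
skull_sim_params <- function(...) {
  defaults <- list(
    scheme = skull_scheme(),
    divergence_vector_scale = 0.026,
    sex_effect_vector_scale = 0.00596,
    allometry_slope = 5.02e-4, cs_mean = 350, cs_sd = 10,
    family_sd = 9.14e-4,
    residual_sd = 2.245e-3,
    da_vector_scale = 0.003,
    fa_sd = 1.31e-3
  )
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

#' Mandible-like simulation parameters
#'
#' Defaults calibrated so the symmetric-shape variance decomposes roughly as
#' 10.8\% admixture, 1.8\% allometry, 3.9\% sex, 12\% family and the rest
#' individual noise, with a parental divergence of 0.042 Procrustes units and
#' mean fluctuating asymmetry near 0.028.
#'
#' @param ... Overrides passed to [simulation_params()].
#' @return A [simulation_params()].
#' @export
mandible_sim_params <- function(...) {
  defaults <- list(
    scheme = mandible_scheme(),
    divergence_vector_scale = 0.042,
    sex_effect_vector_scale = 0.01216,
    allometry_slope = 8.26e-4, cs_mean = 120, cs_sd = 5,
    family_sd = 1.885e-3,
    residual_sd = 4.60e-3,
    da_vector_scale = 0.004,
    fa_sd = 4.95e-3
  )
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

#' Simulate the two parental mean shapes
#'
#' Builds a smooth, non-degenerate, exactly mirror-symmetric (for object
#' schemes) template as the first parental mean, and adds a random symmetric
#' shape perturbation of exactly the requested Procrustes norm to obtain the
#' second.
#'
#' @param scheme A [symmetry_scheme()].
#' @param seed Integer seed.
#' @param divergence_vector_scale Norm of the mean-shape difference.
#' @return A list: `mus_mean`, `dom_mean` (`L x 3` matrices), `delta`
#'   (flattened difference vector).
#' @export
simulate_parental_shapes <- function(scheme, seed = 1L,
                                     divergence_vector_scale = 0.026) {
  stopifnot(inherits(scheme, "symmetry_scheme"))
  mus <- template_configuration(scheme)
  basis <- nuisance_basis(mus)
  delta <- with_seed(seed, draw_effect_vector(mus, scheme, "symmetric", basis)) *
    divergence_vector_scale
  dom <- mus + unflatten_config(delta, nrow(mus))
  list(mus_mean = mus, dom_mean = dom, delta = delta)
}

#' Simulate a hybrid-zone landmark dataset
#'
#' Generates raw landmark configurations plus a covariate table and a truth
#' record. Per specimen: the admixture proportion `h` is drawn uniformly
#' within its group's decile bin; the expected symmetric shape is
#' `mus + h * (dom - mus)` (plus an optional dominance-like `h(1-h)` term),
#' plus a family-shared deviation, a sex effect, an allometric term
#' proportional to centroid size, and residual symmetric noise; the
#' asymmetric part is a fixed directional-asymmetry vector plus individual
#' fluctuating-asymmetry noise. Object schemes emit one whole configuration
#' per specimen (symmetric + asymmetric parts); matching schemes emit left
#' and right configurations (`right = S + A`, `left = reflect(S - A)`).
#' Each raw configuration finally receives a random rotation, translation,
#' scaling to its centroid size, and optional digitization jitter.
#'
#' @param params A [simulation_params()].
#' @return A list: `landmarks` (`L x 3 x N` array, or `list(left, right)` for
#'   matching schemes), `covariates` (data.frame with `specimen_id`,
#'   `pct_dom`, `family_id`, `sex`, `age_weeks`), `truth` (true means, effect
#'   vectors, per-specimen values and realized variance fractions), `params`.
#' @export
simulate_hybrid_dataset <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  scheme <- params$scheme
  L <- scheme$n_landmarks
  n_total <- sum(params$group_sizes)
  if (n_total < 1L) stop("group_sizes sum to zero", call. = FALSE)

  with_seed(params$seed, {
    mus <- template_configuration(scheme)
    basis <- nuisance_basis(mus)
    mus_flat <- flatten_config(mus)
    delta <- draw_effect_vector(mus, scheme, "symmetric", basis) *
      params$divergence_vector_scale
    dom_flat <- mus_flat + delta
    dominance <- if (!params$additive && params$dominance_scale > 0) {
      draw_effect_vector(mus, scheme, "symmetric", basis) * params$dominance_scale
    } else numeric(3L * L)
    sex_vec <- if (params$sex_effect_vector_scale > 0) {
      draw_effect_vector(mus, scheme, "symmetric", basis) * params$sex_effect_vector_scale
    } else numeric(3L * L)
    allo_vec <- if (params$allometry_slope > 0) {
      draw_effect_vector(mus, scheme, "symmetric", basis) * params$allometry_slope
    } else numeric(3L * L)
    da_vec <- if (params$da_vector_scale > 0) {
      draw_effect_vector(mus, scheme, "antisymmetric", basis) * params$da_vector_scale
    } else numeric(3L * L)

    groups <- rep(0:9, params$group_sizes)
    n <- length(groups)
    specimen_id <- sprintf("S%03d", seq_len(n))
    h <- stats::runif(n, groups / 10, (groups + 1) / 10)
    family_id <- character(n)
    for (g in unique(groups)) {
      idx <- which(groups == g)
      family_id[idx] <- sprintf("G%dF%02d",
                                g, rep_len(seq_len(params$families_per_group[g + 1L]),
                                           length(idx)))
    }
    fams <- unique(family_id)
    fam_effects <- matrix(0, length(fams), 3L * L, dimnames = list(fams, NULL))
    for (f in seq_along(fams)) {
      fam_effects[f, ] <- draw_noise_vector(params$family_sd, mus, scheme,
                                            "symmetric", basis)
    }
    sex <- sample(c("m", "f"), n, replace = TRUE)
    cs <- stats::rnorm(n, params$cs_mean, params$cs_sd)
    cs <- pmax(cs, 0.1 * params$cs_mean)
    age_weeks <- sample(9:13, n, replace = TRUE)

    S <- matrix(0, n, 3L * L)   # symmetric part (unit-size frame)
    A <- matrix(0, n, 3L * L)   # asymmetric part
    for (i in seq_len(n)) {
      S[i, ] <- mus_flat + h[i] * delta +
        h[i] * (1 - h[i]) * dominance +
        fam_effects[family_id[i], ] +
        (if (sex[i] == "m") 0.5 else -0.5) * sex_vec +
        (cs[i] - params$cs_mean) * allo_vec +
        draw_noise_vector(params$residual_sd, mus, scheme, "symmetric", basis)
      A[i, ] <- da_vec +
        draw_noise_vector(params$fa_sd, mus, scheme, "antisymmetric", basis)
    }

    apply_nuisance <- function(cfg, target_cs) {
      cfg <- sweep(cfg, 2L, colMeans(cfg))
      cfg <- cfg / sqrt(sum(cfg^2)) * target_cs
      cfg <- cfg %*% random_rotation()
      cfg <- sweep(cfg, 2L, stats::runif(3, -params$nuisance$translation,
                                         params$nuisance$translation), `+`)
      if (params$nuisance$jitter_sd > 0) {
        cfg <- cfg + matrix(stats::rnorm(length(cfg), sd = params$nuisance$jitter_sd),
                            nrow(cfg), 3L)
      }
      cfg
    }

    if (scheme$mode == "object") {
      landmarks <- array(0, dim = c(L, 3L, n),
                         dimnames = list(NULL, c("x", "y", "z"), specimen_id))
      for (i in seq_len(n)) {
        landmarks[, , i] <- apply_nuisance(unflatten_config(S[i, ] + A[i, ], L), cs[i])
      }
    } else {
      left <- right <- array(0, dim = c(L, 3L, n),
                             dimnames = list(NULL, c("x", "y", "z"), specimen_id))
      for (i in seq_len(n)) {
        right[, , i] <- apply_nuisance(unflatten_config(S[i, ] + A[i, ], L), cs[i])
        left[, , i] <- apply_nuisance(
          reflect_axis(unflatten_config(S[i, ] - A[i, ], L), scheme$axis), cs[i])
      }
      landmarks <- list(left = left, right = right)
    }

    covariates <- data.frame(specimen_id = specimen_id, pct_dom = 100 * h,
                             family_id = family_id, sex = sex,
                             age_weeks = age_weeks, stringsAsFactors = FALSE)

    # realized variance fractions of the generated symmetric parts
    comp_ss <- function(M) sum(sweep(M, 2L, colMeans(M))^2)
    adm_mat <- outer(h, delta)
    sex_mat <- outer(ifelse(sex == "m", 0.5, -0.5), sex_vec)
    allo_mat <- outer(cs - params$cs_mean, allo_vec)
    fam_mat <- fam_effects[family_id, , drop = FALSE]
    total_ss <- comp_ss(S)
    realized <- c(admixture = comp_ss(adm_mat), sex = comp_ss(sex_mat),
                  allometry = comp_ss(allo_mat), family = comp_ss(fam_mat)) /
      max(total_ss, .Machine$double.eps) * 100

    truth <- list(
      mus_mean = mus, dom_mean = unflatten_config(dom_flat, L),
      delta = delta, dominance_vector = dominance, sex_vector = sex_vec,
      allometry_vector = allo_vec, da_vector = da_vec,
      per_specimen = data.frame(specimen_id = specimen_id, h = h,
                                family_id = family_id, sex = sex, cs = cs,
                                group = groups, stringsAsFactors = FALSE),
      realized_pct = realized,
      expected_components = expected_variance_components(params)
    )

    list(landmarks = landmarks, covariates = covariates, truth = truth,
         params = params)
  })
}

#' Small fixture datasets for fast end-to-end runs
#'
#' Two tiny simulated datasets — an object-symmetry design (3 pairs + 2
#' midline landmarks) and a matching design (5 landmarks per side), 12
#' specimens each in five occupied admixture bins — sized so the full
#' pipeline completes in a few seconds.
#'
#' @param seed Integer seed.
#' @return A list with elements `object` and `matching`, each a
#'   [simulate_hybrid_dataset()] result.
#' @export
fixture_set <- function(seed = 1L) {
  sizes <- c(3, 2, 0, 0, 2, 0, 0, 0, 2, 3)
  fams <- c(2, 2, 1, 1, 2, 1, 1, 1, 2, 2)
  obj <- simulation_params(
    symmetry_scheme("object", pairs = cbind(1:3, 4:6), midline = 7:8),
    group_sizes = sizes, families_per_group = fams,
    divergence_vector_scale = 0.05, residual_sd = 0.004, family_sd = 0.002,
    sex_effect_vector_scale = 0.01, allometry_slope = 1e-3, cs_mean = 100,
    cs_sd = 5, da_vector_scale = 0.005, fa_sd = 0.003, seed = seed
  )
  mat <- simulation_params(
    symmetry_scheme("matching", n_landmarks = 5L),
    group_sizes = sizes, families_per_group = fams,
    divergence_vector_scale = 0.06, residual_sd = 0.005, family_sd = 0.002,
    sex_effect_vector_scale = 0.012, allometry_slope = 1e-3, cs_mean = 80,
    cs_sd = 4, da_vector_scale = 0.006, fa_sd = 0.004, seed = seed + 1L
  )
  list(object = simulate_hybrid_dataset(obj),
       matching = simulate_hybrid_dataset(mat))
}
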