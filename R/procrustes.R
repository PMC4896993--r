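#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks from their
#' centroid — the standard size measure in geometric morphometrics. Scaling
#' the coordinates by a constant `c` scales centroid size by `c`.
#'
#' @param coords An `L x 3` coordinate matrix or an `L x 3 x N` array (one
#'   value per specimen is returned for an array).
#' @return A positive scalar, or a numeric vector for array input.
#' @examples
#' sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' centroid_size(sq) # sqrt(2)
#' @export
centroid_size <- function(coords) {
  if (length(dim(coords)) == 3L) {
    return(apply(coords, 3L, centroid_size))
  }
  check_config(coords)
  centered <- sweep(coords, 2L, colMeans(coords))
  cs <- sqrt(sum(centered^2))
  if (cs <= 0) stop("degenerate configuration: all landmarks coincide", call. = FALSE)
  cs
}

# Optimal proper rotation R (det = +1) minimizing ||X %*% R - M||_F,
# by singular value decomposition of the cross-covariance.
rotate_onto <- function(X, M) {
  H <- crossprod(X, M)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Orthogonal projection of unit-size aligned configurations onto the tangent
# hyperplane at the consensus (removes the residual scale dimension; the
# translation and rotation dimensions are already exactly zeroed by centering
# and by the optimality of the fitted rotations).
tangent_project <- function(flat, consensus_flat) {
  drop(flat - outer(drop(flat %*% consensus_flat) - 1, consensus_flat))
}

# Core iterative superimposition shared by gpa() and decompose_symmetry().
# `symmetrize_with`, when a scheme, forces the consensus to be exactly
# mirror-symmetric at every iteration (object-symmetry joint fits).
gpa_core <- function(arr, tol = 1e-10, max_iter = 100L, symmetrize_with = NULL) {
  L <- dim(arr)[1]
  n <- dim(arr)[3]
  cs <- numeric(n)
  X <- arr
  for (i in seq_len(n)) {
    check_nondegenerate(arr[, , i], sprintf("configuration %d", i))
    centered <- sweep(arr[, , i], 2L, colMeans(arr[, , i]))
    cs[i] <- sqrt(sum(centered^2))
    X[, , i] <- centered / cs[i]
  }

  normalize <- function(M) {
    M <- sweep(M, 2L, colMeans(M))
    M <- M / sqrt(sum(M^2))
    if (!is.null(symmetrize_with)) {
      M <- symmetrize_config(M, symmetrize_with)
      M <- sweep(M, 2L, colMeans(M))
      M <- M / sqrt(sum(M^2))
    }
    M
  }

  consensus <- normalize(X[, , 1L])
  aligned <- X
  Q_prev <- Inf
  converged <- FALSE
  iter <- 0L
  if (n == 1L) {
    aligned[, , 1L] <- consensus
    converged <- TRUE
  }
  while (n > 1L && iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      aligned[, , i] <- X[, , i] %*% rotate_onto(X[, , i], consensus)
    }
    consensus <- normalize(apply(aligned, c(1L, 2L), mean))
    Q <- sum(sweep(aligned, c(1L, 2L), consensus)^2)
    if (is.finite(Q_prev) && abs(Q_prev - Q) <= tol * max(Q, 1e-12)) {
      converged <- TRUE
      Q_prev <- Q
      break
    }
    Q_prev <- Q
  }
  if (n > 1L && !converged) {
    stop(sprintf("generalized Procrustes analysis did not converge in %d iterations (last residual change %.3e)",
                 max_iter, abs(Q_prev)), call. = FALSE)
  }
  # final rotation pass against the settled consensus, then tangent projection
  for (i in seq_len(n)) {
    aligned[, , i] <- X[, , i] %*% rotate_onto(X[, , i], consensus)
  }
  flat <- flatten_configs(aligned)
  cons_flat <- flatten_config(consensus)
  flat <- tangent_project(flat, cons_flat)
  list(aligned = flat, consensus = cons_flat, centroid_sizes = cs,
       iterations = iter, converged = converged, rss = if (is.finite(Q_prev)) Q_prev else 0)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of landmark configurations: each configuration is
#' centered, scaled to unit centroid size (partial Procrustes fit), and
#' rotated onto the current consensus by the closed-form orthogonal Procrustes
#' solution restricted to proper rotations; the consensus is then re-estimated
#' and the cycle repeats until the summed squared deviation stabilizes.
#' Aligned coordinates are finally projected orthogonally onto the tangent
#' hyperplane at the consensus, so Euclidean distances between rows are
#' Procrustes (tangent-space) distances.
#'
#' @param configs An `L x 3 x N` array of raw landmark configurations (same
#'   landmarks in the same order for every specimen).
#' @param tol Convergence tolerance on the relative change in summed squared
#'   deviations from the consensus.
#' @param max_iter Maximum number of superimposition iterations.
#' @return An object of class `gpa_fit`: `aligned` (`N x 3L` matrix of tangent
#'   coordinates), `mean_shape` (length-`3L` consensus), `centroid_sizes`
#'   (raw centroid sizes), `iterations`, `converged`.
#' @seealso [decompose_symmetry()] for symmetric/asymmetric decomposition.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  arr <- as_array3d(configs)
  fit <- gpa_core(arr, tol = tol, max_iter = max_iter)
  structure(
    list(aligned = fit$aligned, mean_shape = fit$consensus,
         centroid_sizes = fit$centroid_sizes, iterations = fit$iterations,
         converged = fit$converged, n_landmarks = dim(arr)[1]),
    class = "gpa_fit"
  )
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("Generalized Procrustes fit: %d specimens, %d landmarks\n",
              nrow(x$aligned), x$n_landmarks))
  cat(sprintf("  converged in %d iterations\n", x$iterations))
  invisible(x)
}

#' Symmetric/asymmetric decomposition of landmark data
#'
#' Splits shape variation into a symmetric component (the shape variable
#' analyzed throughout a bilateral-symmetry study) and an individual
#' asymmetry component.
#'
#' For **object symmetry**, each specimen's configuration is joined with its
#' reflected-and-relabeled copy ([reflect_relabel()]) and all `2N`
#' configurations are superimposed together, with the consensus constrained to
#' be exactly mirror-symmetric. The symmetric component of a specimen is the
#' average of its two aligned copies (projected exactly onto the symmetric
#' subspace) and the asymmetry component is half their difference.
#'
#' For **matching symmetry**, the left-side configurations are reflected and
#' all `2N` sides superimposed jointly; the symmetric component is the
#' per-specimen average of the two aligned sides, the asymmetry half their
#' difference, and the reported centroid size is the mean of the two sides'
#' raw centroid sizes.
#'
#' @param configs For object symmetry, an `L x 3 x N` array of whole
#'   configurations. For matching symmetry, a list with elements `left` and
#'   `right`, each a `k x 3 x N` array (slice `i` of both arrays belongs to
#'   specimen `i`).
#' @param scheme A [symmetry_scheme()].
#' @param specimen_id Optional specimen identifiers; taken from `dimnames`
#'   when omitted.
#' @param tol,max_iter Passed to the superimposition (see [gpa()]).
#' @return An object of class `aligned_sample` with fields
#'   `symmetric` (`N x 3L` matrix of symmetric-component tangent coordinates),
#'   `asymmetry` (`N x 3L` matrix of individual asymmetry components),
#'   `centroid_sizes`, `mean_shape`, `scheme`, `specimen_id`, `iterations`,
#'   `converged`.
#' @export
decompose_symmetry <- function(configs, scheme, specimen_id = NULL,
                               tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(scheme, "symmetry_scheme"))
  if (scheme$mode == "object") {
    arr <- as_array3d(configs)
    L <- dim(arr)[1]
    n <- dim(arr)[3]
    if (L != scheme$n_landmarks) {
      stop("configurations have ", L, " landmarks but the scheme expects ",
           scheme$n_landmarks, call. = FALSE)
    }
    specimen_id <- specimen_id %||% dimnames(arr)[[3]] %||% sprintf("spec_%03d", seq_len(n))
    joint <- array(0, dim = c(L, 3L, 2L * n))
    joint[, , seq_len(n)] <- arr
    joint[, , n + seq_len(n)] <- reflect_relabel(arr, scheme)
    fit <- gpa_core(joint, tol = tol, max_iter = max_iter, symmetrize_with = scheme)
    orig <- fit$aligned[seq_len(n), , drop = FALSE]
    refl <- fit$aligned[n + seq_len(n), , drop = FALSE]
    sym <- (orig + refl) / 2
    asym <- (orig - refl) / 2
    # exact projections onto the +/-1 eigenspaces of the reflection operator
    for (i in seq_len(n)) {
      sym[i, ] <- symmetrize_config(unflatten_config(sym[i, ], L), scheme)
      asym[i, ] <- antisymmetrize_config(unflatten_config(asym[i, ], L), scheme)
    }
    cs <- fit$centroid_sizes[seq_len(n)]
  } else {
    if (!is.list(configs) || is.null(configs$left) || is.null(configs$right)) {
      stop("matching symmetry requires configs = list(left = , right = )", call. = FALSE)
    }
    left <- as_array3d(configs$left)
    right <- as_array3d(configs$right)
    if (!all(dim(left) == dim(right))) {
      stop("left and right arrays must have identical dimensions", call. = FALSE)
    }
    L <- dim(left)[1]
    n <- dim(left)[3]
    if (L != scheme$n_landmarks) {
      stop("configurations have ", L, " landmarks per side but the scheme expects ",
           scheme$n_landmarks, call. = FALSE)
    }
    ids_l <- dimnames(left)[[3]]
    ids_r <- dimnames(right)[[3]]
    if (!is.null(ids_l) && !is.null(ids_r) && !identical(ids_l, ids_r)) {
      missing <- setdiff(union(ids_l, ids_r), intersect(ids_l, ids_r))
      stop("specimens missing one side: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    specimen_id <- specimen_id %||% ids_l %||% sprintf("spec_%03d", seq_len(n))
    joint <- array(0, dim = c(L, 3L, 2L * n))
    joint[, , seq_len(n)] <- right
    for (i in seq_len(n)) joint[, , n + i] <- reflect_axis(left[, , i], scheme$axis)
    fit <- gpa_core(joint, tol = tol, max_iter = max_iter)
    r_al <- fit$aligned[seq_len(n), , drop = FALSE]
    l_al <- fit$aligned[n + seq_len(n), , drop = FALSE]
    sym <- (r_al + l_al) / 2
    asym <- (r_al - l_al) / 2
    cs <- (fit$centroid_sizes[seq_len(n)] + fit$centroid_sizes[n + seq_len(n)]) / 2
  }
  rownames(sym) <- rownames(asym) <- specimen_id
  colnames(sym) <- colnames(asym) <- coord_names(L)
  names(cs) <- specimen_id
  structure(
    list(symmetric = sym, asymmetry = asym, centroid_sizes = cs,
         mean_shape = fit$consensus, scheme = scheme, specimen_id = specimen_id,
         iterations = fit$iterations, converged = fit$converged),
    class = "aligned_sample"
  )
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat(sprintf("Aligned sample (%s symmetry): %d specimens, %d landmarks\n",
              x$scheme$mode, nrow(x$symmetric), x$scheme$n_landmarks))
  cat(sprintf("  symmetric shape-space dimension: %d\n", shape_space_dim(x$scheme)))
  cat(sprintf("  superimposition converged in %d iterations\n", x$iterations))
  invisible(x)
}

#' Fluctuating-asymmetry scores
#'
#' Scores each individual's deviation from the sample's mean asymmetry (the
#' directional-asymmetry estimate), in units of Procrustes distance: the
#' Euclidean norm of `asymmetry_i - mean(asymmetry)`. Purely directional
#' asymmetry therefore scores zero for every specimen.
#'
#' @param sample An [decompose_symmetry()] result (`aligned_sample`).
#' @param groups Optional group labels (length `N`); per-group mean FA is
#'   reported when given.
#' @return A list of class `fa_scores`: `per_specimen` (named non-negative
#'   vector), `group_means` (or `NULL`), `mean_asymmetry` (the directional
#'   asymmetry vector).
#' @export
fa_scores <- function(sample, groups = NULL) {
  if (!inherits(sample, "aligned_sample") || is.null(sample$asymmetry)) {
    stop("fa_scores requires an aligned_sample with an asymmetry decomposition",
         call. = FALSE)
  }
  da <- colMeans(sample$asymmetry)
  dev <- sweep(sample$asymmetry, 2L, da)
  scores <- sqrt(rowSums(dev^2))
  names(scores) <- sample$specimen_id
  group_means <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(scores))
    group_means <- tapply(scores, factor(groups), mean)
  }
  structure(list(per_specimen = scores, group_means = group_means,
                 mean_asymmetry = da),
            class = "fa_scores")
}

#' Procrustes distance between two shapes in a common frame
#'
#' Euclidean norm of the difference between two shape vectors (rows of the
#' same aligned sample, or means thereof). Symmetric and zero only for
#' identical shapes.
#'
#' @param a,b Numeric shape vectors of equal length.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("shape vectors have mismatched lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}
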