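#' Symmetry schemes for landmark configurations
#'
#' A symmetry scheme records how landmarks relate to the midsagittal plane.
#' Two designs are supported, following the standard treatment of bilateral
#' symmetry in geometric morphometrics:
#'
#' * **object symmetry** — a single structure (e.g. a skull) is itself
#'   bilaterally symmetric. Landmarks come as `k` left/right pairs plus `l`
#'   unpaired midline landmarks, all digitized on the same configuration.
#' * **matching symmetry** — separate left and right copies of a structure
#'   (e.g. hemimandibles), with the same `k` landmarks on each side.
#'
#' The scheme determines the dimensionality of the symmetric shape space:
#' `3k + 2l - 4` for object symmetry and `3k - 7` for matching symmetry (see
#' [shape_space_dim()]).
#'
#' @param mode `"object"` or `"matching"`.
#' @param pairs Two-column integer matrix (or list of length-2 vectors) of
#'   (left, right) landmark indices. For matching symmetry this defaults to
#'   the identity mapping: landmark `i` on the left corresponds to landmark
#'   `i` on the right.
#' @param midline Integer vector of midline landmark indices (object symmetry
#'   only; must be empty for matching symmetry).
#' @param n_landmarks Number of landmarks per configuration (per side for
#'   matching symmetry). Inferred from `pairs`/`midline` when omitted.
#' @param axis Coordinate axis (1, 2 or 3) orthogonal to the plane of
#'   symmetry used when reflecting; the default, axis 1, is a pure
#'   convention — superimposition absorbs any rigid motion of the inputs.
#' @return An object of class `symmetry_scheme` with fields `mode`, `pairs`,
#'   `midline`, `axis`, `n_landmarks`, `k` (number of pairs) and `l` (number
#'   of midline landmarks).
#' @examples
#' sc <- symmetry_scheme("object", pairs = cbind(1:3, 4:6), midline = 7:8)
#' shape_space_dim(sc)
#' @export
symmetry_scheme <- function(mode = c("object", "matching"), pairs = NULL,
                            midline = integer(), n_landmarks = NULL, axis = 1L) {
  mode <- match.arg(mode)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (!is.null(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
  }
  midline <- as.integer(midline)
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)

  if (mode == "matching") {
    if (length(midline) > 0L) {
      stop("matching symmetry admits no midline landmarks", call. = FALSE)
    }
    if (is.null(n_landmarks)) {
      n_landmarks <- if (is.null(pairs)) {
        stop("supply n_landmarks (or pairs) for matching symmetry", call. = FALSE)
      } else {
        max(pairs)
      }
    }
    n_landmarks <- as.integer(n_landmarks)
    if (is.null(pairs)) pairs <- cbind(seq_len(n_landmarks), seq_len(n_landmarks))
    if (nrow(pairs) != n_landmarks) {
      stop("matching symmetry requires one pair per landmark (k = L)", call. = FALSE)
    }
  } else {
    if (is.null(pairs)) pairs <- matrix(integer(), 0L, 2L)
    if (nrow(pairs) + length(midline) < 1L) {
      stop("object symmetry requires paired or midline landmarks", call. = FALSE)
    }
    idx <- c(as.vector(pairs), midline)
    if (anyDuplicated(idx)) {
      stop("paired and midline indices must be disjoint", call. = FALSE)
    }
    if (is.null(n_landmarks)) n_landmarks <- max(idx)
    n_landmarks <- as.integer(n_landmarks)
    if (!setequal(idx, seq_len(n_landmarks))) {
      stop("pairs and midline together must cover all ", n_landmarks,
           " landmarks exactly once", call. = FALSE)
    }
  }

  structure(
    list(mode = mode, pairs = pairs, midline = midline, axis = axis,
         n_landmarks = n_landmarks, k = nrow(pairs), l = length(midline)),
    class = "symmetry_scheme"
  )
}

#' @export
print.symmetry_scheme <- function(x, ...) {
  cat("Symmetry scheme:", x$mode, "symmetry\n")
  cat("  landmarks:", x$n_landmarks,
      sprintf("(k = %d pairs, l = %d midline)", x$k, x$l), "\n")
  cat("  reflection axis:", x$axis, "\n")
  cat("  symmetric shape-space dimension:", shape_space_dim(x), "\n")
  invisible(x)
}

#' Dimensionality of the symmetric shape space
#'
#' Counts the free dimensions of the symmetric component of shape after
#' Procrustes superimposition: `3k + 2l - 4` for object symmetry (`k` paired
#' and `l` midline landmarks; midline landmarks are confined to the symmetry
#' plane, and 4 symmetric nuisance dimensions — two in-plane translations, one
#' in-plane rotation and scale — are removed) and `3k - 7` for matching
#' symmetry (`k` landmarks per side; the full 7 similarity dimensions are
#' removed).
#'
#' @param scheme A [symmetry_scheme()].
#' @return Integer dimension.
#' @examples
#' shape_space_dim(symmetry_scheme("object", pairs = cbind(1:17, 18:34),
#'                                 midline = 35:44)) # 67
#' shape_space_dim(symmetry_scheme("matching", n_landmarks = 13)) # 32
#' @export
shape_space_dim <- function(scheme) {
  stopifnot(inherits(scheme, "symmetry_scheme"))
  if (scheme$mode == "object") 3L * scheme$k + 2L * scheme$l - 4L else 3L * scheme$k - 7L
}

#' Reflect a configuration and relabel paired landmarks
#'
#' Negates the coordinate along the scheme's symmetry axis and swaps the
#' labels of each (left, right) landmark pair; midline landmarks keep their
#' labels. This is the reflected-and-relabeled copy used in object-symmetry
#' superimposition, and it is an exact involution: applying it twice returns
#' the input unchanged.
#'
#' @param coords An `L x 3` coordinate matrix or `L x 3 x N` array.
#' @param scheme An object-symmetry [symmetry_scheme()].
#' @return Reflected coordinates with the same shape as the input.
#' @export
reflect_relabel <- function(coords, scheme) {
  stopifnot(inherits(scheme, "symmetry_scheme"))
  if (scheme$mode != "object") {
    stop("reflect_relabel applies to object symmetry; matching designs reflect one side without relabeling",
         call. = FALSE)
  }
  if (length(dim(coords)) == 3L) {
    out <- coords
    for (i in seq_len(dim(coords)[3])) out[, , i] <- reflect_relabel(coords[, , i], scheme)
    return(out)
  }
  if (nrow(coords) < scheme$n_landmarks) {
    stop("configuration has fewer landmarks than the scheme expects", call. = FALSE)
  }
  if (max(scheme$pairs, scheme$midline) > nrow(coords)) {
    stop("scheme indices out of range for this configuration", call. = FALSE)
  }
  refl <- coords
  refl[, scheme$axis] <- -refl[, scheme$axis]
  out <- refl
  out[scheme$pairs[, 1L], ] <- refl[scheme$pairs[, 2L], ]
  out[scheme$pairs[, 2L], ] <- refl[scheme$pairs[, 1L], ]
  out
}

# Plain reflection (no relabeling); used for the mirrored side in matching
# symmetry and for the simulator.
reflect_axis <- function(coords, axis = 1L) {
  coords[, axis] <- -coords[, axis]
  coords
}

# Orthogonal projections of a flattened configuration onto the +1 / -1
# eigenspaces of the reflect-relabel operator (which is symmetric orthogonal,
# so these are exact orthogonal projectors).
symmetrize_config <- function(config, scheme) {
  (config + reflect_relabel(config, scheme)) / 2
}

antisymmetrize_config <- function(config, scheme) {
  (config - reflect_relabel(config, scheme)) / 2
}
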