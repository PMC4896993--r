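# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state so callers never leak randomness. A `NULL`
#' seed evaluates `code` with the current state untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed derivation; keeps values in 32-bit range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 1000003 * offset) %% 2147483587)
}

# Flatten an L x 3 configuration column-major: (x1..xL, y1..yL, z1..zL).
flatten_config <- function(config) as.vector(config)

unflatten_config <- function(v, n_landmarks) {
  matrix(v, nrow = n_landmarks, ncol = 3L)
}

coord_names <- function(n_landmarks) {
  sprintf("%s%02d", rep(c("x", "y", "z"), each = n_landmarks), seq_len(n_landmarks))
}

# Flatten an L x 3 x N array to an N x 3L matrix (one row per specimen).
flatten_configs <- function(arr) {
  stopifnot(length(dim(arr)) == 3L, dim(arr)[2] == 3L)
  L <- dim(arr)[1]
  n <- dim(arr)[3]
  out <- matrix(arr, nrow = L * 3L, ncol = n)
  out <- t(out)
  colnames(out) <- coord_names(L)
  rownames(out) <- dimnames(arr)[[3]]
  out
}

matrix_to_configs <- function(X) {
  stopifnot(is.matrix(X), ncol(X) %% 3L == 0L)
  L <- ncol(X) %/% 3L
  arr <- array(t(X), dim = c(L, 3L, nrow(X)))
  dimnames(arr) <- list(NULL, c("x", "y", "z"), rownames(X))
  arr
}

check_config <- function(coords, what = "configuration") {
  if (!is.matrix(coords) || ncol(coords) != 3L) {
    stop(what, " must be an L x 3 coordinate matrix", call. = FALSE)
  }
  if (nrow(coords) < 3L) stop(what, " needs at least 3 landmarks", call. = FALSE)
  if (!all(is.finite(coords))) stop(what, " contains non-finite coordinates", call. = FALSE)
  invisible(coords)
}

# Reject configurations that cannot anchor a 3D superimposition: all landmarks
# coincident, or all landmarks on one line (rotation about that line is
# undetermined).
check_nondegenerate <- function(coords, what = "configuration") {
  check_config(coords, what)
  centered <- sweep(coords, 2L, colMeans(coords))
  s <- svd(centered, nu = 0L, nv = 0L)$d
  if (s[1] <= 0 || !is.finite(s[1])) {
    stop("degenerate ", what, ": all landmarks coincide", call. = FALSE)
  }
  if (s[2] < 1e-10 * s[1]) {
    stop("degenerate ", what, ": landmarks are collinear", call. = FALSE)
  }
  invisible(coords)
}

as_array3d <- function(x) {
  if (is.list(x) && !is.null(x$coords)) x <- x$coords
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L, dim(x)[2] == 3L)
  x
}
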