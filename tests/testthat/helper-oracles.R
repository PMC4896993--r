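# Independent oracle implementations used to validate the package's own
# algorithms. These deliberately take different computational routes from the
# implementations they check.

# Absolute orientation by Horn's quaternion method: the proper rotation R
# (3 x 3) such that X %*% t(R) best matches M in least squares. Independent
# of the SVD route used inside the package.
horn_rotation <- function(X, M) {
  S <- crossprod(X, M)
  N <- rbind(
    c(S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1]),
    c(S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3]),
    c(S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2]),
    c(S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3])
  )
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  q0 <- q[1]; qx <- q[2]; qy <- q[3]; qz <- q[4]
  rbind(
    c(q0^2 + qx^2 - qy^2 - qz^2, 2 * (qx * qy - q0 * qz), 2 * (qx * qz + q0 * qy)),
    c(2 * (qy * qx + q0 * qz), q0^2 - qx^2 + qy^2 - qz^2, 2 * (qy * qz - q0 * qx)),
    c(2 * (qz * qx - q0 * qy), 2 * (qz * qy + q0 * qx), q0^2 - qx^2 - qy^2 + qz^2)
  )
}

# Brute-force alternating-optimization superimposition: rotate every
# configuration onto the consensus with Horn's quaternion solver, re-estimate
# the consensus, repeat until the consensus freezes, then apply the same
# unit-size / tangent-projection conventions as the implementation.
oracle_gpa <- function(arr, tol = 1e-28, max_iter = 20000L) {
  L <- dim(arr)[1]; n <- dim(arr)[3]
  X <- arr
  for (i in seq_len(n)) {
    c0 <- sweep(arr[, , i], 2L, colMeans(arr[, , i]))
    X[, , i] <- c0 / sqrt(sum(c0^2))
  }
  cons <- X[, , 1L]
  for (it in seq_len(max_iter)) {
    al <- X
    for (i in seq_len(n)) al[, , i] <- X[, , i] %*% t(horn_rotation(X[, , i], cons))
    newc <- apply(al, c(1L, 2L), mean)
    newc <- sweep(newc, 2L, colMeans(newc))
    newc <- newc / sqrt(sum(newc^2))
    moved <- sum((newc - cons)^2)
    cons <- newc
    if (moved < tol) break
  }
  al <- X
  for (i in seq_len(n)) al[, , i] <- X[, , i] %*% t(horn_rotation(X[, , i], cons))
  flat <- t(matrix(al, nrow = L * 3L))
  cf <- as.vector(cons)
  flat <- flat - outer(drop(flat %*% cf) - 1, cf)
  list(aligned = flat, consensus = cf)
}

# Rotate an oracle solution onto the implementation's consensus frame (using
# the oracle's own rotation solver) so coordinates can be compared directly.
align_oracle_to <- function(ora, consensus_flat) {
  L <- length(consensus_flat) / 3L
  Rg <- horn_rotation(matrix(ora$consensus, L, 3L), matrix(consensus_flat, L, 3L))
  t(apply(ora$aligned, 1L, function(v) as.vector(matrix(v, L, 3L) %*% t(Rg))))
}

# Literal step-down definition of the Holm adjustment.
brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- cummax(pmin((m - seq_len(m) + 1) * p[o], 1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Hotelling T^2 computed directly from its definition (fresh code path).
t2_direct <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  d <- colMeans(X1) - colMeans(X2)
  S <- (crossprod(scale(X1, scale = FALSE)) + crossprod(scale(X2, scale = FALSE))) /
    (n1 + n2 - 2)
  (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(S) %*% d)
}

# Permutation null for the two-sample mean comparison.
perm_hotelling_p <- function(X1, X2, n_perm) {
  obs <- t2_direct(X1, X2)
  pooled <- rbind(X1, X2)
  n1 <- nrow(X1)
  n <- nrow(pooled)
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    t2b <- t2_direct(pooled[idx[seq_len(n1)], , drop = FALSE],
                     pooled[idx[-seq_len(n1)], , drop = FALSE])
    if (t2b >= obs) count <- count + 1L
  }
  (count + 1) / (n_perm + 1)
}

# Monte-Carlo estimate of P(angle <= theta) for independent uniformly random
# directions in `dim` dimensions.
mc_angle_cdf <- function(theta_deg, dim, n_draws) {
  A <- matrix(rnorm(n_draws * dim), n_draws, dim)
  B <- matrix(rnorm(n_draws * dim), n_draws, dim)
  cs <- rowSums(A * B) / sqrt(rowSums(A^2) * rowSums(B^2))
  ang <- acos(pmin(pmax(cs, -1), 1)) * 180 / pi
  vapply(theta_deg, function(th) mean(ang <= th), numeric(1))
}

# Centroid size through the pairwise-distance identity
# sum_i ||x_i - xbar||^2 = (1/L) sum_{i<j} ||x_i - x_j||^2.
cs_pairwise_oracle <- function(coords) {
  L <- nrow(coords)
  ss <- 0
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    ss <- ss + sum((coords[i, ] - coords[j, ])^2)
  }
  sqrt(ss / L)
}
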