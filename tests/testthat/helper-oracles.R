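# Independent oracles and shared fixtures.  Everything here deliberately
# avoids the package's own code paths for the quantity it checks.

# random proper rotation (QR of a Gaussian matrix, det fixed to +1)
rand_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Horn's closed-form quaternion solution for the proper rotation minimizing
# ||A R - B||^2 (A, B centered) -- an algorithm independent of the SVD-based
# Kabsch solution used by opa_fit().
horn_rotation <- function(A, B) {
  M <- crossprod(A, B)
  N <- rbind(
    c(M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2], M[3, 1] - M[1, 3], M[1, 2] - M[2, 1]),
    c(M[2, 3] - M[3, 2], M[1, 1] - M[2, 2] - M[3, 3], M[1, 2] + M[2, 1], M[3, 1] + M[1, 3]),
    c(M[3, 1] - M[1, 3], M[1, 2] + M[2, 1], -M[1, 1] + M[2, 2] - M[3, 3], M[2, 3] + M[3, 2]),
    c(M[1, 2] - M[2, 1], M[3, 1] + M[1, 3], M[2, 3] + M[3, 2], -M[1, 1] - M[2, 2] + M[3, 3]))
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
             c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
             c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
  t(R)   # so that A %*% horn_rotation(A, B) approximates B
}

# brute-force GPA built on the Horn solver: align-to-consensus iteration
# written from scratch.  Returns the converged total residual.
brute_gpa_residual <- function(arr, scale = TRUE, iters = 200) {
  n <- dim(arr)[1]
  X <- array(0, dim(arr))
  for (i in seq_len(n)) {
    m <- sweep(arr[i, , ], 2, colMeans(arr[i, , ]))
    if (scale) m <- m / sqrt(sum(m^2))
    X[i, , ] <- m
  }
  cons <- X[1, , ]
  res <- Inf
  for (it in seq_len(iters)) {
    for (i in seq_len(n)) X[i, , ] <- X[i, , ] %*% horn_rotation(X[i, , ], cons)
    cons <- apply(X, c(2, 3), mean)
    if (scale) cons <- cons / sqrt(sum(cons^2))
    new_res <- sum(vapply(seq_len(n), function(i) sum((X[i, , ] - cons)^2), 0))
    if (is.finite(res) && abs(res - new_res) < 1e-14) break
    res <- new_res
  }
  res
}

# Gaussian radial-basis interpolant: an imputation oracle independent of the
# thin-plate spline kernel.
rbf_impute <- function(src_obs, dst_obs, src_missing, bw = NULL) {
  D <- as.matrix(dist(src_obs))
  if (is.null(bw)) bw <- stats::median(D[D > 0])
  K <- exp(-(D / bw)^2)
  W <- solve(K + diag(1e-10, nrow(K)), dst_obs - src_obs)
  d_new <- sqrt(outer(rowSums(src_missing^2), rowSums(src_obs^2), "+") -
                  2 * src_missing %*% t(src_obs))
  src_missing + exp(-(pmax(d_new, 0) / bw)^2) %*% W
}

# small complete synthetic dataset used across suites
small_dataset <- function(n = 8, seed = 11, n_pairs = 4, n_midline = 3,
                          digitizing_sd = 0.01, ...) {
  tpl <- make_template(n_pairs, n_midline, seed = 5)
  cfg <- synthetic_shape_config(tpl,
    n_per_group = c(g1890s_F = ceiling(n / 4), g1890s_M = floor(n / 4),
                    g2010s_F = ceiling(n / 4), g2010s_M = floor(n / 4)),
    digitizing_sd = digitizing_sd, seed = seed, ...)
  simulate_shapes(cfg)
}

expect_all_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
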