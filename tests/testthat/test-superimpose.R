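# Procrustes machinery: centroid size, OPA, GPA, object symmetry, TPS
# imputation, view merging.

test_that("centroid size: closed form, translation invariance, homogeneity", {
  sq <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 0)
  expect_equal(centroid_size(sq), sqrt(8))
  expect_equal(centroid_size(sweep(sq, 2, c(5, 5, 5), "+")), sqrt(8))
  expect_equal(centroid_size(2 * sq), 2 * sqrt(8))
  expect_error(centroid_size(matrix(NA_real_, 4, 3)), "2 observed")
})

test_that("opa_fit recovers exact rigid transforms and handles reflection", {
  set.seed(21)
  A <- matrix(rnorm(18), 6, 3)
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))  # 90 degrees about z
  B <- A %*% Rz + matrix(rep(c(3, -2, 7), each = 6), 6)
  fit <- opa_fit(A, B)
  expect_lt(fit$residual, 1e-18)
  expect_all_equal(fit$fitted, B, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  mirror <- A %*% diag(c(-1, 1, 1))
  expect_gt(opa_fit(A, mirror, allow_reflection = FALSE)$residual, 1e-4)
  expect_lt(opa_fit(A, mirror, allow_reflection = TRUE)$residual, 1e-18)

  expect_error(opa_fit(cbind(1:5, 0, 0), matrix(rnorm(15), 5)), "degenerate")
})

test_that("opa_fit residual is the minimum over random rotations (Monte Carlo)", {
  set.seed(22)
  A <- matrix(rnorm(18), 6, 3)
  B <- matrix(rnorm(18), 6, 3)
  fit <- opa_fit(A, B)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  mc <- min(vapply(1:10000, function(i) sum((Ac %*% rand_rotation() - Bc)^2), 0))
  expect_lte(fit$residual, mc + 1e-12)
  # and against the independent closed-form quaternion solution
  horn <- sum((Ac %*% horn_rotation(Ac, Bc) - Bc)^2)
  expect_equal(fit$residual, horn, tolerance = 1e-10)
})

test_that("gpa_align: duplicate configurations collapse onto one shape", {
  set.seed(23)
  base <- matrix(rnorm(15), 5, 3)
  arr <- array(0, c(3, 5, 3))
  for (i in 1:3)
    arr[i, , ] <- base %*% rand_rotation() +
      matrix(rep(rnorm(3, sd = 4), each = 5), 5)
  al <- gpa_align(arr, scale = TRUE)
  for (i in 2:3) expect_all_equal(al$shapes[1, , ], al$shapes[i, , ], 1e-8)
  expect_all_equal(al$consensus, al$shapes[1, , ], 1e-8)
})

test_that("gpa_align contracts: unit size, centered, mean consensus, monotone log", {
  ds <- small_dataset(n = 8, seed = 41)
  al <- gpa_align(ds, scale = TRUE)
  n <- dim(al$shapes)[1]
  for (i in seq_len(n)) {
    expect_lt(abs(sqrt(sum(sweep(al$shapes[i, , ], 2,
                                 colMeans(al$shapes[i, , ]))^2)) - 1), 1e-9)
    expect_all_equal(colMeans(al$shapes[i, , ]), c(0, 0, 0), 1e-9)
  }
  expect_all_equal(al$consensus, apply(al$shapes, c(2, 3), mean), 1e-12)
  expect_true(all(diff(al$iterations) <= 1e-12))
  expect_equal(al$centroid_sizes, apply(ds$coords, 1, centroid_size))
})

test_that("rigid invariance: random rotations/translations leave GPA output alone", {
  ds <- small_dataset(n = 6, seed = 42)
  al0 <- gpa_align(ds, scale = TRUE)
  set.seed(7)
  ds2 <- ds
  for (i in seq_len(dim(ds$coords)[1]))
    ds2$coords[i, , ] <- ds$coords[i, , ] %*% rand_rotation() +
      matrix(rep(rnorm(3, sd = 10), each = dim(ds$coords)[2]),
             dim(ds$coords)[2])
  al1 <- gpa_align(ds2, scale = TRUE)
  expect_equal(al1$centroid_sizes, al0$centroid_sizes, tolerance = 1e-12)
  # shapes agree up to the global orientation of the consensus
  fit <- opa_fit(al1$consensus, al0$consensus)
  for (i in seq_len(dim(ds$coords)[1]))
    expect_all_equal(al1$shapes[i, , ] %*% fit$rotation, al0$shapes[i, , ], 1e-8)
})

test_that("gpa_align agrees with the independent brute-force oracle", {
  set.seed(24)
  for (case in 1:4) {
    n <- sample(3:5, 1); p <- sample(4:6, 1)
    arr <- array(rnorm(n * p * 3), c(n, p, 3))
    al <- gpa_align(arr, scale = TRUE)
    expect_equal(utils::tail(al$iterations, 1),
                 brute_gpa_residual(arr, scale = TRUE),
                 tolerance = 1e-8)
  }
})

test_that("reflect_relabel is an involution that fixes midline rows", {
  tpl <- make_template(4, 3, seed = 6)
  set.seed(8)
  cfg <- matrix(rnorm(11 * 3), 11, 3)
  out <- reflect_relabel(cfg, tpl)
  expect_all_equal(reflect_relabel(out, tpl), cfg, 1e-14)
  mid <- match(tpl$midline, tpl$landmark_names)
  expect_equal(out[mid, 2:3], cfg[mid, 2:3])   # y,z of midline unchanged
  expect_equal(out[mid, 1], -cfg[mid, 1])
  # a symmetric configuration maps to itself up to a rigid motion
  base <- attr(tpl, "base_shape")
  expect_lt(opa_fit(reflect_relabel(base, tpl), base)$residual, 1e-16)
})

test_that("symmetric decomposition: identity, zero asymmetry, variance split", {
  # perfectly symmetric specimens -> asymmetric component ~ 0
  tpl <- make_template(4, 3, seed = 6)
  base <- attr(tpl, "base_shape")
  set.seed(9)
  n <- 5
  arr <- array(0, c(n, 11, 3))
  for (i in seq_len(n)) {
    sym_noise <- matrix(rnorm(11 * 3, 0, 0.01), 11, 3)
    sym_noise <- (sym_noise + reflect_relabel(sym_noise, tpl)) / 2
    arr[i, , ] <- (base + sym_noise) %*% rand_rotation()
  }
  ds <- shape_dataset(tpl, arr, data.frame(specimen_id = sprintf("s%d", 1:n),
                                           replicate = 0L))
  dec <- symmetric_decomposition(ds)
  expect_lt(sqrt(sum(dec$asymmetric$shapes^2)), 1e-8)

  # general data: symmetric + asymmetric reconstructs aligned originals,
  # and variances add up
  ds2 <- small_dataset(n = 6, seed = 43, digitizing_sd = 0.02)
  dec2 <- symmetric_decomposition(ds2)
  whole <- gpa_align(array_from <- {
    n2 <- dim(ds2$coords)[1]
    doubled <- array(0, c(2 * n2, dim(ds2$coords)[2], 3))
    doubled[seq_len(n2), , ] <- ds2$coords
    for (i in seq_len(n2))
      doubled[n2 + i, , ] <- reflect_relabel(ds2$coords[i, , ], ds2$template)
    doubled
  }, scale = TRUE)
  n2 <- dim(ds2$coords)[1]
  for (i in seq_len(n2))
    expect_all_equal(dec2$symmetric$shapes[i, , ] + dec2$asymmetric$shapes[i, , ],
                     whole$shapes[i, , ], 1e-10)
  # on the doubled set {original, reflected} the cross term cancels exactly:
  # originals are sym + asym, reflected copies sym - asym, so total variance
  # = duplicated symmetric variance + mirrored asymmetric variance
  abind2 <- function(a, neg = FALSE) {
    n <- dim(a)[1]
    out <- array(0, c(2 * n, dim(a)[2], dim(a)[3]))
    out[seq_len(n), , ] <- a
    out[n + seq_len(n), , ] <- if (neg) -a else a
    out
  }
  v <- function(a) { Y <- flatten_shapes(a); sum(sweep(Y, 2, colMeans(Y))^2) }
  sym_dev <- dec2$symmetric$shapes; asy <- dec2$asymmetric$shapes
  expect_equal(v(whole$shapes),
               v(abind2(sym_dev)) + v(abind2(asy, neg = TRUE)),
               tolerance = 1e-8)
})

test_that("relabeling left/right in the template leaves the symmetric part stable", {
  ds <- small_dataset(n = 4, seed = 44, digitizing_sd = 0.02)
  dec <- symmetric_decomposition(ds)
  tpl2 <- ds$template
  tpl2$paired <- tpl2$paired[, c(2, 1)]
  colnames(tpl2$paired) <- c("left", "right")
  ds2 <- ds; ds2$template <- tpl2
  dec2 <- symmetric_decomposition(ds2)
  # symmetric components identical up to a rigid motion (incl. reflection)
  for (i in seq_len(dim(ds$coords)[1])) {
    fit <- opa_fit(dec2$symmetric$shapes[i, , ], dec$symmetric$shapes[i, , ],
                   allow_reflection = TRUE)
    expect_lt(fit$residual, 1e-10)
  }
})

test_that("TPS imputation is exact on identity and affine maps", {
  tpl <- make_template(19, 5, seed = 43)
  ref <- attr(tpl, "base_shape")
  p <- nrow(ref)
  # identity: masked landmark recovered exactly
  res <- estimate_missing_tps(ref, seq_len(p) == 7, ref)
  expect_all_equal(res$coords, ref, 1e-9)
  # affine map, every maskable landmark (property)
  A <- matrix(c(1.2, 0.1, -0.05, 0.02, 0.9, 0.03, -0.04, 0.08, 1.1), 3)
  b <- c(2, -1, 0.5)
  warped <- ref %*% A + matrix(rep(b, each = p), p)
  for (j in seq(1, p, by = 3)) {
    got <- estimate_missing_tps(warped, seq_len(p) == j, ref)
    expect_all_equal(got$coords, warped, 1e-8)
  }
})

test_that("TPS recovery on a smooth nonlinear warp beats the 5% bound and an RBF oracle agrees", {
  tpl <- make_template(19, 5, seed = 43)
  ref <- attr(tpl, "base_shape") * 50   # mm scale
  p <- nrow(ref)
  warp <- function(x) x + cbind(0.8 * sin(x[, 2] / 30), 0.8 * cos(x[, 1] / 30),
                                0.5 * sin(x[, 3] / 25))
  target <- warp(ref)
  mean_ild <- mean(dist(target))
  set.seed(10)
  for (j in sample(p, 8)) {
    miss <- seq_len(p) == j
    got <- estimate_missing_tps(target, miss, ref)
    err_tps <- sqrt(sum((got$coords[j, ] - target[j, ])^2))
    oracle <- rbf_impute(ref[!miss, ], target[!miss, ], ref[j, , drop = FALSE])
    err_rbf <- sqrt(sum((oracle - target[j, , drop = FALSE])^2))
    expect_lt(err_tps, 0.05 * mean_ild)
    expect_lt(abs(err_tps - err_rbf), 0.05 * mean_ild)
  }
})

test_that("impute_missing completes a dataset and flags imputed landmarks", {
  ds <- small_dataset(n = 6, seed = 45)
  ds$missing[3, 2] <- TRUE; ds$coords[3, 2, ] <- NA
  out <- impute_missing(ds)
  expect_false(any(out$missing))
  expect_true(attr(out, "imputed")[3, 2])
  expect_equal(out$coords[-3, , ], ds$coords[-3, , ])
  expect_error(impute_missing({
    d <- ds; d$missing[, 1] <- TRUE; d
  }), "complete specimens")
})

test_that("merge_views reassembles an exactly rigid ventral view", {
  tpl <- cranium_template()
  truth <- attr(tpl, "base_shape") * 40
  p <- nrow(truth)
  d_idx <- view_indices(tpl, "dorsal"); v_idx <- view_indices(tpl, "ventral")
  expect_equal(length(union(d_idx, v_idx)), 18L + 30L - 5L)
  set.seed(12)
  Rv <- rand_rotation(); tv <- rnorm(3, sd = 20)
  dorsal <- matrix(NA_real_, p, 3); ventral <- matrix(NA_real_, p, 3)
  dorsal[d_idx, ] <- truth[d_idx, ]
  ventral[v_idx, ] <- truth[v_idx, ] %*% Rv + matrix(rep(tv, each = length(v_idx)),
                                                     length(v_idx))
  merged <- merge_views(dorsal, ventral, tpl)
  expect_all_equal(merged[union(d_idx, v_idx), ], truth[union(d_idx, v_idx), ], 1e-9)

  # identical common landmarks -> identity transform
  ventral2 <- matrix(NA_real_, p, 3)
  ventral2[v_idx, ] <- truth[v_idx, ]
  merged2 <- merge_views(dorsal, ventral2, tpl)
  com <- which(tpl$views == "common")
  expect_all_equal(merged2[com, ], truth[com, ], 1e-9)

  # too few common landmarks
  ventral3 <- ventral
  ventral3[which(tpl$views == "common")[1:3], ] <- NA
  expect_error(merge_views(dorsal, ventral3, tpl), ">= 3 common")
})
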