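# RRPP linear models, model comparison, slope homogeneity, measurement
# error, PCA.

test_that("univariate balanced one-way design reproduces the classical ANOVA F", {
  set.seed(51)
  for (case in 1:3) {
    g <- factor(rep(c("A", "B"), each = 5))
    y <- rnorm(10) + 0.8 * (g == "B")
    res <- rrpp_lm(cbind(y), model_spec("g", n_perm = 199, seed = case),
                   data.frame(g = g))
    # textbook closed form
    gm <- tapply(y, g, mean)
    ssb <- sum(5 * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    f_classical <- (ssb / 1) / (ssw / 8)
    tab <- res$table
    expect_equal(tab$F[1], f_classical, tolerance = 1e-12)
    expect_equal(tab$SS[1], ssb, tolerance = 1e-12)
    expect_equal(tab$df, c(1, 8, 9))
  }
})

test_that("sequential SS matches stats::lm/anova on a multi-term design", {
  set.seed(52)
  n <- 30
  dat <- data.frame(x = rnorm(n), g = factor(sample(c("A", "B"), n, TRUE)),
                    s = factor(sample(c("F", "M"), n, TRUE)))
  y <- 1 + 0.5 * dat$x + (dat$g == "B") + rnorm(n)
  res <- rrpp_lm(cbind(y), model_spec(c("x", "g", "s", "x:g"), n_perm = 49,
                                      seed = 1), dat)
  oracle <- anova(lm(y ~ x + g + s + x:g, dat))
  expect_equal(res$table$SS[1:4], oracle$`Sum Sq`[1:4], tolerance = 1e-10)
  expect_equal(res$table$F[1:4], oracle$`F value`[1:4], tolerance = 1e-10)
  expect_equal(res$table$df[1:4], oracle$Df[1:4])
})

test_that("anova table invariants hold on multivariate shape data", {
  ds <- small_dataset(n = 16, seed = 53, digitizing_sd = 0.02)
  al <- gpa_align(ds)
  Y <- flatten_shapes(al$shapes)
  dat <- data.frame(log_size = log(al$centroid_sizes),
                    period = factor(al$meta$period),
                    sex = factor(al$meta$sex))
  spec <- model_spec(c("log_size", "period", "sex", "period:sex"),
                     n_perm = 99, seed = 3)
  res <- rrpp_lm(Y, spec, dat)
  tab <- res$table
  k <- nrow(tab) - 2
  expect_equal(sum(tab$SS[1:(k + 1)]), tab$SS[k + 2], tolerance = 1e-8)
  expect_equal(sum(tab$Rsq[1:(k + 1)]), 1, tolerance = 1e-8)
  expect_equal(sum(tab$df[1:(k + 1)]), tab$df[k + 2])
  expect_true(all(tab$p[1:k] >= 1 / spec$n_perm & tab$p[1:k] <= 1))
  # reproducible under the seed
  res2 <- rrpp_lm(Y, spec, dat)
  expect_identical(res$table, res2$table)
})

test_that("the seven-term cranium-style model has the study's df structure", {
  # n = 49 specimens, 7 sequential single-df terms -> residuals 41, total 48
  set.seed(54)
  n <- 49
  dat <- data.frame(log_size = rnorm(n),
                    period = factor(rep(c("1890s", "2010s"), length.out = n)),
                    sex = factor(rep(c("F", "F", "M"), length.out = n)))
  Y <- matrix(rnorm(n * 12), n)
  res <- rrpp_lm(Y, model_spec(c("log_size", "period", "sex",
                                 "log_size:period", "log_size:sex",
                                 "period:sex", "log_size:period:sex"),
                               n_perm = 19, seed = 1), dat)
  expect_equal(res$table$df, c(rep(1, 7), 41, 48))
})

test_that("aliased terms raise a structured error", {
  dat <- data.frame(g = factor(c("A", "A", "B", "B")),
                    h = factor(c("A", "A", "B", "B")))
  expect_error(rrpp_lm(cbind(rnorm(4)),
                       model_spec(c("g", "h"), n_perm = 9), dat),
               "aliased.*'h'|'h'.*aliased")
})

test_that("model_compare: degenerate and nesting identities, period power", {
  ds <- small_dataset(n = 16, seed = 55, digitizing_sd = 0.02)
  al <- gpa_align(ds)
  Y <- flatten_shapes(al$shapes)
  dat <- data.frame(log_size = log(al$centroid_sizes),
                    period = factor(al$meta$period))
  full <- model_spec(c("log_size", "period"), n_perm = 199, seed = 9)
  red <- model_spec("log_size", n_perm = 199, seed = 9)
  # reduced == full
  same <- model_compare(Y, full, full, dat)
  expect_equal(same$SS_diff, 0, tolerance = 1e-10)
  expect_gt(same$p, 0.95)
  # full = reduced + one term: SS_diff equals that term's sequential SS
  cmp <- model_compare(Y, full, red, dat)
  seq_tab <- rrpp_lm(Y, full, dat)$table
  expect_equal(cmp$SS_diff, seq_tab$SS[seq_tab$term == "period"],
               tolerance = 1e-10)
  expect_error(model_compare(Y, red, full, dat), "not nested")

  # synthetic period effect of ~2x residual sd is detected at n = 40
  tpl <- make_template(4, 3, seed = 5)
  p <- length(tpl$landmark_names)
  eff <- matrix(rnorm(p * 3, 0, 2 * 0.01 / sqrt(3)), p, 3)
  cfg <- synthetic_shape_config(tpl,
    n_per_group = c(g1890s_F = 10, g1890s_M = 10, g2010s_F = 10, g2010s_M = 10),
    period_effect = eff, individual_sd = 0.01, digitizing_sd = 0,
    size_range = c(45, 50), seed = 56)
  ds2 <- simulate_shapes(cfg)
  al2 <- gpa_align(ds2)
  Y2 <- flatten_shapes(al2$shapes)
  dat2 <- data.frame(log_size = log(al2$centroid_sizes),
                     period = factor(al2$meta$period))
  cmp2 <- model_compare(Y2, model_spec(c("log_size", "period"),
                                       n_perm = 199, seed = 2),
                        model_spec("log_size", n_perm = 199, seed = 2), dat2)
  expect_lte(cmp2$p, 0.01)
})

test_that("slope_homogeneity: antiparallel slopes give 180 degrees, self gives 0", {
  set.seed(57)
  n <- 24; q <- 6
  x <- runif(n, 1, 2)
  b <- rnorm(q)
  g <- rep(c("u", "v"), each = n / 2)
  Y <- outer(x, b) * ifelse(g == "u", 1, -1) + matrix(rnorm(n * q, 0, 1e-4), n)
  out <- slope_homogeneity(Y, x, g, n_perm = 49, seed = 1)
  expect_equal(out$angle_deg, 180, tolerance = 0.5)
  # identical group labels duplicated -> compare a group against itself
  Y2 <- rbind(Y[g == "u", ], Y[g == "u", ])
  g2 <- rep(c("a", "b"), each = n / 2)
  out2 <- slope_homogeneity(Y2, c(x[g == "u"], x[g == "u"]), g2,
                            n_perm = 49, seed = 1)
  expect_equal(out2$length_diff, 0, tolerance = 1e-12)
  expect_equal(out2$angle_deg, 0, tolerance = 1e-6)
  expect_error(slope_homogeneity(Y, rep(1, n), g, n_perm = 9), "zero size variance")
})

test_that("slope_homogeneity is calibrated when slopes are truly common", {
  set.seed(58)
  hits <- 0; runs <- 20
  for (r in seq_len(runs)) {
    n <- 30; q <- 4
    x <- runif(n, 1, 3)
    b <- rnorm(q)
    g <- rep(c("u", "v"), each = n / 2)
    Y <- outer(x, b) + matrix(rnorm(n * q, 0, 0.5), n)
    out <- slope_homogeneity(Y, x, g, n_perm = 99, seed = r)
    if (out$p_angle > 0.05) hits <- hits + 1
  }
  expect_gte(hits, runs * 0.8)   # >= 90% expected; slack for 20 runs
})

test_that("measurement error: identical replicates 0%, pure noise ~100%, 10:1 sd < 5%", {
  tpl <- make_template(3, 3, seed = 5)
  p <- length(tpl$landmark_names)
  mk <- function(confs, ids, reps) {
    arr <- array(0, c(length(confs), p, 3))
    for (i in seq_along(confs)) arr[i, , ] <- confs[[i]]
    gpa_align(shape_dataset(tpl, arr,
                            data.frame(specimen_id = ids, replicate = reps)))
  }
  set.seed(59)
  a <- attr(tpl, "base_shape") * 50
  b <- a + matrix(rnorm(p * 3, 0, 2), p, 3)
  # bit-identical replicates
  al <- mk(list(a, a, b, b), c("s1", "s1", "s2", "s2"), c(0, 1, 0, 1))
  expect_lt(measurement_error_pct(al)$error_pct, 1e-6)
  # identical specimen means, pure replicate noise
  noise <- function() matrix(rnorm(p * 3, 0, 0.5), p, 3)
  al2 <- mk(list(a + noise(), a + noise(), a + noise(), a + noise()),
            c("s1", "s1", "s2", "s2"), c(0, 1, 0, 1))
  expect_gt(measurement_error_pct(al2)$error_pct, 60)
  # between-specimen sd 10x replicate sd, 2 specimens x 10 replicates
  spec_means <- list(a, a + matrix(rnorm(p * 3, 0, 1), p, 3))
  confs <- list(); ids <- character(); reps <- integer()
  for (s in 1:2) for (r in 1:10) {
    confs[[length(confs) + 1]] <- spec_means[[s]] +
      matrix(rnorm(p * 3, 0, 0.1), p, 3)
    ids <- c(ids, sprintf("s%d", s)); reps <- c(reps, r - 1L)
  }
  expect_lt(measurement_error_pct(mk(confs, ids, reps))$error_pct, 5)
  expect_error(measurement_error_pct(mk(list(a, b), c("s1", "s2"), c(0, 0))),
               "replicated")
})

test_that("shape PCA: trace identity, orthogonal scores, distance preservation", {
  ds <- small_dataset(n = 10, seed = 60, digitizing_sd = 0.02)
  al <- gpa_align(ds)
  pca <- shape_pca(al)
  Y <- flatten_shapes(al$shapes)
  Yc <- sweep(Y, 2, colMeans(Y))
  expect_equal(sum(pca$eigenvalues), sum(Yc^2) / (nrow(Y) - 1),
               tolerance = 1e-8)
  expect_equal(sum(pca$pct_variance), 1, tolerance = 1e-12)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  G <- crossprod(pca$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # scores reproduce pairwise shape distances
  expect_all_equal(as.matrix(dist(pca$scores)), as.matrix(dist(Y)), 1e-6)
})

test_that("PCA recovers a planted direction and ignores duplication", {
  set.seed(61)
  p <- 9
  dir <- rnorm(3 * p); dir <- dir / sqrt(sum(dir^2))
  n <- 40
  Y <- outer(rnorm(n, 0, 0.1), dir) + matrix(rnorm(n * 3 * p, 0, 1e-3), n)
  arr <- array(0, c(n, p, 3))
  for (i in seq_len(n)) arr[i, , ] <- unflatten_shape(Y[i, ], p)
  pca <- shape_pca(arr)
  expect_gt(abs(sum(pca$vectors[, 1] * dir)), 0.99)
  arr2 <- array(0, c(2 * n, p, 3))
  arr2[seq_len(n), , ] <- arr; arr2[n + seq_len(n), , ] <- arr
  pca2 <- shape_pca(arr2)
  k <- min(length(pca$pct_variance), length(pca2$pct_variance), 5)
  expect_all_equal(pca2$pct_variance[1:k], pca$pct_variance[1:k], 1e-8)
})
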