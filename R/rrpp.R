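# RRPP linear models on shape.
#
# Sums of squares are sequential (type I): SS of term k is the reduction in
# the residual sum of squared Procrustes distances when term k is added to
# the model containing terms 1..k-1.  Goodall's F divides each term's mean
# square by the full-model residual mean square, pooling over all response
# columns.  Significance comes from the randomized residual permutation
# procedure: for term k the residuals of the reduced model (terms 1..k-1)
# are row-permuted and added back to the reduced fitted values, and the full
# statistic recomputed; the observed arrangement counts as one permutation,
# so p >= 1/n_perm.  One shared permutation per iteration serves all terms.
#
# Factor coding: treatment contrasts with alphabetical level order ("1890s"
# before "2010s", "F" before "M").  This affects term-wise sequential SS
# only under non-orthogonal (unbalanced) designs.

#' Specify an RRPP linear model
#'
#' @param terms character vector of effects in fitting order, e.g.
#'   `c("log_size", "period", "sex", "log_size:period")`.  Interactions use
#'   `:` and must come after their main effects.  Order matters: SS are
#'   sequential.
#' @param n_perm total permutations including the observed arrangement.
#' @param seed integer master seed (`NULL` = use the current RNG state).
#' @return a `model_spec` object.
#' @export
model_spec <- function(terms, n_perm = 1000, seed = NULL) {
  stopifnot(length(terms) >= 1, n_perm >= 1)
  structure(list(terms = as.character(terms), ss_type = "sequential",
                 n_perm = as.integer(n_perm), seed = seed),
            class = "model_spec")
}

# orthonormal column bases Q_0..Q_K of the nested design matrices; df per term
nested_bases <- function(terms, data, n) {
  old <- options(contrasts = c("contr.treatment", "contr.poly"))
  on.exit(options(old))
  data <- as.data.frame(data)
  for (cl in names(data))
    if (is.character(data[[cl]])) data[[cl]] <- factor(data[[cl]])
  Qs <- vector("list", length(terms) + 1)
  X <- matrix(1, n, 1)
  qr0 <- qr(X)
  Qs[[1]] <- qr.Q(qr0)[, seq_len(qr0$rank), drop = FALSE]
  rank_prev <- qr0$rank
  df <- integer(length(terms))
  for (k in seq_along(terms)) {
    f <- stats::reformulate(terms[seq_len(k)])
    X <- stats::model.matrix(f, data)
    qk <- qr(X)
    if (qk$rank <= rank_prev)
      stop("term '", terms[k], "' is aliased (adds no rank to the design)")
    df[k] <- qk$rank - rank_prev
    rank_prev <- qk$rank
    Qs[[k + 1]] <- qr.Q(qk)[, seq_len(qk$rank), drop = FALSE]
  }
  list(Qs = Qs, df = df)
}

rss_of <- function(Q, Y) sum(Y^2) - sum(crossprod(Q, Y)^2)

#' RRPP linear model (Procrustes ANOVA / ANCOVA)
#'
#' @param Y `n x q` response matrix (flattened Procrustes shape variables
#'   from [flatten_shapes()], or a single column such as log centroid size).
#' @param spec a [model_spec()].
#' @param data data.frame of covariates/factors named in `spec$terms`.
#' @return an `rrpp_anova`: data.frame with one row per term plus
#'   `Residuals` and `Total`, columns `df`, `SS`, `MS`, `Rsq`, `F`, `Z`,
#'   `p`.  `Z` is computed on the F distribution itself (not log F).
#' @export
rrpp_lm <- function(Y, spec, data) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  nb <- nested_bases(spec$terms, data, n)
  Qs <- nb$Qs; df <- nb$df
  K <- length(spec$terms)
  df_res <- (n - 1) - sum(df)
  if (df_res <= 0) stop("model exhausts the degrees of freedom (n too small)")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  perms <- replicate(spec$n_perm - 1, sample.int(n))
  Fmat <- matrix(NA_real_, spec$n_perm, K)
  # reduced-model fits for the RRPP step
  fits <- lapply(seq_len(K), function(k) Qs[[k]] %*% crossprod(Qs[[k]], Y))
  rss_obs <- vapply(seq_len(K + 1), function(j) rss_of(Qs[[j]], Y), 0)
  SS <- rss_obs[seq_len(K)] - rss_obs[2:(K + 1)]
  Fmat[1, ] <- (SS / df) / (rss_obs[K + 1] / df_res)
  for (it in seq_len(spec$n_perm - 1)) {
    pm <- perms[, it]
    for (k in seq_len(K)) {
      E <- Y - fits[[k]]
      Ystar <- fits[[k]] + E[pm, , drop = FALSE]
      ss_k <- rss_of(Qs[[k]], Ystar) - rss_of(Qs[[k + 1]], Ystar)
      Fmat[it + 1, k] <- (ss_k / df[k]) / (rss_of(Qs[[K + 1]], Ystar) / df_res)
    }
  }
  pval <- colMeans(sweep(Fmat, 2, Fmat[1, ], ">=") | abs(sweep(Fmat, 2, Fmat[1, ])) < 1e-12)
  Zval <- (Fmat[1, ] - colMeans(Fmat)) / apply(Fmat, 2, stats::sd)
  ss_total <- rss_obs[1]
  tab <- data.frame(
    term = c(spec$terms, "Residuals", "Total"),
    df = c(df, df_res, n - 1),
    SS = c(SS, rss_obs[K + 1], ss_total),
    MS = c(SS / df, rss_obs[K + 1] / df_res, NA),
    Rsq = c(SS, rss_obs[K + 1], NA) / ss_total,
    F = c(Fmat[1, ], NA, NA),
    Z = c(Zval, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab, n_perm = spec$n_perm, seed = spec$seed,
                 F_perm = Fmat), class = "rrpp_anova")
}

#' @export
print.rrpp_anova <- function(x, ...) {
  cat("RRPP ANOVA (sequential SS, Goodall's F,", x$n_perm, "permutations)\n")
  tab <- x$table
  tab[, -1] <- lapply(tab[, -1], function(v) round(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Full-versus-reduced RRPP model comparison
#'
#' Tests the joint contribution of the terms present in `full` but not in
#' `reduced` (the reduced model must be nested in the full one — its terms a
#' prefix-closed subset).  Residuals of the reduced model are permuted.
#'
#' @param Y response matrix.
#' @param full,reduced [model_spec()]s; `n_perm`/`seed` taken from `full`.
#' @param data covariate data.frame.
#' @return list with `SS_diff`, `df_diff`, `F`, `Z`, `p`.
#' @export
model_compare <- function(Y, full, reduced, data) {
  if (!all(reduced$terms %in% full$terms))
    stop("models are not nested: reduced terms must all appear in the full model")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  nf <- nested_bases(full$terms, data, n)
  nr <- nested_bases(reduced$terms, data, n)
  Qf <- nf$Qs[[length(nf$Qs)]]
  Qr <- nr$Qs[[length(nr$Qs)]]
  df_diff <- ncol(Qf) - ncol(Qr)
  df_res <- n - ncol(Qf)
  if (!is.null(full$seed)) set.seed(full$seed)
  stat <- function(Yx) {
    rss_r <- rss_of(Qr, Yx); rss_f <- rss_of(Qf, Yx)
    list(ss = rss_r - rss_f,
         F = if (df_diff > 0) ((rss_r - rss_f) / df_diff) / (rss_f / df_res) else 0)
  }
  obs <- stat(Y)
  fit_r <- Qr %*% crossprod(Qr, Y)
  E <- Y - fit_r
  Fs <- numeric(full$n_perm)
  Fs[1] <- obs$F
  for (it in seq_len(full$n_perm - 1))
    Fs[it + 1] <- stat(fit_r + E[sample.int(n), , drop = FALSE])$F
  list(SS_diff = obs$ss, df_diff = df_diff, F = obs$F,
       Z = (Fs[1] - mean(Fs)) / stats::sd(Fs),
       p = mean(Fs >= Fs[1] - 1e-12))
}

#' Homogeneity-of-slopes test
#'
#' Fits a per-group multivariate regression of `Y` on `log_size` and compares
#' every pair of groups by (a) the absolute difference of slope-vector
#' magnitudes and (b) the angle between slope vectors.  P-values come from
#' RRPP under the common-slope model `Y ~ log_size + group`.
#'
#' @param Y `n x q` response matrix.
#' @param log_size numeric covariate.
#' @param groups factor (or coercible) of group labels, each with `n >= 3`
#'   and nonzero size variance.
#' @param n_perm,seed permutation controls.
#' @return data.frame with one row per group pair: `length_diff` (mm of
#'   shape per unit log size), `angle_deg` in `[0, 180]`, `p_length`,
#'   `p_angle`.
#' @export
slope_homogeneity <- function(Y, log_size, groups, n_perm = 1000, seed = NULL) {
  Y <- as.matrix(Y)
  groups <- factor(groups)
  n <- nrow(Y)
  lv <- levels(groups)
  if (any(table(groups) < 3)) stop("each group needs at least 3 specimens")
  for (g in lv)
    if (stats::var(log_size[groups == g]) == 0)
      stop("group '", g, "' has zero size variance")
  slopes <- function(Yx) {
    t(vapply(lv, function(g) {
      i <- groups == g
      x <- log_size[i] - mean(log_size[i])
      crossprod(x, sweep(Yx[i, , drop = FALSE], 2,
                         colMeans(Yx[i, , drop = FALSE])))[1, ] / sum(x^2)
    }, numeric(ncol(Y))))
  }
  pairs <- utils::combn(length(lv), 2)
  pair_stats <- function(B) {
    nor <- sqrt(rowSums(B^2))
    out <- matrix(0, ncol(pairs), 2,
                  dimnames = list(NULL, c("length_diff", "angle_deg")))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      cosang <- sum(B[i, ] * B[j, ]) / (nor[i] * nor[j])
      out[k, ] <- c(abs(nor[i] - nor[j]),
                    acos(min(1, max(-1, cosang))) * 180 / pi)
    }
    out
  }
  obs <- pair_stats(slopes(Y))
  # null: common slope, group-specific intercepts
  dat <- data.frame(log_size = log_size, grp = groups)
  X <- stats::model.matrix(~ log_size + grp, dat)
  Q <- qr.Q(qr(X))
  fit <- Q %*% crossprod(Q, Y)
  E <- Y - fit
  if (!is.null(seed)) set.seed(seed)
  cnt_l <- cnt_a <- rep(1, nrow(obs))   # observed counts as one permutation
  for (it in seq_len(n_perm - 1)) {
    st <- pair_stats(slopes(fit + E[sample.int(n), , drop = FALSE]))
    cnt_l <- cnt_l + (st[, "length_diff"] >= obs[, "length_diff"] - 1e-12)
    cnt_a <- cnt_a + (st[, "angle_deg"] >= obs[, "angle_deg"] - 1e-12)
  }
  data.frame(group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]],
             length_diff = obs[, "length_diff"], angle_deg = obs[, "angle_deg"],
             p_length = cnt_l / n_perm, p_angle = cnt_a / n_perm,
             stringsAsFactors = FALSE)
}

#' Digitizing-error percentage from replicated measurements
#'
#' Procrustes ANOVA with specimen identity as the sole factor on an aligned
#' replicated dataset; the error percentage is `100 * SS_residual /
#' SS_total` — the share of shape variance attributable to digitizing rather
#' than to real specimen differences.
#'
#' @param aligned an `aligned_dataset` whose `meta` has `specimen_id` and
#'   `replicate` columns, with >= 2 specimens and >= 2 replicates each.
#' @param n_perm permutations for the accompanying ANOVA table.
#' @return list with `error_pct` and the underlying `anova` table.
#' @export
measurement_error_pct <- function(aligned, n_perm = 100) {
  meta <- aligned$meta
  if (is.null(meta)) stop("aligned dataset carries no metadata")
  if (length(unique(meta$specimen_id)) < 2)
    stop("need at least 2 specimens")
  if (!any(table(meta$specimen_id) >= 2))
    stop("need replicated measurements")
  Y <- flatten_shapes(aligned$shapes)
  res <- rrpp_lm(Y, model_spec("specimen", n_perm = n_perm, seed = 1),
                 data.frame(specimen = factor(meta$specimen_id)))
  tab <- res$table
  list(error_pct = 100 * tab$SS[tab$term == "Residuals"] /
         tab$SS[tab$term == "Total"],
       anova = res)
}
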