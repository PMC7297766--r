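# Multivariate drift test: is the observed between-period trait divergence
# compatible with draws from MVN(0, P * t/Ne), the dispersion genetic drift
# produces in t generations at effective size Ne?

#' Generation count between two sampling windows
#'
#' @param years_a,years_b `(start, end)` calendar-year ranges of the earlier
#'   and later samples; must not overlap.
#' @param gen_per_year generations per year (rats: 3).
#' @return list with `min`, `max`, `mean`: `min` spans the closest pair of
#'   years, `max` the farthest, `mean` their midpoint.
#' @export
generations_count <- function(years_a, years_b, gen_per_year = 3) {
  if (years_a[1] > years_a[2] || years_b[1] > years_b[2])
    stop("inverted year range")
  if (gen_per_year <= 0) stop("gen_per_year must be positive")
  if (years_b[1] <= years_a[2] && years_a[1] <= years_b[2] &&
      !identical(as.numeric(years_a), as.numeric(years_b)))
    stop("year ranges overlap")
  gmin <- gen_per_year * (years_b[1] - years_a[2])
  gmax <- gen_per_year * (years_b[2] - years_a[1])
  list(min = gmin, max = gmax, mean = (gmin + gmax) / 2)
}

#' Drift-test parameters
#'
#' @param t generations between the two samples (> 0).
#' @param Ne effective population size (> 0).
#' @param n_sim drift simulations (>= 100).
#' @param n_boot bootstrap resamples for the observed CI (>= 100).
#' @param seed integer seed.
#' @param alpha two-sided CI level (default 0.05 -> 2.5/97.5 percentiles).
#' @param correct_sampling subtract the estimated sampling-error
#'   contribution `tr(S1)/n1 + tr(S2)/n2` from the squared observed
#'   divergence (floored at 0).  With finite samples the raw `||dz||`
#'   confounds drift with the noise of estimating two mean vectors; the
#'   correction makes the observed statistic comparable to the pure-drift
#'   envelope.  Set `FALSE` for the literal uncorrected norm.
#' @return a `drift_params` list.
#' @export
drift_params <- function(t, Ne, n_sim = 1000, n_boot = 1000, seed = NULL,
                         alpha = 0.05, correct_sampling = TRUE) {
  stopifnot(t > 0, Ne > 0, n_sim >= 100, n_boot >= 100,
            alpha > 0, alpha < 1)
  list(t = t, Ne = Ne, n_sim = as.integer(n_sim), n_boot = as.integer(n_boot),
       seed = seed, alpha = alpha, correct_sampling = correct_sampling)
}

# MVN sampler via symmetric eigendecomposition: handles PSD matrices with
# zero eigenvalues (e.g. t = 0 gives the zero matrix).
rmvn <- function(n, sigma) {
  m <- nrow(sigma)
  ei <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(ei$values, 0)
  matrix(stats::rnorm(n * m), n) %*% (t(ei$vectors) * sqrt(lam))
}

divergence_stat <- function(pop1, pop2, correct) {
  dz <- colMeans(pop2) - colMeans(pop1)
  nrm2 <- sum(dz^2)
  if (correct) {
    noise <- sum(diag(stats::cov(pop1))) / nrow(pop1) +
      sum(diag(stats::cov(pop2))) / nrow(pop2)
    sqrt(max(0, nrm2 - noise))
  } else sqrt(nrm2)
}

#' Multivariate drift test
#'
#' Compares the observed divergence of trait means between an ancestral and
#' a descendant sample against the envelope expected under pure genetic
#' drift.  Drift predicts the between-period mean shift to be a draw from
#' `MVN(0, D)` with divergence matrix `D = P_anc * t / Ne` (the ancestral
#' P-matrix standing in for G).  `n_sim` such draws give the simulated norm
#' distribution and its `(alpha/2, 1-alpha/2)` quantile envelope; the
#' observed norm gets a nonparametric bootstrap CI (resampling specimens
#' within each population).  Drift is rejected when the observed CI lies
#' entirely above the drift envelope — a conservative rule.
#'
#' @param pop1,pop2 `n1 x m` and `n2 x m` trait matrices (rows = specimens);
#'   `pop1` is the ancestral-period sample.  `trait_matrix` values also
#'   accepted.
#' @param P_anc ancestral-period [p_matrix()] (or bare `m x m` PSD matrix).
#' @param params a [drift_params()].
#' @return a `drift_test` object: `delta_z`, `observed_norm`, `observed_ci`,
#'   `drift_sim_norms`, `drift_ci`, `verdict` (`"drift_rejected"` /
#'   `"drift_not_rejected"`), `params`.
#' @export
drift_divergence_test <- function(pop1, pop2, P_anc, params) {
  pop1 <- as.matrix(pop1); pop2 <- as.matrix(pop2)
  M <- if (inherits(P_anc, "p_matrix")) P_anc$cov else as.matrix(P_anc)
  if (ncol(pop1) != ncol(pop2) || ncol(pop1) != nrow(M))
    stop("trait dimension mismatch between populations and P matrix")
  if (inherits(P_anc, "p_matrix") && !is.null(colnames(pop1)) &&
      !identical(colnames(pop1), P_anc$labels))
    stop("trait labels of pop1 do not match P_anc")
  if (nrow(pop1) < 3 || nrow(pop2) < 3)
    stop("need at least 3 specimens per population to bootstrap")
  check_psd(M, "P_anc")
  if (!is.null(params$seed)) set.seed(params$seed)
  dz <- colMeans(pop2) - colMeans(pop1)
  obs <- divergence_stat(pop1, pop2, params$correct_sampling)
  sims <- rmvn(params$n_sim, M * (params$t / params$Ne))
  drift_norms <- sqrt(rowSums(sims^2))
  qs <- c(params$alpha / 2, 1 - params$alpha / 2)
  drift_ci <- stats::quantile(drift_norms, qs, names = FALSE)
  boot <- vapply(seq_len(params$n_boot), function(b) {
    divergence_stat(pop1[sample.int(nrow(pop1), replace = TRUE), , drop = FALSE],
                    pop2[sample.int(nrow(pop2), replace = TRUE), , drop = FALSE],
                    params$correct_sampling)
  }, 0)
  observed_ci <- stats::quantile(boot, qs, names = FALSE)
  verdict <- if (observed_ci[1] > drift_ci[2]) "drift_rejected"
             else "drift_not_rejected"
  structure(list(delta_z = dz, observed_norm = obs,
                 observed_ci = observed_ci, drift_sim_norms = drift_norms,
                 drift_ci = drift_ci, verdict = verdict, params = params),
            class = "drift_test")
}

#' @export
print.drift_test <- function(x, ...) {
  cat("multivariate drift test (t =", x$params$t, ", Ne =", x$params$Ne, ")\n")
  cat(sprintf("  observed divergence: %.4f  [%.4f, %.4f]%s\n",
              x$observed_norm, x$observed_ci[1], x$observed_ci[2],
              if (x$params$correct_sampling) " (sampling-error corrected)" else ""))
  cat(sprintf("  drift envelope:      [%.4f, %.4f]\n",
              x$drift_ci[1], x$drift_ci[2]))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
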