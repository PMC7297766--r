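# Synthetic data with known ground truth.  Every generator is fully seeded
# so downstream recovery tests are reproducible bit-for-bit.

#' Generate a symmetric landmark template with a matching base shape
#'
#' Midline landmarks sit on the x = 0 sagittal plane; each bilateral pair is
#' mirrored in x, so the base shape is exactly bilaterally symmetric.
#' Distance definitions cover every midline-midline pair, plus one bilateral
#' distance per pair (left landmark to the first midline landmark) with its
#' mirrored right-side copy, `mirror_of` set reciprocally.
#'
#' @param n_pairs bilateral pairs (>= 0); 19 pairs + 5 midline reproduces
#'   the 43-landmark cranium count.
#' @param n_midline midline landmarks (>= 3).
#' @param seed integer seed for the base geometry.
#' @return a `landmark_template`; `attr(, "base_shape")` holds the `p x 3`
#'   base shape scaled to unit centroid size.
#' @export
make_template <- function(n_pairs, n_midline, seed = 1L) {
  stopifnot(n_pairs >= 0, n_midline >= 3)
  base <- standin_base_shape(n_pairs, n_midline, seed)
  mid_nm <- sprintf("mid%d", seq_len(n_midline))
  l_nm <- if (n_pairs) sprintf("L%d", seq_len(n_pairs)) else character()
  r_nm <- if (n_pairs) sprintf("R%d", seq_len(n_pairs)) else character()
  nm <- c(mid_nm, l_nm, r_nm)
  paired <- if (n_pairs) cbind(left = l_nm, right = r_nm) else NULL
  dd_list <- list()
  mm <- utils::combn(n_midline, 2)
  dd_list$mid <- distance_defs(
    name = sprintf("d_%s_%s", mid_nm[mm[1, ]], mid_nm[mm[2, ]]),
    end1 = mid_nm[mm[1, ]], end2 = mid_nm[mm[2, ]])
  if (n_pairs) {
    ln <- sprintf("d_%s_%s", l_nm, mid_nm[1])
    rn <- sprintf("d_%s_%s", r_nm, mid_nm[1])
    dd_list$bil <- rbind(
      distance_defs(ln, l_nm, rep(mid_nm[1], n_pairs), mirror_of = rn),
      distance_defs(rn, r_nm, rep(mid_nm[1], n_pairs), mirror_of = ln))
  }
  dd <- do.call(rbind, dd_list)
  rownames(dd) <- NULL
  tpl <- landmark_template(nm, paired = paired, midline = mid_nm,
                           views = stats::setNames(rep("common", length(nm)), nm),
                           distance_defs = dd)
  base <- sweep(base, 2, colMeans(base))
  attr(tpl, "base_shape") <- base / centroid_size(base)
  tpl
}

#' Configuration for the landmark-data simulator
#'
#' The generator emulates the statistical structure the shape ANCOVA
#' assumes: a common mean shape, static allometry (a shape direction per
#' unit log centroid size), additive time-period and sex mean shifts,
#' individual variation drawn from a known covariance, and iid Gaussian
#' digitizing noise per coordinate per replicate.  Effects live in shape
#' space (consensus-relative, unit centroid size) and are added before the
#' configuration is scaled to its drawn size.
#'
#' @param template a [make_template()] template.
#' @param n_per_group named counts for the `period x sex` cells
#'   (`g1890s_F`, `g1890s_M`, `g2010s_F`, `g2010s_M`).
#' @param base_shape `p x 3` mean shape; defaults to the template's, always
#'   renormalized to unit centroid size.
#' @param allometry,period_effect,sex_effect `p x 3` shape displacements
#'   (allometry is per unit log size; period applies to 2010s, sex to M).
#' @param individual_sd scalar sd of isotropic individual shape variation,
#'   or a full `3p x 3p` covariance via `individual_cov`.
#' @param individual_cov optional PSD covariance over the flattened shape.
#' @param digitizing_sd mm sd of digitizing noise per coordinate.
#' @param size_range `(min, max)` centroid size in mm; sizes drawn uniform.
#' @param n_replicates replicate digitizations per specimen (>= 1; replicate
#'   0 is the primary).
#' @param seed integer seed.
#' @return a `synthetic_shape_config` list (validated).
#' @export
synthetic_shape_config <- function(template,
                                   n_per_group = c(g1890s_F = 12, g1890s_M = 12,
                                                   g2010s_F = 12, g2010s_M = 12),
                                   base_shape = attr(template, "base_shape"),
                                   allometry = NULL, period_effect = NULL,
                                   sex_effect = NULL,
                                   individual_sd = 0.005,
                                   individual_cov = NULL,
                                   digitizing_sd = 0.05,
                                   size_range = c(40, 55),
                                   n_replicates = 1, seed = 1L) {
  p <- length(template$landmark_names)
  zero <- matrix(0, p, 3)
  if (is.null(allometry)) allometry <- zero
  if (is.null(period_effect)) period_effect <- zero
  if (is.null(sex_effect)) sex_effect <- zero
  stopifnot(all(n_per_group >= 0), digitizing_sd >= 0, individual_sd >= 0,
            n_replicates >= 1, size_range[1] <= size_range[2],
            size_range[1] > 0, nrow(base_shape) == p)
  base_shape <- sweep(base_shape, 2, colMeans(base_shape))
  base_shape <- base_shape / centroid_size(base_shape)
  if (nrow(template$paired)) {
    refl <- reflect_relabel(base_shape, template)
    if (max(abs(refl - base_shape)) > 1e-8)
      stop("base_shape must be bilaterally symmetric for a paired template")
  }
  if (!is.null(individual_cov)) check_psd(individual_cov, "individual_cov")
  structure(list(template = template, n_per_group = n_per_group,
                 base_shape = base_shape, allometry = allometry,
                 period_effect = period_effect, sex_effect = sex_effect,
                 individual_sd = individual_sd, individual_cov = individual_cov,
                 digitizing_sd = digitizing_sd, size_range = size_range,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "synthetic_shape_config")
}

#' Simulate a landmark dataset
#'
#' Each specimen's unit-size shape is
#' `base + log(size) * allometry + period_effect * 1(2010s) +
#' sex_effect * 1(M) + individual deviation`; the configuration is then
#' scaled to its drawn centroid size and each replicate receives fresh iid
#' digitizing noise.  Same seed, same dataset, bit for bit.
#'
#' @param config a [synthetic_shape_config()].
#' @return a [shape_dataset()]; `attr(, "truth")` records the effect fields
#'   and per-specimen sizes for recovery tests.
#' @export
simulate_shapes <- function(config) {
  stopifnot(inherits(config, "synthetic_shape_config"))
  set.seed(config$seed)
  tpl <- config$template
  p <- nrow(config$base_shape)
  cells <- expand.grid(sex = c("F", "M"), period = c("1890s", "2010s"),
                       stringsAsFactors = FALSE)[, 2:1]
  counts <- config$n_per_group[sprintf("g%s_%s", cells$period, cells$sex)]
  n <- sum(counts)
  period <- rep(cells$period, counts)
  sex <- rep(cells$sex, counts)
  year <- ifelse(period == "1890s", 1890L, 2015L)
  sizes <- stats::runif(n, config$size_range[1], config$size_range[2])
  coords_list <- list()
  meta_list <- list()
  for (i in seq_len(n)) {
    dev <- if (!is.null(config$individual_cov))
      unflatten_shape(as.vector(rmvn(1, config$individual_cov)), p)
    else matrix(stats::rnorm(p * 3, 0, config$individual_sd), p, 3)
    shp <- config$base_shape + log(sizes[i]) * config$allometry +
      (period[i] == "2010s") * config$period_effect +
      (sex[i] == "M") * config$sex_effect + dev
    shp <- sizes[i] * shp / centroid_size(shp)
    for (r in seq_len(config$n_replicates)) {
      noisy <- shp + matrix(stats::rnorm(p * 3, 0, config$digitizing_sd), p, 3)
      coords_list[[length(coords_list) + 1]] <- noisy
      meta_list[[length(meta_list) + 1]] <- data.frame(
        specimen_id = sprintf("syn%03d", i), replicate = r - 1L,
        year = year[i], period = period[i], sex = sex[i],
        stringsAsFactors = FALSE)
    }
  }
  arr <- array(0, c(length(coords_list), p, 3))
  for (k in seq_along(coords_list)) arr[k, , ] <- coords_list[[k]]
  ds <- shape_dataset(tpl, arr, do.call(rbind, meta_list))
  attr(ds, "truth") <- list(allometry = config$allometry,
                            period_effect = config$period_effect,
                            sex_effect = config$sex_effect, sizes = sizes)
  ds
}

#' Configuration for the trait-divergence simulator
#'
#' @param m trait count.
#' @param P_true `m x m` PSD within-population covariance (mm^2); default is
#'   a moderately correlated matrix `0.25 * (0.3 J + 0.7 I)` typical of mm-
#'   scale skull distances.
#' @param t,Ne drift parameters; the default ratio `370/24905` mirrors a
#'   ~120-year rodent time series.
#' @param mode `"drift"` or `"selection"`.
#' @param selection_vector length-`m` added mean shift (required iff
#'   `mode = "selection"`).
#' @param n1,n2 sample sizes.
#' @param mu trait baseline (positive); default `10 + 0.5 * (1:m)` mm.
#' @param seed integer seed.
#' @return a `divergence_sim_config` list.
#' @export
divergence_sim_config <- function(m = 20, P_true = NULL, t = 370, Ne = 24905,
                                  mode = c("drift", "selection"),
                                  selection_vector = NULL,
                                  n1 = 25, n2 = 25, mu = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(P_true))
    P_true <- 0.25 * (matrix(0.3, m, m) + diag(0.7, m))
  check_psd(P_true, "P_true")
  if (mode == "selection" && is.null(selection_vector))
    stop("selection mode requires selection_vector")
  if (mode == "drift" && !is.null(selection_vector))
    stop("selection_vector only applies in selection mode")
  if (is.null(mu)) mu <- 10 + 0.5 * seq_len(m)
  stopifnot(nrow(P_true) == m, length(mu) == m, t >= 0, Ne > 0, n1 >= 1, n2 >= 1)
  structure(list(m = m, P_true = P_true, t = t, Ne = Ne, mode = mode,
                 selection_vector = selection_vector, n1 = n1, n2 = n2,
                 mu = mu, seed = seed),
            class = "divergence_sim_config")
}

#' Simulate two trait populations diverged under drift or selection
#'
#' The ancestral sample is `n1` draws from `MVN(mu, P_true)`.  A single
#' drift shift `delta ~ MVN(0, P_true * t/Ne)` is drawn, and the descendant
#' sample is `n2` draws from `MVN(mu + delta + s, P_true)` where `s` is the
#' selection vector (zero under pure drift).
#'
#' @param config a [divergence_sim_config()].
#' @return list with `pop1`, `pop2` (matrices with trait column names) and
#'   `delta` (the realized drift shift) for moment checks.
#' @export
simulate_trait_divergence <- function(config) {
  stopifnot(inherits(config, "divergence_sim_config"))
  set.seed(config$seed)
  m <- config$m
  delta <- if (config$t > 0)
    as.vector(rmvn(1, config$P_true * (config$t / config$Ne)))
  else rep(0, m)
  s <- if (config$mode == "selection") config$selection_vector else rep(0, m)
  pop1 <- rmvn(config$n1, config$P_true)
  pop1 <- sweep(pop1, 2, config$mu, FUN = "+")
  pop2 <- rmvn(config$n2, config$P_true)
  pop2 <- sweep(pop2, 2, config$mu + delta + s, FUN = "+")
  colnames(pop1) <- colnames(pop2) <- sprintf("trait%02d", seq_len(m))
  list(pop1 = pop1, pop2 = pop2, delta = delta)
}
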