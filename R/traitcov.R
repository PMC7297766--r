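# Interlandmark-distance traits and P-matrix comparison.
#
# Distances are computed from RAW digitized coordinates (mm), never from
# Procrustes-aligned ones: Euclidean distances are rigid-motion invariant,
# so superimposition is unnecessary, and keeping mm units preserves
# biologically interpretable differences (e.g. a 0.19 mm tooth-row change).

#' Interlandmark-distance trait matrix
#'
#' One Euclidean distance per definition; definitions related by `mirror_of`
#' (left/right copies of a bilaterally symmetric distance) are averaged into
#' a single trait named after the alphabetically first member of the pair.
#'
#' @param ds a [shape_dataset()]; landmarks referenced by the definitions
#'   must be observed or imputed.  Only primary measurements
#'   (`replicate == 0`) enter the trait matrix.
#' @param defs distance-definition data.frame; defaults to the template's.
#' @param log take natural logs of the averaged distances.
#' @return a `trait_matrix`: list with `values` (`n x m`, mm), `specimens`,
#'   `traits`, `population` (the period label per specimen).
#' @export
interlandmark_distances <- function(ds, defs = ds$template$distance_defs,
                                    log = FALSE) {
  if (!nrow(defs)) stop("no distance definitions")
  prim <- which(ds$meta$replicate == 0)
  nm <- ds$template$landmark_names
  i1 <- match(defs$end1, nm); i2 <- match(defs$end2, nm)
  need <- unique(c(i1, i2))
  if (any(ds$missing[prim, need]))
    stop("a distance definition references a missing, unimputed landmark")
  raw <- t(vapply(prim, function(s) {
    a <- matrix(ds$coords[s, i1, ], nrow = length(i1))
    b <- matrix(ds$coords[s, i2, ], nrow = length(i2))
    sqrt(rowSums((a - b)^2))
  }, numeric(nrow(defs))))
  if (nrow(defs) == 1) raw <- matrix(raw, ncol = 1)
  colnames(raw) <- defs$name
  # collapse mirror pairs
  keep <- rep(TRUE, nrow(defs))
  for (k in seq_len(nrow(defs))) {
    mo <- defs$mirror_of[k]
    if (!is.na(mo) && defs$name[k] > mo) keep[k] <- FALSE
  }
  vals <- raw[, keep, drop = FALSE]
  for (k in which(keep)) {
    mo <- defs$mirror_of[k]
    if (!is.na(mo))
      vals[, defs$name[k]] <- (raw[, defs$name[k]] + raw[, mo]) / 2
  }
  if (log) vals <- base::log(vals)
  structure(list(values = vals, specimens = ds$meta$specimen_id[prim],
                 traits = colnames(vals),
                 population = as.character(ds$meta$period[prim])),
            class = "trait_matrix")
}

#' Phenotypic variance-covariance (P-) matrix
#'
#' Unbiased (n-1) sample covariance of one population's trait values.  P
#' stands in for the additive-genetic G-matrix in the drift test, a standard
#' proxy for mammalian skull traits.
#'
#' @param traits a `trait_matrix`.
#' @param population population label to subset on (`NULL` = all rows).
#' @return a `p_matrix`: list with `labels`, `cov` (`m x m`, mm^2), `n`,
#'   `population`.
#' @export
p_matrix <- function(traits, population = NULL) {
  rows <- if (is.null(population)) seq_len(nrow(traits$values))
          else which(traits$population == population)
  n <- length(rows)
  if (n < 3) stop("need at least 3 specimens for a covariance matrix")
  m <- ncol(traits$values)
  if (n < m)
    warning(sprintf("n = %d < m = %d traits: P-matrix is singular", n, m))
  cv <- stats::cov(traits$values[rows, , drop = FALSE])
  structure(list(labels = traits$traits, cov = cv, n = n,
                 population = if (is.null(population)) "all" else population),
            class = "p_matrix")
}

#' @export
print.p_matrix <- function(x, ...) {
  cat("P-matrix (", x$population, "): ", length(x$labels), " traits, n = ",
      x$n, "\n", sep = "")
  cat("  trace:", format(sum(diag(x$cov))), "mm^2\n")
  invisible(x)
}

check_psd <- function(M, label) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * sum(pmax(ev, 0)))
    stop(label, " is not positive semidefinite")
  invisible(ev)
}

#' Random-skewers comparison of two covariance matrices
#'
#' Draws `n_vectors` random selection vectors uniformly on the unit sphere
#' (normalized iid Gaussians), applies each to both matrices
#' (`dz = P beta`), and records the cosine of the angle between the two
#' response vectors.  The reported correlation is the mean response
#' correlation; the p-value is the probability that the cosine of two
#' independent uniform random unit vectors in `m` dimensions exceeds the
#' observed mean, from the closed-form null `(1 + X)/2 ~
#' Beta((m-1)/2, (m-1)/2)`.
#'
#' @param P1,P2 `p_matrix` objects (or bare matrices) with matching traits.
#' @param n_vectors number of skewers.
#' @param seed integer seed.
#' @param dist `"sphere"` (default) or `"cube"` (historical
#'   uniform-in-a-cube draws, centered).
#' @return a `skewers_result`: list with `correlation`, `p`, `n_vectors`,
#'   `seed`, `response_correlations`.
#' @export
random_skewers <- function(P1, P2, n_vectors = 1000, seed = NULL,
                           dist = c("sphere", "cube")) {
  dist <- match.arg(dist)
  M1 <- if (inherits(P1, "p_matrix")) P1$cov else as.matrix(P1)
  M2 <- if (inherits(P2, "p_matrix")) P2$cov else as.matrix(P2)
  if (inherits(P1, "p_matrix") && inherits(P2, "p_matrix") &&
      !identical(P1$labels, P2$labels))
    stop("trait labels differ between the two matrices")
  m <- nrow(M1)
  if (!identical(dim(M1), dim(M2))) stop("matrix dimensions differ")
  check_psd(M1, "P1"); check_psd(M2, "P2")
  if (!is.null(seed)) set.seed(seed)
  B <- if (dist == "sphere") matrix(stats::rnorm(n_vectors * m), n_vectors)
       else matrix(stats::runif(n_vectors * m, -1, 1), n_vectors)
  B <- B / sqrt(rowSums(B^2))
  R1 <- B %*% M1
  R2 <- B %*% M2
  rc <- rowSums(R1 * R2) / (sqrt(rowSums(R1^2)) * sqrt(rowSums(R2^2)))
  corr <- mean(rc)
  p <- stats::pbeta((1 + corr) / 2, (m - 1) / 2, (m - 1) / 2,
                    lower.tail = FALSE)
  structure(list(correlation = corr, p = p, n_vectors = n_vectors,
                 seed = seed, response_correlations = rc),
            class = "skewers_result")
}

#' @export
print.skewers_result <- function(x, ...) {
  cat(sprintf("random skewers: mean response correlation %.3f (p = %.3g, %d vectors)\n",
              x$correlation, x$p, x$n_vectors))
  invisible(x)
}
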