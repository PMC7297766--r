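#' Principal component analysis of shape variables
#'
#' Eigendecomposition of the covariance of the mean-centered flattened
#' Procrustes shape variables (via SVD).  Because shape data live in a
#' degenerate subspace, only components with non-negligible variance are
#' kept.  For wireframe-style visualisation each axis also carries the
#' reconstructed extreme shapes `consensus +/- max|score| * vector`.
#'
#' @param aligned an `aligned_dataset` (or an `n x p x 3` array) with
#'   `n >= 3`.
#' @param tol relative eigenvalue cutoff below which axes are dropped.
#' @return a `shape_pca`: list with non-increasing `eigenvalues`,
#'   `pct_variance` (fractions summing to 1), `scores` (`n x k`,
#'   mutually orthogonal columns), `vectors` (loadings, `3p x k`), and
#'   `axis_shapes` (per-axis list of `lo`/`hi` `p x 3` reconstructions).
#' @export
shape_pca <- function(aligned, tol = 1e-10) {
  shapes <- if (inherits(aligned, "aligned_dataset")) aligned$shapes else aligned
  n <- dim(shapes)[1]; p <- dim(shapes)[2]
  if (n < 3) stop("PCA needs at least 3 specimens")
  Y <- flatten_shapes(shapes)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  total_var <- sum(Yc^2) / (n - 1)
  if (total_var == 0) stop("zero shape variance")
  sv <- svd(Yc)
  ev <- sv$d^2 / (n - 1)
  keep <- ev > tol * ev[1]
  ev <- ev[keep]
  scores <- (sv$u %*% diag(sv$d, length(sv$d)))[, keep, drop = FALSE]
  vectors <- sv$v[, keep, drop = FALSE]
  colnames(scores) <- colnames(vectors) <- sprintf("PC%d", seq_len(sum(keep)))
  axis_shapes <- lapply(seq_len(ncol(scores)), function(a) {
    ext <- max(abs(scores[, a]))
    list(lo = unflatten_shape(mu - ext * vectors[, a], p),
         hi = unflatten_shape(mu + ext * vectors[, a], p))
  })
  structure(list(eigenvalues = ev, pct_variance = ev / sum(ev),
                 total_variance = total_var,
                 scores = scores, vectors = vectors, center = mu,
                 axis_shapes = axis_shapes), class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat("shape PCA:", length(x$eigenvalues), "axes;",
      "first", k, "explain",
      sprintf("%.1f%%", 100 * sum(x$pct_variance[seq_len(k)])), "\n")
  print(round(rbind(eigenvalue = x$eigenvalues[seq_len(k)],
                    pct = 100 * x$pct_variance[seq_len(k)]), 4))
  invisible(x)
}
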