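# Procrustes machinery.  All configurations are p x 3 matrices in mm.

#' Centroid size
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard geometric-morphometric size measure.
#'
#' @param config `p x 3` matrix; rows with non-finite values (missing
#'   landmarks) are excluded.
#' @return positive scalar (mm).
#' @export
centroid_size <- function(config) {
  ok <- apply(is.finite(config), 1, all)
  if (sum(ok) < 2) stop("need at least 2 observed landmarks for centroid size")
  m <- config[ok, , drop = FALSE]
  sqrt(sum(sweep(m, 2, colMeans(m))^2))
}

#' Ordinary Procrustes fit of one configuration onto another
#'
#' Least-squares superimposition of `moving` onto `target` over translation,
#' rotation, optionally scaling and reflection.  With
#' `allow_reflection = FALSE` the rotation has determinant +1.
#'
#' @param moving,target complete `p x 3` matrices with equal `p`.
#' @param allow_scale permit a uniform scale factor.
#' @param allow_reflection permit an improper rotation.
#' @return list with `fitted` (`p x 3`, in the target frame), `residual`
#'   (minimized sum of squared distances), `rotation`, `scale`,
#'   `translation` such that
#'   `fitted = scale * sweep(moving, 2, centroid(moving)) %*% rotation + translation`.
#' @export
opa_fit <- function(moving, target, allow_scale = FALSE, allow_reflection = FALSE) {
  stopifnot(nrow(moving) == nrow(target), ncol(moving) == 3, ncol(target) == 3)
  if (!all(is.finite(moving)) || !all(is.finite(target)))
    stop("opa_fit requires complete configurations")
  cm <- colMeans(moving); ct <- colMeans(target)
  A <- sweep(moving, 2, cm); B <- sweep(target, 2, ct)
  if (qr(A)$rank < 2 || qr(B)$rank < 2) stop("degenerate (rank < 2) configuration")
  M <- crossprod(A, B)
  sv <- svd(M)
  sgn <- rep(1, 3)
  if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0) sgn[3] <- -1
  R <- sv$u %*% diag(sgn) %*% t(sv$v)
  s <- if (allow_scale) sum(sv$d * sgn) / sum(A^2) else 1
  fitted <- s * A %*% R
  fitted <- sweep(fitted, 2, ct, FUN = "+")
  list(fitted = fitted, residual = sum((fitted - target)^2),
       rotation = R, scale = s, translation = ct)
}

#' Generalized Procrustes alignment
#'
#' Iteratively rotates every configuration to the running consensus until the
#' total residual changes by less than `tol` (default 1e-10) or `max_iter`
#' passes.  With `scale = TRUE` (full/partial Procrustes as used throughout
#' this package) configurations are normalized to unit centroid size; the
#' original centroid sizes are always kept in `centroid_sizes` for use as the
#' allometry covariate.  Deterministic — no RNG.
#'
#' @param ds a complete [shape_dataset()] (impute missing landmarks first),
#'   or an `n x p x 3` array.
#' @param scale normalize to unit centroid size.
#' @param tol,max_iter convergence controls.
#' @return an `aligned_dataset`: list with `shapes` (`n x p x 3` Procrustes
#'   shape variables), `centroid_sizes` (original, mm), `consensus`
#'   (arithmetic mean of `shapes`), `component = "whole"`, `iterations`
#'   (residual log, non-increasing), plus the carried `meta`/`template`.
#' @export
gpa_align <- function(ds, scale = TRUE, tol = 1e-10, max_iter = 100) {
  arr <- if (inherits(ds, "shape_dataset")) ds$coords else ds
  if (inherits(ds, "shape_dataset") && any(ds$missing))
    stop("gpa_align requires complete configurations; impute missing landmarks first")
  n <- dim(arr)[1]; p <- dim(arr)[2]
  if (n < 1) stop("empty dataset")
  cs <- apply(arr, 1, centroid_size)
  X <- array(0, dim(arr))
  for (i in seq_len(n)) {
    m <- sweep(arr[i, , ], 2, colMeans(arr[i, , ]))
    X[i, , ] <- if (scale) m / cs[i] else m
  }
  consensus <- X[1, , ]
  resid_log <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n))
      X[i, , ] <- opa_fit(X[i, , ], consensus)$fitted
    consensus <- apply(X, c(2, 3), mean)
    if (scale) consensus <- consensus / sqrt(sum(consensus^2))
    total <- sum(vapply(seq_len(n),
                        function(i) sum((X[i, , ] - consensus)^2), 0))
    resid_log <- c(resid_log, total)
    if (is.finite(prev) && abs(prev - total) < tol) break
    prev <- total
  }
  if (length(resid_log) == max_iter && abs(diff(utils::tail(resid_log, 2))) >= tol)
    warning("GPA did not converge in ", max_iter, " passes; residual log attached")
  consensus <- apply(X, c(2, 3), mean)   # stored consensus = mean of shapes
  structure(list(shapes = X, centroid_sizes = cs, consensus = consensus,
                 component = "whole", iterations = resid_log,
                 scaled = scale,
                 meta = if (inherits(ds, "shape_dataset")) ds$meta else NULL,
                 template = if (inherits(ds, "shape_dataset")) ds$template else NULL),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("aligned_dataset (", x$component, " component): ",
      dim(x$shapes)[1], " x ", dim(x$shapes)[2], " landmarks\n", sep = "")
  cat("  GPA passes:", length(x$iterations),
      " final residual:", format(utils::tail(x$iterations, 1)), "\n")
  invisible(x)
}

#' Reflect a configuration and relabel its bilateral landmarks
#'
#' The reflection-and-relabel step of the object-symmetry method: the sign of
#' one coordinate axis is flipped and the rows of each bilateral pair are
#' swapped; midline landmarks keep their row.  Applying it twice is the
#' identity.
#'
#' @param config `p x 3` matrix in template landmark order.
#' @param template a [landmark_template()] with pair structure.
#' @param axis reflection axis.
#' @return `p x 3` matrix.
#' @export
reflect_relabel <- function(config, template, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  out <- config
  out[, a] <- -out[, a]
  if (nrow(template$paired)) {
    li <- match(template$paired[, 1], template$landmark_names)
    ri <- match(template$paired[, 2], template$landmark_names)
    tmp <- out[li, , drop = FALSE]
    out[li, ] <- out[ri, , drop = FALSE]
    out[ri, ] <- tmp
  }
  out
}

#' Object-symmetry decomposition
#'
#' For structures with internal bilateral symmetry: GPA is run on the
#' doubled set {originals U reflected-relabeled copies}; each specimen's
#' symmetric component is the mean of its two aligned copies and the
#' asymmetric component the half-difference, so symmetric + asymmetric
#' reconstructs the aligned original exactly.  Downstream shape analyses
#' consume the symmetric component.
#'
#' @param ds a complete [shape_dataset()] whose template has bilateral pairs.
#' @param scale passed to [gpa_align()].
#' @return list with `symmetric` and `asymmetric` `aligned_dataset`s.
#' @export
symmetric_decomposition <- function(ds, scale = TRUE) {
  tpl <- ds$template
  if (!nrow(tpl$paired))
    stop("object-symmetry decomposition needs a template with bilateral pairs")
  if (any(ds$missing)) stop("impute missing landmarks first")
  n <- dim(ds$coords)[1]
  doubled <- array(0, c(2 * n, dim(ds$coords)[2], 3))
  doubled[seq_len(n), , ] <- ds$coords
  for (i in seq_len(n))
    doubled[n + i, , ] <- reflect_relabel(ds$coords[i, , ], tpl)
  al <- gpa_align(doubled, scale = scale)
  sym <- asym <- array(0, dim(ds$coords))
  for (i in seq_len(n)) {
    sym[i, , ] <- (al$shapes[i, , ] + al$shapes[n + i, , ]) / 2
    asym[i, , ] <- (al$shapes[i, , ] - al$shapes[n + i, , ]) / 2
  }
  mk <- function(shapes, comp, center) structure(list(
    shapes = shapes, centroid_sizes = apply(ds$coords, 1, centroid_size),
    consensus = apply(shapes, c(2, 3), mean) * center,
    component = comp, iterations = al$iterations, scaled = scale,
    meta = ds$meta, template = tpl), class = "aligned_dataset")
  list(symmetric = mk(sym, "symmetric", 1),
       asymmetric = mk(asym, "asymmetric", 1))
}

# 3D thin-plate spline with the biharmonic kernel U(r) = r: interpolates the
# mapping src -> dst and reproduces affine maps exactly (the affine part of
# the spline absorbs them, leaving zero bending weights).
tps_fit <- function(src, dst) {
  k <- nrow(src)
  K <- as.matrix(stats::dist(src))
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst, matrix(0, 4, ncol(dst)))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular thin-plate spline system (coplanar or coincident landmarks)"))
  list(src = src, w = sol[seq_len(k), , drop = FALSE],
       a = sol[(k + 1):(k + 4), , drop = FALSE])
}

tps_eval <- function(fit, pts) {
  U <- sqrt(outer(rowSums(pts^2), rowSums(fit$src^2), "+") -
              2 * pts %*% t(fit$src))
  U[!is.finite(U) | U < 0] <- 0
  cbind(1, pts) %*% fit$a + U %*% fit$w
}

#' Estimate missing landmarks with a thin-plate spline
#'
#' Fits a 3D TPS (kernel `U(r) = r` plus affine part) mapping a complete
#' reference configuration to the specimen's observed landmarks, then places
#' each missing landmark at the image of its reference position.  Observed
#' coordinates are untouched.  Exact whenever the specimen is an affine
#' transform of the reference.
#'
#' @param coords specimen `p x 3` matrix (missing rows arbitrary).
#' @param missing logical length-`p` mask.
#' @param reference complete `p x 3` matrix, typically the consensus of the
#'   complete specimens.
#' @return list with completed `coords` and `imputed` (the input mask); the
#'   dataset-level wrapper [impute_missing()] clears the missing mask and
#'   retains the imputed flag.
#' @export
estimate_missing_tps <- function(coords, missing, reference) {
  if (!any(missing)) return(list(coords = coords, imputed = missing))
  obs <- which(!missing)
  if (length(obs) < 4) stop("need at least 4 observed landmarks for TPS imputation")
  if (qr(cbind(1, reference[obs, , drop = FALSE]))$rank < 4)
    stop("observed landmarks are coplanar in the reference; TPS underdetermined")
  fit <- tps_fit(reference[obs, , drop = FALSE], coords[obs, , drop = FALSE])
  coords[missing, ] <- tps_eval(fit, reference[which(missing), , drop = FALSE])
  list(coords = coords, imputed = missing)
}

#' Impute every missing landmark in a dataset
#'
#' Reference = mean configuration of the complete specimens (after a rigid
#' alignment of the complete specimens to the first one, so the mean is
#' geometrically meaningful), mapped into each incomplete specimen's own
#' frame via [estimate_missing_tps()].
#'
#' @param ds a [shape_dataset()].
#' @return a complete `shape_dataset`; `attr(,"imputed")` carries the
#'   original mask.
#' @export
impute_missing <- function(ds) {
  if (!any(ds$missing)) return(ds)
  complete <- which(rowSums(ds$missing) == 0)
  if (length(complete) < 1)
    stop("no complete specimens available to build an imputation reference")
  ref_set <- ds$coords[complete, , , drop = FALSE]
  ref <- ref_set[1, , ]
  if (length(complete) > 1) {
    acc <- array(0, dim(ref_set))
    for (i in seq_along(complete))
      acc[i, , ] <- opa_fit(ref_set[i, , ], ref)$fitted
    ref <- apply(acc, c(2, 3), mean)
  }
  out <- ds$coords
  for (i in which(rowSums(ds$missing) > 0))
    out[i, , ] <- estimate_missing_tps(ds$coords[i, , ], ds$missing[i, ], ref)$coords
  res <- shape_dataset(ds$template, out, ds$meta,
                       matrix(FALSE, dim(out)[1], dim(out)[2]))
  attr(res, "imputed") <- ds$missing
  res
}

#' Merge dorsal and ventral digitizing views of one specimen
#'
#' Rigidly superimposes the ventral view onto the dorsal frame (rotation +
#' translation only — both views are mm measurements of one physical object,
#' so no scaling and no reflection) using the landmarks common to both
#' views, then assembles the full configuration: dorsal-only landmarks from
#' the dorsal view, ventral-only landmarks transformed, common landmarks
#' averaged across the two fitted copies.
#'
#' @param dorsal,ventral `p x 3` matrices in full template order with
#'   non-view rows set to `NA` (or list objects with `coords`/`missing`).
#' @param template a [landmark_template()] with view labels.
#' @param max_rmsd sanity threshold (mm) on the common-landmark fit RMSD; a
#'   digitizing blunder triggers an error.
#' @return complete `p x 3` matrix over the union of the two views.
#' @export
merge_views <- function(dorsal, ventral, template, max_rmsd = Inf) {
  d_idx <- view_indices(template, "dorsal")
  v_idx <- view_indices(template, "ventral")
  c_idx <- which(template$views[template$landmark_names] == "common")
  ok_d <- apply(is.finite(dorsal), 1, all)
  ok_v <- apply(is.finite(ventral), 1, all)
  com <- intersect(c_idx, intersect(which(ok_d), which(ok_v)))
  if (length(com) < 3)
    stop("need >= 3 common landmarks observed in both views (have ",
         length(com), ")")
  fit <- opa_fit(ventral[com, , drop = FALSE], dorsal[com, , drop = FALSE],
                 allow_scale = FALSE, allow_reflection = FALSE)
  rmsd <- sqrt(fit$residual / length(com))
  if (rmsd > max_rmsd)
    stop(sprintf("view-merge fit RMSD %.3f mm exceeds threshold %.3f mm", rmsd, max_rmsd))
  cen <- colMeans(ventral[com, , drop = FALSE])
  xform <- function(m) sweep(sweep(m, 2, cen) %*% fit$rotation, 2,
                             fit$translation, FUN = "+")
  p <- length(template$landmark_names)
  merged <- matrix(NA_real_, p, 3)
  merged[d_idx, ] <- dorsal[d_idx, , drop = FALSE]
  v_only <- setdiff(v_idx, c_idx)
  merged[v_only, ] <- xform(ventral[v_only, , drop = FALSE])
  merged[com, ] <- (dorsal[com, , drop = FALSE] +
                      xform(ventral[com, , drop = FALSE])) / 2
  merged
}
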