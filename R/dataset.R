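#' Landmark dataset container
#'
#' Holds raw (or imputed) specimen landmark configurations together with the
#' template they follow and per-specimen metadata.  Coordinates are stored in
#' the units they were digitized in (mm); no rescaling happens before
#' superimposition, so interlandmark distances computed from a
#' `shape_dataset` are in the original units.
#'
#' @param template a [landmark_template()].
#' @param coords numeric array `n x p x 3` (specimen, landmark, axis), or a
#'   single `p x 3` matrix for one specimen.
#' @param meta data.frame with columns `specimen_id`, `replicate` (0 = primary
#'   measurement), and optionally `year`, `period` (`"1890s"`/`"2010s"`),
#'   `sex` (`"F"`/`"M"`).  One row per configuration.
#' @param missing logical `n x p` matrix marking unobserved landmarks;
#'   defaults to rows of `coords` that are non-finite.
#' @return an object of class `shape_dataset`.
#' @export
shape_dataset <- function(template, coords, meta, missing = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, nrow(coords), ncol(coords)))
  n <- dim(coords)[1]; p <- dim(coords)[2]
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"replicate" %in% names(meta)) meta$replicate <- rep(0L, nrow(meta))
  for (col in c("year", "period", "sex"))
    if (!col %in% names(meta)) meta[[col]] <- rep(NA, nrow(meta))
  meta$replicate <- as.integer(meta$replicate)
  if (is.null(missing)) {
    missing <- matrix(FALSE, n, p)
    for (i in seq_len(n))
      missing[i, ] <- !apply(is.finite(coords[i, , , drop = TRUE]), 1, all)
  }
  ds <- structure(list(template = template, coords = coords,
                       missing = missing, meta = meta),
                  class = "shape_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a shape dataset against its template
#'
#' Checks dimensions, uniqueness of `specimen_id x replicate`, finiteness of
#' observed coordinates, allowed factor codes, and period/year consistency
#' (1889-1895 belongs to the 1890s period, 2014-2016 to the 2010s).
#'
#' @param ds a `shape_dataset`.
#' @return `ds`, invisibly; errors on violation.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "shape_dataset"))
  tpl <- ds$template
  p <- length(tpl$landmark_names)
  d <- dim(ds$coords)
  if (length(d) != 3 || d[2] != p || d[3] != tpl$dim)
    stop(sprintf("coords must be n x %d x %d to match the template", p, tpl$dim))
  n <- d[1]
  if (nrow(ds$meta) != n) stop("meta must have one row per configuration")
  if (!identical(dim(ds$missing), c(n, p)) && !identical(dim(ds$missing), as.integer(c(n, p))))
    stop("missing mask must be n x p")
  key <- paste(ds$meta$specimen_id, ds$meta$replicate)
  if (anyDuplicated(key))
    stop("duplicated specimen_id x replicate: ", key[duplicated(key)][1])
  for (i in seq_len(n)) {
    obs <- !ds$missing[i, ]
    if (any(obs) && !all(is.finite(ds$coords[i, obs, ])))
      stop("non-finite observed coordinates in specimen ",
           ds$meta$specimen_id[i])
  }
  sx <- ds$meta$sex
  if (!all(is.na(sx) | sx %in% c("F", "M")))
    stop("unknown sex code: ", paste(unique(sx[!is.na(sx) & !sx %in% c("F", "M")]), collapse = ","))
  pd <- ds$meta$period
  if (!all(is.na(pd) | pd %in% c("1890s", "2010s")))
    stop("unknown period code: ", paste(unique(pd[!is.na(pd) & !pd %in% c("1890s", "2010s")]), collapse = ","))
  yr <- ds$meta$year
  chk <- !is.na(pd) & !is.na(yr)
  if (any(chk)) {
    exp_pd <- ifelse(yr >= 1889 & yr <= 1895, "1890s",
                     ifelse(yr >= 2014 & yr <= 2016, "2010s", NA))
    bad <- chk & !is.na(exp_pd) & pd != exp_pd
    if (any(bad))
      stop("period inconsistent with year for specimen ",
           ds$meta$specimen_id[which(bad)[1]])
  }
  invisible(ds)
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat("shape_dataset:", dim(x$coords)[1], "configurations x",
      dim(x$coords)[2], "landmarks (3D)\n")
  cat("  specimens:", length(unique(x$meta$specimen_id)),
      " missing landmarks:", sum(x$missing), "\n")
  if (!all(is.na(x$meta$period)))
    print(table(period = x$meta$period, sex = x$meta$sex, useNA = "no"))
  invisible(x)
}

#' Subset a shape dataset by configuration index
#' @param ds a `shape_dataset`.
#' @param i integer or logical index over configurations.
#' @return a `shape_dataset` with the selected configurations.
#' @export
subset_dataset <- function(ds, i) {
  shape_dataset(ds$template,
                ds$coords[i, , , drop = FALSE],
                ds$meta[i, , drop = FALSE],
                ds$missing[i, , drop = FALSE])
}

#' Flatten an n x p x 3 shape array to n x 3p
#'
#' Column order is landmark-major: `x1, y1, z1, x2, ...` — the convention all
#' covariance/PCA code in this package uses.
#' @param shapes `n x p x 3` array.
#' @return `n x 3p` matrix.
#' @export
flatten_shapes <- function(shapes) {
  n <- dim(shapes)[1]; p <- dim(shapes)[2]; k <- dim(shapes)[3]
  out <- matrix(0, n, p * k)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(shapes[i, , ]))
  out
}

#' Inverse of [flatten_shapes()] for a single configuration
#' @param v length-`3p` vector (landmark-major).
#' @param p landmark count.
#' @return `p x 3` matrix.
#' @export
unflatten_shape <- function(v, p) matrix(v, p, length(v) / p, byrow = TRUE)
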