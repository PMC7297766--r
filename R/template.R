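#' Landmark template
#'
#' A template declares the landmark scheme a study uses: landmark names and
#' order, which landmarks form bilateral (left/right) pairs, which lie on the
#' sagittal midline, which digitizing view each belongs to, and the
#' interlandmark distances used to build trait matrices.  Every dataset read
#' or simulated by this package is validated against a template.
#'
#' Landmark indices are 1-based in files and in all user-facing R interfaces
#' (R convention); the TPS writer/reader uses the same 1-based order.
#'
#' @param landmark_names character vector of unique landmark identifiers, in
#'   digitizing order.
#' @param paired two-column character matrix (or data.frame) of
#'   `(left, right)` landmark names forming bilateral pairs. May have 0 rows.
#' @param midline character vector of landmark names on the sagittal plane.
#' @param views named character vector mapping every landmark name to one of
#'   `"dorsal"`, `"ventral"`, `"common"`, `"mandible"`.  `"common"` marks
#'   landmarks digitized in both the dorsal and the ventral view.
#' @param distance_defs data.frame of interlandmark distance definitions with
#'   columns `name`, `end1`, `end2`, `mirror_of` (`NA` when unmirrored); see
#'   [distance_defs()].
#' @param dim spatial dimension; always 3 here.
#' @return An object of class `landmark_template`.
#' @seealso [cranium_template()], [mandible_template()], [make_template()]
#' @export
landmark_template <- function(landmark_names, paired = NULL, midline = character(),
                              views = NULL, distance_defs = NULL, dim = 3L) {
  landmark_names <- as.character(landmark_names)
  if (anyDuplicated(landmark_names))
    stop("landmark_names must be unique")
  if (is.null(paired)) {
    paired <- matrix(character(), ncol = 2)
  } else {
    paired <- as.matrix(paired)
    if (ncol(paired) != 2) stop("paired must have two columns (left, right)")
    storage.mode(paired) <- "character"
  }
  colnames(paired) <- c("left", "right")
  if (is.null(views)) {
    views <- stats::setNames(rep("common", length(landmark_names)), landmark_names)
  }
  if (is.null(distance_defs)) {
    distance_defs <- data.frame(name = character(), end1 = character(),
                                end2 = character(), mirror_of = character(),
                                stringsAsFactors = FALSE)
  }
  tpl <- structure(list(
    landmark_names = landmark_names,
    dim = as.integer(dim),
    paired = paired,
    midline = as.character(midline),
    views = views,
    distance_defs = distance_defs
  ), class = "landmark_template")
  validate_template(tpl)
  tpl
}

#' Build a distance-definition table
#'
#' @param name trait labels.
#' @param end1,end2 endpoint landmark names.
#' @param mirror_of label of the contralateral definition this one is averaged
#'   with (`NA` for midline / unmirrored distances).  The relation must be
#'   reciprocal.
#' @return data.frame usable as the `distance_defs` field of a template.
#' @export
distance_defs <- function(name, end1, end2, mirror_of = NA_character_) {
  data.frame(name = as.character(name), end1 = as.character(end1),
             end2 = as.character(end2),
             mirror_of = rep_len(as.character(mirror_of), length(name)),
             stringsAsFactors = FALSE)
}

#' Validate a landmark template
#'
#' Checks every structural invariant: all referenced ids exist, paired and
#' midline sets are disjoint, no landmark sits in two pairs, distance
#' endpoints are distinct and `mirror_of` relations are reciprocal.
#'
#' @param template a `landmark_template`.
#' @return the template, invisibly; errors on violation.
#' @export
validate_template <- function(template) {
  nm <- template$landmark_names
  stopifnot(inherits(template, "landmark_template"))
  pr <- template$paired
  ids_used <- c(as.vector(pr), template$midline, names(template$views),
                template$distance_defs$end1, template$distance_defs$end2)
  bad <- setdiff(ids_used, nm)
  if (length(bad))
    stop("template references unknown landmark(s): ", paste(bad, collapse = ", "))
  if (length(intersect(as.vector(pr), template$midline)))
    stop("paired and midline landmark sets must be disjoint")
  if (anyDuplicated(as.vector(pr)))
    stop("a landmark appears in more than one bilateral pair")
  if (nrow(pr) && any(pr[, 1] == pr[, 2]))
    stop("a bilateral pair cannot pair a landmark with itself")
  dd <- template$distance_defs
  if (nrow(dd)) {
    if (anyDuplicated(dd$name)) stop("distance definition names must be unique")
    if (any(dd$end1 == dd$end2)) stop("distance endpoints must be distinct")
    has_m <- !is.na(dd$mirror_of)
    if (any(has_m)) {
      if (!all(dd$mirror_of[has_m] %in% dd$name))
        stop("mirror_of references an unknown distance definition")
      back <- dd$mirror_of[match(dd$mirror_of[has_m], dd$name)]
      if (!all(back == dd$name[has_m]))
        stop("mirror_of relation is not reciprocal")
    }
  }
  vw <- template$views
  if (!all(vw %in% c("dorsal", "ventral", "common", "mandible")))
    stop("views must be one of dorsal/ventral/common/mandible")
  if (length(vw) && !setequal(names(vw), nm))
    stop("views must cover exactly the template landmarks")
  invisible(template)
}

#' @export
print.landmark_template <- function(x, ...) {
  cat("landmark_template:", length(x$landmark_names), "landmarks in",
      x$dim, "D\n")
  cat("  bilateral pairs:", nrow(x$paired),
      " midline:", length(x$midline), "\n")
  cat("  views:", paste(sprintf("%s=%d", names(table(x$views)),
                                table(x$views)), collapse = " "), "\n")
  cat("  distance definitions:", nrow(x$distance_defs), "\n")
  invisible(x)
}

#' Row indices of a view's landmarks
#'
#' Landmarks labelled `"common"` belong to both the dorsal and the ventral
#' view.
#'
#' @param template a `landmark_template`.
#' @param view one of `"dorsal"`, `"ventral"`, `"mandible"`.
#' @return integer indices into the template's landmark order.
#' @export
view_indices <- function(template, view) {
  v <- template$views[template$landmark_names]
  keep <- if (view %in% c("dorsal", "ventral")) v %in% c(view, "common") else v == view
  which(keep)
}

# deterministic stand-in geometry used by the shipped templates: midline on
# the x=0 plane, pairs mirrored in x.  Not real anatomy.
standin_base_shape <- function(n_pairs, n_midline, seed = 1L) {
  set.seed(seed)
  repeat {
    mid <- cbind(0, stats::runif(n_midline, -1, 1), stats::runif(n_midline, -1, 1))
    lft <- cbind(-stats::runif(n_pairs, 0.2, 1), stats::runif(n_pairs, -1, 1),
                 stats::runif(n_pairs, -1, 1))
    base <- rbind(mid, lft, cbind(-lft[, 1], lft[, 2:3, drop = FALSE]))
    # re-draw collinear geometries (midline-only templates are legitimately
    # planar, so only rank < 2 counts as degenerate)
    if (qr(scale(base, scale = FALSE))$rank >= 2) break
  }
  base
}

#' Synthetic stand-in templates with the study landmark counts
#'
#' The real landmark and distance definitions live in museum-collection
#' supplementary material and are not shipped; these templates are documented
#' synthetic stand-ins with the correct structure: the cranium has 43
#' landmarks (19 bilateral pairs + 5 midline) split into an 18-landmark
#' dorsal view and a 30-landmark ventral view sharing 5 common landmarks;
#' the mandible has 15 left-side landmarks with no object symmetry.
#'
#' @return a `landmark_template`.  `attr(tpl, "base_shape")` carries a
#'   matching synthetic mean shape (unit centroid size).
#' @export
cranium_template <- function() {
  tpl <- make_template(n_pairs = 19, n_midline = 5, seed = 43L)
  nm <- tpl$landmark_names
  # midline: 3 dorsal-only, 1 common, 1 ventral-only; pairs: 5 dorsal-only,
  # 2 common, 12 ventral-only -> |dorsal| = 18, |ventral| = 30, |common| = 5
  v <- stats::setNames(rep("ventral", length(nm)), nm)
  v[c("mid1", "mid2", "mid3")] <- "dorsal"
  v["mid4"] <- "common"
  left <- tpl$paired[, 1]; right <- tpl$paired[, 2]
  v[c(left[1:5], right[1:5])] <- "dorsal"
  v[c(left[6:7], right[6:7])] <- "common"
  tpl$views <- v
  validate_template(tpl)
  tpl
}

#' @rdname cranium_template
#' @export
mandible_template <- function() {
  nm <- sprintf("mnd%d", 1:15)
  set.seed(15L)
  base <- matrix(stats::runif(45, -1, 1), ncol = 3)
  base <- sweep(base, 2, colMeans(base))
  base <- base / sqrt(sum(base^2))
  combs <- utils::combn(15, 2)
  keep <- combs[, seq(1, ncol(combs), by = 7)]   # sparse stand-in distance set
  dd <- distance_defs(name = sprintf("d_%s_%s", nm[keep[1, ]], nm[keep[2, ]]),
                      end1 = nm[keep[1, ]], end2 = nm[keep[2, ]])
  tpl <- landmark_template(nm, paired = NULL, midline = character(),
                           views = stats::setNames(rep("mandible", 15), nm),
                           distance_defs = dd)
  attr(tpl, "base_shape") <- base
  tpl
}
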