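#' Oriented planes
#'
#' A plane is stored as a unit normal `n` and offset `d` such that a point
#' `p` lies on the plane iff `n . p == d`. Clipping planes additionally carry
#' an `interior` tag: `-1` means the palatal/interior half-space is
#' `n . p < d` (the convention used throughout), `+1` the opposite side,
#' `NA` for planes not used for clipping.
#'
#' @param normal Length-3 numeric; normalized internally.
#' @param offset Scalar offset (mm).
#' @param interior `-1`, `+1` or `NA`.
#' @return An object of class `palate_plane`.
#' @export
palate_plane <- function(normal, offset, interior = NA_real_) {
  normal <- unitize(as.numeric(normal))
  stopifnot_scalar_number(offset, "offset")
  structure(
    list(normal = normal, offset = as.numeric(offset), interior = interior),
    class = "palate_plane"
  )
}

#' @export
print.palate_plane <- function(x, ...) {
  cat(sprintf(
    "<palate_plane: n = (%.4f, %.4f, %.4f), d = %.4f%s>\n",
    x$normal[1], x$normal[2], x$normal[3], x$offset,
    if (!is.na(x$interior)) sprintf(", interior on %s side", if (x$interior < 0) "negative" else "positive") else ""
  ))
  invisible(x)
}

#' Signed distance of points from a plane
#'
#' @param plane A [palate_plane()].
#' @param points Numeric matrix (rows are points) or a length-3 vector.
#' @return Numeric vector of `n . p - d` values.
#' @export
signed_distance <- function(plane, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  drop(points %*% plane$normal) - plane$offset
}

# Flip a plane's normal/offset so `point` lies on the negative side, leaving
# the geometric plane unchanged. Points exactly on the plane keep the fitted
# sign.
orient_negative_towards <- function(plane, point) {
  s <- sum(plane$normal * point) - plane$offset
  if (s > 0) {
    plane$normal <- -plane$normal
    plane$offset <- -plane$offset
  }
  plane
}

#' Total-least-squares plane through a point cloud
#'
#' Fits the plane minimizing the sum of squared perpendicular distances: the
#' plane through the centroid whose normal is the singular vector of the
#' centered coordinates with the smallest singular value. The sign of the
#' normal is made deterministic by requiring its largest-magnitude component
#' to be positive.
#'
#' @param points Numeric matrix with >= 3 non-collinear rows.
#' @return A [palate_plane()] (no interior tag).
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) {
    rlang::abort("Plane fitting needs at least 3 points.",
      class = "palatwin_geometry_error"
    )
  }
  ctr <- colMeans(points)
  centered <- sweep(points, 2L, ctr)
  sv <- svd(centered)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    rlang::abort("Points are collinear or coincident; plane is undefined.",
      class = "palatwin_geometry_error"
    )
  }
  normal <- sv$v[, 3L]
  imax <- which.max(abs(normal))
  if (normal[imax] < 0) normal <- -normal
  palate_plane(normal, sum(normal * ctr))
}

raphe_points <- function(lm) {
  nms <- c("raphe_anterior", "raphe_middle", "raphe_posterior")
  present <- intersect(nms, rownames(lm$points))
  if (length(present) < length(nms)) {
    rlang::abort(sprintf(
      "Missing raphe landmark(s): %s",
      paste(setdiff(nms, present), collapse = ", ")
    ), class = "palatwin_geometry_error")
  }
  lm$points[nms, , drop = FALSE]
}

#' Gingival plane of a cast
#'
#' Total-least-squares plane through all palatal dento-gingival midpoints,
#' oriented so the palatal vault (the side containing `raphe_middle`) is the
#' negative, interior side.
#'
#' @param lm A completed [landmark_set()]: every `dg_*` landmark available.
#' @return A [palate_plane()] with `interior = -1`.
#' @export
gingival_plane <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  dg <- grep("^dg_", rownames(lm$points), value = TRUE)
  dg_missing <- grep("^dg_", lm$missing, value = TRUE)
  if (length(dg_missing) > 0L) {
    rlang::abort(sprintf(
      "Gingival plane needs all dento-gingival landmarks; missing: %s (run complete_landmarks() first)",
      paste(dg_missing, collapse = ", ")
    ), class = "palatwin_geometry_error")
  }
  pl <- fit_plane(lm$points[dg, , drop = FALSE])
  pl <- orient_negative_towards(pl, lm$points["raphe_middle", ])
  pl$interior <- -1
  pl
}

#' Mid-palatal (sagittal) plane of a cast
#'
#' The plane containing the least-squares line through the three raphe
#' landmarks projected onto the gingival plane, constructed orthogonal to the
#' gingival plane.
#'
#' @param lm A [landmark_set()] with the three raphe landmarks.
#' @param gingival The [gingival_plane()].
#' @return A [palate_plane()] orthogonal to `gingival` (no interior tag).
#' @export
midpalatal_plane <- function(lm, gingival) {
  rp <- raphe_points(lm)
  s <- signed_distance(gingival, rp)
  proj <- rp - outer(s, gingival$normal)
  ctr <- colMeans(proj)
  centered <- sweep(proj, 2L, ctr)
  sv <- svd(centered)
  if (sv$d[1] < 1e-9) {
    rlang::abort("Raphe landmarks are coincident; mid-palatal plane undefined.",
      class = "palatwin_geometry_error"
    )
  }
  dir <- sv$v[, 1L]
  normal <- unitize(cross3(dir, gingival$normal))
  imax <- which.max(abs(normal))
  if (normal[imax] < 0) normal <- -normal
  palate_plane(normal, sum(normal * ctr))
}

#' Posterior limit plane of the palate
#'
#' Transverse plane through the midpoint of the two most-distal palatal
#' landmarks of the terminal teeth, orthogonal to both the gingival and
#' mid-palatal planes, oriented so the anterior side (containing the incisive
#' papilla) is interior.
#'
#' @param lm A [landmark_set()] with both `distal_*` landmarks.
#' @param gingival,midpalatal The reference [palate_plane()]s.
#' @return A [palate_plane()] with `interior = -1`.
#' @export
posterior_plane <- function(lm, gingival, midpalatal) {
  teeth <- measurement_teeth(lm$stage)
  have <- intersect(teeth$distal, rownames(lm$points))
  if (length(have) < 2L) {
    rlang::abort(sprintf(
      "Missing distal landmark(s): %s",
      paste(setdiff(teeth$distal, have), collapse = ", ")
    ), class = "palatwin_geometry_error")
  }
  mid <- colMeans(lm$points[teeth$distal, , drop = FALSE])
  normal <- unitize(cross3(gingival$normal, midpalatal$normal))
  pl <- palate_plane(normal, sum(normal * mid))
  if (!"raphe_anterior" %in% rownames(lm$points)) {
    rlang::abort("raphe_anterior needed to orient the posterior plane.",
      class = "palatwin_geometry_error"
    )
  }
  pl <- orient_negative_towards(pl, lm$points["raphe_anterior", ])
  pl$interior <- -1
  pl
}

#' General transverse plane through an antimere pair
#'
#' Constructs the transverse plane orthogonal to both the gingival and
#' mid-palatal planes through the midpoint of a left/right landmark pair
#' projected onto the gingival plane. Exposed as a building block; the
#' Table-1 measurements themselves use [posterior_plane()] and raw landmark
#' lines.
#'
#' @param lm A [landmark_set()].
#' @param pair Character vector of two landmark names.
#' @param gingival,midpalatal Reference [palate_plane()]s.
#' @return A [palate_plane()] (no interior tag).
#' @export
transverse_plane <- function(lm, pair, gingival, midpalatal) {
  have <- intersect(pair, rownames(lm$points))
  if (length(have) < 2L) {
    rlang::abort(sprintf("Missing landmark(s): %s", paste(setdiff(pair, have), collapse = ", ")),
      class = "palatwin_geometry_error"
    )
  }
  pts <- lm$points[pair, , drop = FALSE]
  s <- signed_distance(gingival, pts)
  proj <- pts - outer(s, gingival$normal)
  mid <- colMeans(proj)
  normal <- unitize(cross3(gingival$normal, midpalatal$normal))
  palate_plane(normal, sum(normal * mid))
}
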