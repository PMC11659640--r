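# The seven palatal measurements: widths, depths, antero-posterior length,
# and the plane-clipped surface area and volume.

need_landmarks <- function(lm, names) {
  have <- intersect(names, rownames(lm$points))
  if (length(have) < length(names)) {
    rlang::abort(sprintf(
      "Missing landmark(s) required for measurement: %s",
      paste(setdiff(names, have), collapse = ", ")
    ), class = "palatwin_measurement_error")
  }
  lm$points[names, , drop = FALSE]
}

#' Anterior and posterior palatal widths
#'
#' Euclidean distance between the palatal dento-gingival midpoints of the
#' canines (anterior width) and of the terminal molars used at the given
#' stage (posterior width): primary canines/second primary molars in the
#' primary dentition, primary canines/first permanent molars in the mixed,
#' permanent canines/first permanent molars in the permanent dentition.
#'
#' @param lm A (completed) [landmark_set()].
#' @param stage Dentition stage; defaults to the stage of `lm`.
#' @return Tibble with `anterior_width` and `posterior_width` (mm).
#' @export
measure_widths <- function(lm, stage = lm$stage) {
  teeth <- measurement_teeth(stage)
  can <- need_landmarks(lm, teeth$canines)
  mol <- need_landmarks(lm, teeth$molars)
  tibble::tibble(
    anterior_width = vnorm(can[1, ] - can[2, ]),
    posterior_width = vnorm(mol[1, ] - mol[2, ])
  )
}

#' Antero-posterior palatal length
#'
#' Perpendicular distance from the incisive papilla (`raphe_anterior`) to the
#' posterior limit plane.
#'
#' @param lm A [landmark_set()].
#' @param posterior The [posterior_plane()].
#' @return Length in mm.
#' @export
measure_ap_length <- function(lm, posterior) {
  p <- need_landmarks(lm, "raphe_anterior")
  as.numeric(abs(signed_distance(posterior, p)))
}

# Intersection points of mesh edges with a plane (linear interpolation along
# each crossing edge, plus vertices lying on the plane).
mesh_plane_section <- function(mesh, plane, tol = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- unique(rbind(
    cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
    cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
    cbind(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3]))
  ))
  s <- drop(v %*% plane$normal) - plane$offset
  s1 <- s[e[, 1]]
  s2 <- s[e[, 2]]
  cross <- (s1 > tol & s2 < -tol) | (s1 < -tol & s2 > tol)
  pts <- NULL
  if (any(cross)) {
    t <- s1[cross] / (s1[cross] - s2[cross])
    pts <- v[e[cross, 1], , drop = FALSE] +
      t * (v[e[cross, 2], , drop = FALSE] - v[e[cross, 1], , drop = FALSE])
  }
  on_plane <- abs(s) <= tol
  rbind(pts, v[on_plane, , drop = FALSE])
}

point_line_distance <- function(points, origin, direction) {
  u <- unitize(direction)
  d <- sweep(as.matrix(points), 2L, origin)
  along <- drop(d %*% u)
  perp <- d - outer(along, u)
  sqrt(rowSums(perp^2))
}

#' Anterior and posterior palatal depths
#'
#' Depth of the palatal vault at a dental station: the palate surface is
#' sectioned by the transverse plane containing the reference dento-gingival
#' line (canine line for anterior depth, molar line for posterior depth) and
#' the gingival normal; section points within `eps` of the mid-palatal plane
#' (the raphe region) and on the vault side of the gingival plane are the
#' "deepest point" candidates, and the depth is the maximum perpendicular
#' distance from the reference line among them. Sectioning interpolates
#' along mesh edges, so the result is tessellation-independent up to surface
#' curvature.
#'
#' @param lm A (completed) [landmark_set()].
#' @param mesh The cast [palate_mesh()] supplying the vault surface.
#' @param gingival,midpalatal Reference [palate_plane()]s; computed from `lm`
#'   when omitted.
#' @param stage Dentition stage; defaults to the stage of `lm`.
#' @param eps Half-width (mm) of the band around the mid-palatal plane in
#'   which vault candidates are accepted.
#' @return Tibble with `anterior_depth` and `posterior_depth` (mm).
#' @export
measure_depths <- function(lm, mesh, gingival = gingival_plane(lm),
                           midpalatal = midpalatal_plane(lm, gingival),
                           stage = lm$stage, eps = 0.5) {
  teeth <- measurement_teeth(stage)
  depth_at <- function(pair) {
    pts <- need_landmarks(lm, pair)
    origin <- pts[1, ]
    u <- unitize(pts[2, ] - pts[1, ])
    m <- cross3(u, gingival$normal)
    if (vnorm(m) < 1e-9) {
      rlang::abort("Reference line is parallel to the gingival normal.",
        class = "palatwin_measurement_error"
      )
    }
    station <- palate_plane(m, sum(unitize(m) * origin))
    sec <- mesh_plane_section(mesh, station)
    if (is.null(sec) || nrow(sec) == 0L) {
      rlang::abort(
        "No vault section at the reference line; the mesh may not cover this station.",
        class = "palatwin_measurement_error"
      )
    }
    near_raphe <- abs(signed_distance(midpalatal, sec)) <= eps
    vault_side <- gingival$interior * signed_distance(gingival, sec) >= -1e-7
    cand <- sec[near_raphe & vault_side, , drop = FALSE]
    if (nrow(cand) == 0L) {
      rlang::abort(sprintf(
        "Empty vault candidate band at this station; consider increasing eps (currently %.3g mm).",
        eps
      ), class = "palatwin_measurement_error")
    }
    max(point_line_distance(cand, origin, u))
  }
  tibble::tibble(
    anterior_depth = depth_at(teeth$canines),
    posterior_depth = depth_at(teeth$molars)
  )
}

#' Measure the seven palatal traits of one cast
#'
#' Runs the full single-cast pipeline: landmark completion, construction of
#' the gingival, mid-palatal and posterior planes, the two widths, two
#' depths, the antero-posterior length, and the plane-clipped palatal
#' surface area and enclosed volume.
#'
#' @param mesh The cast [palate_mesh()].
#' @param lm The cast's [landmark_set()].
#' @param eps Raphe band half-width for [measure_depths()] (mm).
#' @param clip_tol On-plane tolerance for clipping (mm).
#' @return One-row tibble: `cast_id`, `stage`, the seven traits, and
#'   `n_imputed` (landmarks filled in by completion).
#' @export
measure_palate <- function(mesh, lm, eps = 0.5, clip_tol = 1e-7) {
  lm <- complete_landmarks(lm)
  ging <- gingival_plane(lm)
  mid <- midpalatal_plane(lm, ging)
  post <- posterior_plane(lm, ging, mid)
  widths <- measure_widths(lm)
  depths <- measure_depths(lm, mesh, gingival = ging, midpalatal = mid, eps = eps)
  clipped <- clip_palate(mesh, ging, post, tol = clip_tol)
  tibble::tibble(
    cast_id = lm$cast_id,
    stage = lm$stage,
    anterior_width = widths$anterior_width,
    posterior_width = widths$posterior_width,
    anterior_depth = depths$anterior_depth,
    posterior_depth = depths$posterior_depth,
    ap_length = measure_ap_length(lm, post),
    area = mesh_area(clipped),
    volume = clipped_volume(clipped, ging, post),
    n_imputed = length(lm$imputed)
  )
}
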