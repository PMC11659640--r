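# Rigid (rotation + translation, no scaling) least-squares superimposition of
# landmark configurations, used to impute missing landmarks from mirrored
# antimeres.

#' Rigid Procrustes superimposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum(|| moving %*% R + t - target ||^2)` over matched rows (the Kabsch
#' solution). No scaling is applied.
#'
#' @param moving,target Numeric matrices with matching rows (3 columns).
#' @return List with `rotation` (3x3), `translation` (length 3) and
#'   `transform`, a function applying the map to an n-by-3 matrix.
#' @export
rigid_superimpose <- function(moving, target) {
  moving <- as.matrix(moving)
  target <- as.matrix(target)
  stopifnot(nrow(moving) == nrow(target), ncol(moving) == 3L, ncol(target) == 3L)
  if (nrow(moving) < 3L) {
    rlang::abort("Rigid superimposition needs at least 3 shared landmarks.",
      class = "palatwin_geometry_error"
    )
  }
  cm <- colMeans(moving)
  ct <- colMeans(target)
  M <- crossprod(sweep(moving, 2L, cm), sweep(target, 2L, ct))
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- ct - drop(cm %*% R)
  list(
    rotation = R,
    translation = tr,
    transform = function(x) sweep(as.matrix(x) %*% R, 2L, tr, "+")
  )
}

reflect_points <- function(points, plane) {
  s <- signed_distance(plane, points)
  points - 2 * outer(s, plane$normal)
}

#' Impute missing landmarks by mirroring and Procrustes superimposition
#'
#' Missing bilateral landmarks are reconstructed from their antimeres: the
#' full configuration is reflected across the current mid-sagittal estimate
#' (the mid-palatal plane fitted to the available landmarks), relabelled so
#' every left landmark becomes its right partner and vice versa, rigidly
#' superimposed back onto the original configuration over all shared
#' landmarks (rotation + translation, no scaling), and the missing landmark's
#' coordinates are taken from the superimposed copy. This respects
#' asymmetric casts: the superimposition absorbs any global misalignment of
#' the mirrored copy, so on a perfectly symmetric cast the imputed point is
#' the exact mirror image of its antimere.
#'
#' @param lm A [landmark_set()]; raphe landmarks must be present, and at most
#'   one member of each antimere pair may be missing.
#' @return A completed [landmark_set()] with imputed landmarks flagged in
#'   `$imputed`. If nothing is missing the input is returned unchanged.
#' @export
complete_landmarks <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  missing <- lm$missing
  if (length(missing) == 0L) {
    return(lm)
  }
  partners <- antimere_names(missing)
  both_gone <- missing[!(partners %in% rownames(lm$points))]
  if (length(both_gone) > 0L) {
    rlang::abort(sprintf(
      "Both antimeres missing for: %s",
      paste(sprintf("%s/%s", both_gone, antimere_names(both_gone)), collapse = ", ")
    ), class = "palatwin_completion_error")
  }

  # Mid-sagittal estimate from the available landmarks.
  dg <- grep("^dg_", rownames(lm$points), value = TRUE)
  ging <- fit_plane(lm$points[dg, , drop = FALSE])
  ging <- orient_negative_towards(ging, lm$points["raphe_middle", ])
  ging$interior <- -1
  sagittal <- midpalatal_plane(lm, ging)

  mirrored <- reflect_points(lm$points, sagittal)
  rownames(mirrored) <- antimere_names(rownames(lm$points))

  shared <- intersect(rownames(lm$points), rownames(mirrored))
  fit <- rigid_superimpose(
    mirrored[shared, , drop = FALSE],
    lm$points[shared, , drop = FALSE]
  )
  aligned <- fit$transform(mirrored)

  filled <- rbind(lm$points, aligned[missing, , drop = FALSE])
  rownames(filled) <- c(rownames(lm$points), missing)
  landmark_set(lm$cast_id, lm$stage, filled,
    imputed = union(lm$imputed, missing)
  )
}
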