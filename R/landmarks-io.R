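#' Landmark vocabulary for a dentition stage
#'
#' Landmarks are named with a fixed vocabulary: `dg_<FDI code>` for the
#' palatal dento-gingival midpoint of each tooth, `raphe_anterior` (the
#' incisive papilla), `raphe_middle` and `raphe_posterior` for the mid-palatal
#' raphe, and `distal_<FDI code>` for the most distal palatal points of the
#' terminal teeth. The tooth set depends on the dentition stage: primary uses
#' the deciduous codes 51-55/61-65; the mixed dentition keeps the deciduous
#' canines and molars alongside permanent incisors and first molars; the
#' permanent stage uses 11-16/21-26.
#'
#' @param stage One of `"primary"`, `"mixed"`, `"permanent"`.
#' @return Character vector of the required landmark names for that stage.
#' @export
landmark_vocabulary <- function(stage) {
  stage <- match.arg(stage, c("primary", "mixed", "permanent"))
  teeth <- switch(stage,
    primary = c(51:55, 61:65),
    mixed = c(11, 12, 21, 22, 53, 54, 55, 63, 64, 65, 16, 26),
    permanent = c(11:16, 21:26)
  )
  distal <- switch(stage,
    primary = c(55, 65),
    mixed = c(16, 26),
    permanent = c(16, 26)
  )
  c(
    paste0("dg_", teeth),
    "raphe_anterior", "raphe_middle", "raphe_posterior",
    paste0("distal_", distal)
  )
}

# FDI tooth codes used by the Table-1 measurements at each stage.
measurement_teeth <- function(stage) {
  stage <- match.arg(stage, c("primary", "mixed", "permanent"))
  switch(stage,
    primary = list(canines = c("dg_53", "dg_63"), molars = c("dg_55", "dg_65"),
      distal = c("distal_55", "distal_65")),
    mixed = list(canines = c("dg_53", "dg_63"), molars = c("dg_16", "dg_26"),
      distal = c("distal_16", "distal_26")),
    permanent = list(canines = c("dg_13", "dg_23"), molars = c("dg_16", "dg_26"),
      distal = c("distal_16", "distal_26"))
  )
}

#' The bilateral (antimere) partner of a landmark name
#'
#' FDI quadrants 1/5 are the patient's right, 2/6 the left; mirroring swaps
#' quadrant 1 with 2 and 5 with 6. Raphe landmarks lie on the midline and are
#' their own antimeres.
#'
#' @param names Character vector of landmark names.
#' @return Character vector of partner names.
#' @export
antimere_names <- function(names) {
  vapply(names, function(nm) {
    if (startsWith(nm, "raphe_")) {
      return(nm)
    }
    m <- regmatches(nm, regexec("^(dg|distal)_([1256])([0-9])$", nm))[[1]]
    if (length(m) == 0L) {
      rlang::abort(sprintf("Unrecognized landmark name: %s", nm),
        class = "palatwin_format_error"
      )
    }
    q <- c("1" = "2", "2" = "1", "5" = "6", "6" = "5")[m[3]]
    paste0(m[2], "_", q, m[4])
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a validated landmark set
#'
#' @param cast_id Identifier for the cast.
#' @param stage Dentition stage, `"primary"`, `"mixed"` or `"permanent"`.
#' @param points Numeric matrix with 3 columns and landmark names as row
#'   names, or a named list of length-3 numeric vectors. Coordinates in mm.
#' @param imputed Character vector of names that were filled in by
#'   [complete_landmarks()] rather than digitized.
#' @return A `landmark_set`: list with `cast_id`, `stage`, `points` (matrix),
#'   `imputed`, and `missing` (required names absent from `points`). Missing
#'   landmarks are data, not an error; downstream completion handles them.
#' @export
landmark_set <- function(cast_id, stage, points, imputed = character()) {
  stage <- match.arg(stage, c("primary", "mixed", "permanent"))
  if (is.list(points)) {
    nms <- names(points)
    points <- do.call(rbind, lapply(points, as.numeric))
    rownames(points) <- nms
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) > 0L && (ncol(points) != 3L || is.null(rownames(points)))) {
    rlang::abort("`points` must have 3 columns and landmark names as row names.",
      class = "palatwin_format_error"
    )
  }
  if (!all(is.finite(points))) {
    rlang::abort("All landmark coordinates must be finite.",
      class = "palatwin_format_error"
    )
  }
  nms <- rownames(points)
  if (anyDuplicated(nms)) {
    rlang::abort(sprintf(
      "Duplicate landmark name(s): %s",
      paste(unique(nms[duplicated(nms)]), collapse = ", ")
    ), class = "palatwin_format_error")
  }
  vocab <- landmark_vocabulary(stage)
  unknown <- setdiff(nms, vocab)
  if (length(unknown) > 0L) {
    rlang::abort(sprintf(
      "Unknown landmark name(s) for stage '%s': %s",
      stage, paste(unknown, collapse = ", ")
    ), class = "palatwin_format_error")
  }
  structure(
    list(
      cast_id = as.character(cast_id),
      stage = stage,
      points = points,
      imputed = intersect(imputed, nms),
      missing = setdiff(vocab, nms)
    ),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(
    "<landmark_set '%s' (%s): %d landmarks%s%s>\n",
    x$cast_id, x$stage, nrow(x$points),
    if (length(x$missing)) paste0(", missing: ", paste(x$missing, collapse = ", ")) else "",
    if (length(x$imputed)) paste0(", imputed: ", paste(x$imputed, collapse = ", ")) else ""
  ))
  invisible(x)
}

#' Read a landmark set from JSON
#'
#' The document must contain `cast_id`, `stage` and a `points` object mapping
#' landmark names to `[x, y, z]` coordinate triples (mm). Names outside the
#' stage vocabulary are rejected; required names simply absent are recorded
#' as missing.
#'
#' @param path Path to a JSON landmark file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
    error = function(e) {
      rlang::abort(sprintf("Malformed landmark JSON %s: %s", path, conditionMessage(e)),
        class = "palatwin_format_error"
      )
    }
  )
  for (field in c("cast_id", "stage", "points")) {
    if (is.null(doc[[field]])) {
      rlang::abort(sprintf("Landmark file %s lacks field '%s'.", path, field),
        class = "palatwin_format_error"
      )
    }
  }
  if (!doc$stage %in% c("primary", "mixed", "permanent")) {
    rlang::abort(sprintf("Unknown stage '%s' in %s.", doc$stage, path),
      class = "palatwin_format_error"
    )
  }
  pts <- lapply(doc$points, function(p) {
    p <- unlist(p)
    if (length(p) != 3L || !is.numeric(p) || any(!is.finite(p))) {
      rlang::abort(sprintf("Non-numeric or malformed coordinate in %s.", path),
        class = "palatwin_format_error"
      )
    }
    as.numeric(p)
  })
  landmark_set(doc$cast_id, doc$stage, pts,
    imputed = unlist(doc$imputed) %||% character()
  )
}

#' Write a landmark set to JSON
#'
#' @param lm A [landmark_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  pts <- lapply(seq_len(nrow(lm$points)), function(i) as.numeric(lm$points[i, ]))
  names(pts) <- rownames(lm$points)
  doc <- list(
    cast_id = lm$cast_id, stage = lm$stage, points = pts,
    imputed = as.list(lm$imputed)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
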