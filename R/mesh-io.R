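#' Triangle mesh objects
#'
#' A `palate_mesh` is a minimal triangle-mesh container: a numeric matrix of
#' vertex coordinates in millimetres and an integer matrix of 1-based triangle
#' vertex indices. Degenerate (zero-area) triangles are dropped at
#' construction with a message, since they carry no surface and break
#' clipping.
#'
#' @param vertices Numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces Integer matrix, one row per triangle, three vertex indices.
#' @param degenerate_tol Triangles with area below this (mm^2) are dropped.
#' @return An object of class `palate_mesh` with elements `vertices` and
#'   `faces`.
#' @export
palate_mesh <- function(vertices, faces, degenerate_tol = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L || !all(is.finite(vertices))) {
    rlang::abort("`vertices` must be a finite numeric matrix with 3 columns.",
      class = "palatwin_format_error"
    )
  }
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) {
    rlang::abort("`faces` must have 3 columns.", class = "palatwin_format_error")
  }
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    rlang::abort("Face indices out of range.", class = "palatwin_format_error")
  }
  if (nrow(faces) > 0L) {
    areas <- face_areas(vertices, faces)
    bad <- areas <= degenerate_tol
    if (any(bad)) {
      message(sprintf("Dropped %d degenerate (zero-area) triangle(s).", sum(bad)))
      faces <- faces[!bad, , drop = FALSE]
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "palate_mesh")
}

#' @export
print.palate_mesh <- function(x, ...) {
  cat(sprintf(
    "<palate_mesh: %d vertices, %d triangles>\n",
    nrow(x$vertices), nrow(x$faces)
  ))
  invisible(x)
}

# Weld vertices that are bitwise identical (STL stores one vertex copy per
# incident triangle).
weld_vertices <- function(vertices, faces) {
  key <- paste(vertices[, 1], vertices[, 2], vertices[, 3], sep = "|")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  new_vertices <- vertices[first, , drop = FALSE]
  new_faces <- matrix(idx[faces], ncol = 3L)
  list(vertices = new_vertices, faces = new_faces)
}

#' Read a triangle mesh from an STL file
#'
#' Both binary and ASCII STL encodings are supported; the encoding is
#' detected from the file itself (the 80-byte header of a binary STL may
#' legitimately start with "solid", so detection uses the record layout, not
#' the header text). Duplicate vertex records are welded and zero-area
#' triangles dropped.
#'
#' @param path Path to an `.stl` file. Coordinates are taken to be mm.
#' @return A [palate_mesh()].
#' @export
read_palate_mesh <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("STL file does not exist: %s", path),
      class = "palatwin_format_error"
    )
  }
  size <- file.info(path)$size
  if (is.na(size) || size == 0) {
    rlang::abort(sprintf("STL file is empty: %s", path),
      class = "palatwin_format_error"
    )
  }
  is_binary <- FALSE
  if (size >= 84) {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    invisible(readBin(con, "raw", 80L))
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(ntri) == 1L && !is.na(ntri) && size == 84 + 50 * as.numeric(ntri)) {
      is_binary <- TRUE
      rec <- readBin(con, "raw", 50L * ntri)
    }
  }
  if (is_binary) {
    if (ntri == 0L) {
      rlang::abort(sprintf("STL file contains no triangles: %s", path),
        class = "palatwin_format_error"
      )
    }
    m <- matrix(rec, nrow = 50L)
    coords <- readBin(as.vector(m[1:48, ]), "double",
      n = 12L * ntri, size = 4L, endian = "little"
    )
    tri <- matrix(coords, nrow = 12L) # normal (3) + 3 vertices (9) per column
    verts <- matrix(as.vector(tri[4:12, ]), ncol = 3L, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
      rlang::abort(sprintf("Not a parseable ASCII STL file: %s", path),
        class = "palatwin_format_error"
      )
    }
    nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(f) as.numeric(f[2:4]))
    verts <- do.call(rbind, nums)
    if (any(!is.finite(verts))) {
      rlang::abort(sprintf("Non-numeric vertex coordinate in %s", path),
        class = "palatwin_format_error"
      )
    }
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  w <- weld_vertices(verts, faces)
  palate_mesh(w$vertices, w$faces)
}

#' Write a triangle mesh to an STL file
#'
#' @param mesh A [palate_mesh()].
#' @param path Output path.
#' @param format `"ascii"` (default) or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_palate_mesh <- function(mesh, path, format = c("ascii", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "palate_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  av <- face_area_vectors(v, f)
  nrm <- av / pmax(sqrt(rowSums(av^2)), 1e-30)
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines("solid palatwin", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf(
        "  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]
      ), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- v[f[i, j], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid palatwin", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    header <- charToRaw(formatC("palatwin binary STL", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], t(v[f[i, ], ]))), con,
        size = 4L, endian = "little"
      )
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}
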