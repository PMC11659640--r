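# Small internal helpers shared across modules.

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) {
    rlang::abort("Cannot normalize a (near-)zero vector.", class = "palatwin_geometry_error")
  }
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Area vectors (0.5 * cross product) for every face of a mesh; rows of the
# result are the per-triangle area-weighted normals.
face_area_vectors <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  0.5 * cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
}

face_areas <- function(vertices, faces) {
  av <- face_area_vectors(vertices, faces)
  sqrt(rowSums(av^2))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

# Deterministic integer sub-seed derived from a master seed, kept < 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1009L + as.integer(k) * 9973L) %% 2147483647L
}
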