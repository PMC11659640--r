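# Plane clipping of triangle meshes and area/volume of the clipped palate.

# Clip a mesh to the interior half-space of an oriented plane. Triangles
# entirely interior are kept, straddling triangles are split along the
# plane, exterior ones dropped. Vertices within `tol` of the plane count as
# interior, which avoids sliver triangles. Intersection vertices are computed
# once per (canonically ordered) edge so that adjacent triangles share
# bitwise-identical cut points and the cut boundary stays closed.
clip_mesh_plane <- function(mesh, plane, tol = 1e-7) {
  if (is.na(plane$interior)) {
    rlang::abort("Clipping plane has no interior orientation tag.",
      class = "palatwin_geometry_error"
    )
  }
  v <- mesh$vertices
  f <- mesh$faces
  # interior signed distance: positive inside
  s <- plane$interior * (drop(v %*% plane$normal) - plane$offset)
  inside <- s >= -tol

  new_vertices <- list()
  n_old <- nrow(v)
  edge_cache <- new.env(parent = emptyenv())
  cut_point <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    idx <- edge_cache[[key]]
    if (!is.null(idx)) {
      return(idx)
    }
    a <- if (i < j) i else j
    b <- if (i < j) j else i
    t <- s[a] / (s[a] - s[b])
    p <- v[a, ] + t * (v[b, ] - v[a, ])
    new_vertices[[length(new_vertices) + 1L]] <<- p
    idx <- n_old + length(new_vertices)
    edge_cache[[key]] <- idx
    idx
  }

  out_faces <- vector("list", nrow(f))
  for (k in seq_len(nrow(f))) {
    tri <- f[k, ]
    ins <- inside[tri]
    n_in <- sum(ins)
    if (n_in == 3L) {
      out_faces[[k]] <- tri
    } else if (n_in == 0L) {
      next
    } else {
      # rotate so pattern starts at a canonical vertex
      ord <- if (n_in == 1L) which(ins) else which(!ins)
      idx <- ((ord - 1L + 0:2) %% 3L) + 1L
      a <- tri[idx[1]]
      b <- tri[idx[2]]
      cc <- tri[idx[3]]
      if (n_in == 1L) {
        # a inside, b and c outside -> one triangle
        pab <- cut_point(a, b)
        pca <- cut_point(cc, a)
        out_faces[[k]] <- c(a, pab, pca)
      } else {
        # a outside, b and c inside -> quad (pab, b, c, pca) -> two triangles
        pab <- cut_point(a, b)
        pca <- cut_point(cc, a)
        out_faces[[k]] <- rbind(c(pab, b, cc), c(pab, cc, pca))
      }
    }
  }
  faces <- do.call(rbind, out_faces)
  if (is.null(faces) || nrow(faces) == 0L) {
    rlang::abort("Clipping removed the whole mesh.",
      class = "palatwin_geometry_error"
    )
  }
  vertices <- rbind(v, do.call(rbind, new_vertices))
  # drop unreferenced vertices
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(vertices))
  remap[used] <- seq_along(used)
  structure(
    list(vertices = vertices[used, , drop = FALSE],
      faces = matrix(remap[faces], ncol = 3L)),
    class = "palate_mesh"
  )
}

#' Clip a palate mesh to the region enclosed by two planes
#'
#' Keeps the part of the surface inside the intersection of the interior
#' half-spaces of the gingival and posterior planes. Straddling triangles are
#' split at the planes; the open boundary edges produced by the cut are
#' recorded in the `boundary` attribute (an n-by-2 matrix of directed vertex
#' indices).
#'
#' @param mesh A [palate_mesh()].
#' @param gingival,posterior Oriented [palate_plane()]s with interior tags.
#' @param tol On-plane classification tolerance (mm).
#' @return The clipped [palate_mesh()] with a `boundary` attribute.
#' @export
clip_palate <- function(mesh, gingival, posterior, tol = 1e-7) {
  out <- clip_mesh_plane(mesh, gingival, tol = tol)
  out <- clip_mesh_plane(out, posterior, tol = tol)
  attr(out, "boundary") <- boundary_edges(out)
  out
}

#' Directed boundary edges of a triangle mesh
#'
#' Edges used by exactly one triangle, in that triangle's winding order.
#'
#' @param mesh A [palate_mesh()].
#' @return Integer matrix with columns `from`, `to`.
#' @export
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  b <- e[cnt[key] == 1L, , drop = FALSE]
  colnames(b) <- c("from", "to")
  b
}

#' Surface area of a mesh
#'
#' Sum of triangle areas; for a clipped palate this is the vault surface
#' only — the planar caps closing the boundary are deliberately excluded
#' (the palatal surface area, not the area of a closed solid).
#'
#' @param mesh A [palate_mesh()].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0L) {
    return(0)
  }
  sum(face_areas(mesh$vertices, mesh$faces))
}

#' Volume enclosed by a clipped surface and its clipping planes
#'
#' Closes the clipped vault surface with planar caps on the gingival and
#' posterior planes and evaluates the signed volume of the resulting
#' watertight solid by the divergence theorem. The caps are formed by
#' fanning every open boundary edge from a single apex point lying on the
#' clipping plane(s) — a point on the intersection line of the two planes
#' when the boundary touches both, so both caps remain planar. Every
#' boundary vertex must lie on one of the clipping planes (within `tol`);
#' otherwise the surface cannot be closed and an error is raised.
#'
#' @param mesh A clipped [palate_mesh()] (e.g. from [clip_palate()]).
#' @param gingival,posterior The clipping [palate_plane()]s.
#' @param tol Distance tolerance (mm) for classifying boundary vertices as
#'   on-plane.
#' @return Volume in mm^3 (absolute value).
#' @export
clipped_volume <- function(mesh, gingival, posterior, tol = 1e-5) {
  v <- mesh$vertices
  f <- mesh$faces
  vol6 <- sum(
    v[f[, 1], 1] * (v[f[, 2], 2] * v[f[, 3], 3] - v[f[, 2], 3] * v[f[, 3], 2]) -
      v[f[, 1], 2] * (v[f[, 2], 1] * v[f[, 3], 3] - v[f[, 2], 3] * v[f[, 3], 1]) +
      v[f[, 1], 3] * (v[f[, 2], 1] * v[f[, 3], 2] - v[f[, 2], 2] * v[f[, 3], 1])
  )
  b <- attr(mesh, "boundary")
  if (is.null(b)) b <- boundary_edges(mesh)
  if (nrow(b) > 0L) {
    bv <- sort(unique(as.vector(b)))
    s1 <- abs(signed_distance(gingival, v[bv, , drop = FALSE]))
    s2 <- abs(signed_distance(posterior, v[bv, , drop = FALSE]))
    if (any(pmin(s1, s2) > tol)) {
      rlang::abort(
        "Boundary is not closable: some boundary vertices lie on neither clipping plane.",
        class = "palatwin_geometry_error"
      )
    }
    on1 <- any(s1 <= tol & s2 > tol)
    on2 <- any(s2 <= tol & s1 > tol)
    if (on1 && on2) {
      # apex on the intersection line of the two planes (minimum-norm point
      # shifted to the boundary centroid for conditioning)
      n1 <- gingival$normal
      n2 <- posterior$normal
      u <- cross3(n1, n2)
      if (vnorm(u) < 1e-8) {
        rlang::abort("Clipping planes are parallel; cannot close caps.",
          class = "palatwin_geometry_error"
        )
      }
      A <- rbind(n1, n2)
      d <- c(gingival$offset, posterior$offset)
      c0 <- drop(t(A) %*% solve(A %*% t(A), d))
      u <- unitize(u)
      ctr <- colMeans(v[bv, , drop = FALSE])
      apex <- c0 + sum((ctr - c0) * u) * u
    } else {
      pl <- if (on2 && !on1) posterior else gingival
      ctr <- colMeans(v[bv, , drop = FALSE])
      apex <- ctr - signed_distance(pl, ctr) * pl$normal
    }
    # cap triangles (to, from, apex) close each boundary edge (from -> to)
    a <- v[b[, 2], , drop = FALSE]
    bb <- v[b[, 1], , drop = FALSE]
    vol6 <- vol6 + sum(
      a[, 1] * (bb[, 2] * apex[3] - bb[, 3] * apex[2]) -
        a[, 2] * (bb[, 1] * apex[3] - bb[, 3] * apex[1]) +
        a[, 3] * (bb[, 1] * apex[2] - bb[, 2] * apex[1])
    )
  }
  abs(vol6) / 6
}
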