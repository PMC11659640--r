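far_plane <- function() palate_plane(c(0, 1, 0), 1e3, interior = -1)

test_that("clipping a sphere at the equator yields a hemisphere", {
  s <- uv_sphere(80)
  keep_low <- palate_plane(c(0, 0, 1), 0, interior = -1)
  cl <- clip_palate(s, keep_low, far_plane())
  expect_lte(max(cl$vertices[, 3]), 1e-7)
  expect_equal(mesh_area(cl), 2 * pi, tolerance = 0.01)
  expect_equal(clipped_volume(cl, keep_low, far_plane()), 2 * pi / 3, tolerance = 0.01)
})

test_that("a fully interior mesh passes through clipping unchanged", {
  cube <- cube_mesh()
  pl <- palate_plane(c(0, 0, 1), 5, interior = -1)
  out <- clip_palate(cube, pl, far_plane())
  expect_equal(out$vertices, cube$vertices)
  expect_equal(out$faces, cube$faces)
  expect_equal(nrow(attr(out, "boundary")), 0L)
  # closed solid: divergence-theorem volume with no caps
  expect_equal(clipped_volume(out, pl, far_plane()), 1, tolerance = 1e-12)
})

test_that("cube clipped by a diagonal plane matches the polygon-clipping oracle", {
  cube <- cube_mesh()
  diag_pl <- palate_plane(c(1, 0, 1), 1 / sqrt(2), interior = -1) # keep x + z <= 1
  cl <- clip_palate(cube, diag_pl, far_plane())
  expect_true(all(signed_distance(diag_pl, cl$vertices) <= 1e-7))

  # oracle: Sutherland-Hodgman clip of each triangle, independent code path
  clip_tri_area <- function(tri, n, d) {
    poly <- tri
    out <- list()
    for (i in seq_len(nrow(poly))) {
      a <- poly[i, ]
      b <- poly[i %% nrow(poly) + 1, ]
      sa <- sum(a * n) - d
      sb <- sum(b * n) - d
      if (sa <= 0) out[[length(out) + 1]] <- a
      if ((sa < 0) != (sb < 0) && sa != sb) {
        out[[length(out) + 1]] <- a + (sa / (sa - sb)) * (b - a)
      }
    }
    if (length(out) < 3) {
      return(0)
    }
    p <- do.call(rbind, out)
    av <- c(0, 0, 0)
    for (i in 2:(nrow(p) - 1)) {
      av <- av + 0.5 * cross_prod(p[i, ] - p[1, ], p[i + 1, ] - p[1, ])
    }
    sqrt(sum(av^2))
  }
  cross_prod <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  }
  oracle_area <- sum(vapply(seq_len(nrow(cube$faces)), function(i) {
    clip_tri_area(cube$vertices[cube$faces[i, ], ], c(1, 0, 1) / sqrt(2), 1 / sqrt(2))
  }, numeric(1)))
  expect_equal(mesh_area(cl), oracle_area, tolerance = 1e-9)

  # volume below x + z <= 1 in the unit cube is 1 - 1/2
  expect_equal(clipped_volume(cl, diag_pl, far_plane()), 0.5, tolerance = 1e-9)
})

test_that("half-ellipsoid volume matches the closed form at fine tessellation", {
  a <- 13.7
  b <- 12.65
  cc <- 10.6
  ell <- uv_ellipsoid(90, a, b, cc)
  keep_up <- palate_plane(c(0, 0, 1), 0, interior = 1) # keep z >= 0
  far <- palate_plane(c(0, 1, 0), 1e3, interior = -1)
  cl <- clip_palate(ell, keep_up, far)
  expect_equal(clipped_volume(cl, keep_up, far), (2 / 3) * pi * a * b * cc,
    tolerance = 0.01
  )
})

test_that("clipping everything away raises a geometry error", {
  cube <- cube_mesh()
  pl <- palate_plane(c(0, 0, 1), -5, interior = -1)
  expect_error(clip_palate(cube, pl, far_plane()), class = "palatwin_geometry_error")
})

test_that("area and volume follow rigid and scaling laws on closed solids", {
  cube <- cube_mesh()
  pl_in <- palate_plane(c(0, 0, 1), 5, interior = -1)
  for (seed in 1:3) {
    R <- random_rotation(seed)
    tr <- c(seed, -2 * seed, 0.5)
    m <- cube
    m$vertices <- sweep(m$vertices %*% R, 2, tr, "+")
    expect_equal(mesh_area(m), mesh_area(cube), tolerance = 1e-12)
    s <- 1 + seed / 2
    ms <- cube
    ms$vertices <- ms$vertices * s
    expect_equal(mesh_area(ms), s^2 * mesh_area(cube), tolerance = 1e-12)
    pls <- palate_plane(c(0, 0, 1), 5 * s, interior = -1)
    expect_equal(clipped_volume(ms, pls, far_plane()), s^3, tolerance = 1e-12)
  }
})
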