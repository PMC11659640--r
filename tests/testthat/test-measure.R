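test_that("widths are Euclidean dento-gingival distances per stage", {
  g <- generate_palate()
  w <- measure_widths(g$landmarks)
  expect_equal(w$anterior_width, 22.1, tolerance = 1e-9)
  expect_equal(w$posterior_width, 27.4, tolerance = 1e-9)

  # rigid invariance
  R <- random_rotation(3)
  tc <- transform_cast(g$mesh, g$landmarks, R, c(-2, 4, 9))
  w2 <- measure_widths(tc$landmarks)
  expect_equal(w2$anterior_width, w$anterior_width, tolerance = 1e-9)
  expect_equal(w2$posterior_width, w$posterior_width, tolerance = 1e-9)

  # coincident antimeres give zero width
  pts <- g$landmarks$points
  pts["dg_53", ] <- pts["dg_63", ]
  lm0 <- landmark_set("c", "primary", pts)
  expect_equal(measure_widths(lm0)$anterior_width, 0)

  # the permanent stage uses permanent canine/molar codes
  gp <- generate_palate(stage = "permanent")
  expect_equal(measure_widths(gp$landmarks)$anterior_width, 22.1, tolerance = 1e-9)
})

test_that("antero-posterior length is the papilla-to-posterior-plane distance", {
  pl <- palate_plane(c(0, 1, 0), -25, interior = -1)
  lm <- landmark_set("c", "primary", rbind(raphe_anterior = c(0, 0.3, 0)))
  expect_equal(measure_ap_length(lm, pl), 25.3)
  lm_on <- landmark_set("c", "primary", rbind(raphe_anterior = c(4, -25, 7)))
  expect_equal(measure_ap_length(lm_on, pl), 0)
  # translating the papilla within the plane's tangent directions changes nothing
  lm_t <- landmark_set("c", "primary", rbind(raphe_anterior = c(12, 0.3, -5)))
  expect_equal(measure_ap_length(lm_t, pl), 25.3)
})

test_that("depth of a half-cylinder under the reference line equals its radius", {
  # half-cylinder of radius 10 whose axis is the canine line
  yc <- 17
  th <- seq(0, pi, length.out = 121)
  xs <- seq(-15, 15, by = 0.25)
  verts <- as.matrix(expand.grid(t = th, x = xs))
  verts <- cbind(verts[, 2], yc + 10 * cos(verts[, 1]), -10 * sin(verts[, 1]))
  n_t <- length(th)
  n_x <- length(xs)
  idx <- function(i, j) (i - 1L) * n_t + j
  faces <- list()
  for (i in seq_len(n_x - 1)) {
    j <- seq_len(n_t - 1)
    faces[[i]] <- rbind(
      cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
      cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    )
  }
  mesh <- palate_mesh(verts, do.call(rbind, faces))
  lm <- landmark_set("cyl", "primary", rbind(
    dg_53 = c(-11, yc, 0), dg_63 = c(11, yc, 0),
    dg_55 = c(-13, yc, 0), dg_65 = c(13, yc, 0)
  ))
  ging <- palate_plane(c(0, 0, 1), 0, interior = -1) # vault below z = 0
  mid <- palate_plane(c(1, 0, 0), 0)
  d <- measure_depths(lm, mesh, gingival = ging, midpalatal = mid)
  expect_equal(d$anterior_depth, 10, tolerance = 1e-3)
  expect_equal(d$posterior_depth, 10, tolerance = 1e-3)
})

test_that("a flat palate has zero depth and an empty band suggests larger eps", {
  xs <- seq(-15, 15, by = 1)
  ys <- seq(0, 30, by = 1)
  verts <- as.matrix(expand.grid(x = xs, y = ys))
  verts <- cbind(verts, 0)
  nx <- length(xs)
  ny <- length(ys)
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- list()
  for (j in seq_len(ny - 1)) {
    i <- seq_len(nx - 1)
    faces[[j]] <- rbind(
      cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
      cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    )
  }
  mesh <- palate_mesh(verts, do.call(rbind, faces))
  lm <- landmark_set("flat", "primary", rbind(
    dg_53 = c(-11, 20, 0), dg_63 = c(11, 20, 0),
    dg_55 = c(-13, 5, 0), dg_65 = c(13, 5, 0)
  ))
  ging <- palate_plane(c(0, 0, 1), 0, interior = -1)
  mid <- palate_plane(c(1, 0, 0), 0)
  d <- measure_depths(lm, mesh, gingival = ging, midpalatal = mid)
  expect_equal(d$anterior_depth, 0, tolerance = 1e-9)
  expect_equal(d$posterior_depth, 0, tolerance = 1e-9)

  # station outside the mesh -> no section
  lm_out <- landmark_set("flat", "primary", rbind(
    dg_53 = c(-11, 50, 0), dg_63 = c(11, 50, 0),
    dg_55 = c(-13, 5, 0), dg_65 = c(13, 5, 0)
  ))
  expect_error(
    measure_depths(lm_out, mesh, gingival = ging, midpalatal = mid),
    class = "palatwin_measurement_error"
  )
})

test_that("all seven measurements are rigid-motion invariant and scale by law", {
  g <- generate_palate(palate_shape(edge_length = 0.8))
  base <- measure_palate(g$mesh, g$landmarks)
  R <- random_rotation(11)
  tc <- transform_cast(g$mesh, g$landmarks, R, c(13, -40, 8))
  moved <- measure_palate(tc$mesh, tc$landmarks)
  lin <- c("anterior_width", "posterior_width", "anterior_depth", "posterior_depth", "ap_length")
  for (tr in lin) expect_equal(moved[[tr]], base[[tr]], tolerance = 1e-6)
  expect_equal(moved$area, base$area, tolerance = 1e-4)
  expect_equal(moved$volume, base$volume, tolerance = 1e-4)

  s <- 1.7
  mesh_s <- g$mesh
  mesh_s$vertices <- mesh_s$vertices * s
  lm_s <- landmark_set(
    g$landmarks$cast_id, g$landmarks$stage, g$landmarks$points * s
  )
  scaled <- measure_palate(mesh_s, lm_s)
  for (tr in lin) expect_equal(scaled[[tr]], s * base[[tr]], tolerance = 1e-8)
  expect_equal(scaled$area, s^2 * base$area, tolerance = 1e-7 * base$area)
  expect_equal(scaled$volume, s^3 * base$volume, tolerance = 1e-7 * base$volume)
})
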