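test_that("fit_plane recovers exact coplanar configurations", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  pl <- fit_plane(pts)
  expect_equal(pl$normal, c(0, 0, 1))
  expect_equal(pl$offset, 0)

  pts2 <- rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(1, 1, 1))
  pl2 <- fit_plane(pts2)
  expect_equal(pl2$normal, rep(1 / sqrt(3), 3), tolerance = 1e-12)
  expect_equal(pl2$offset, sqrt(3), tolerance = 1e-12)

  expect_error(fit_plane(cbind(1:5, 1:5, 1:5)), class = "palatwin_geometry_error")
})

test_that("fit_plane matches a brute-force search over gridded normals", {
  set.seed(42)
  pts <- cbind(runif(20, -5, 5), runif(20, -5, 5), rnorm(20, 0, 0.3))
  pl <- fit_plane(pts)
  ssq <- function(n, pts) {
    n <- n / sqrt(sum(n^2))
    ctr <- colMeans(pts)
    sum((sweep(pts, 2, ctr) %*% n)^2)
  }
  # spherical grid oracle
  best <- Inf
  for (th in seq(0, pi, length.out = 181)) {
    for (ph in seq(0, pi, length.out = 181)) {
      n <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      best <- min(best, ssq(n, pts))
    }
  }
  expect_lte(ssq(pl$normal, pts), best + 1e-6)
})

test_that("gingival plane is recovered and rotates equivariantly", {
  g <- generate_palate()
  lm <- g$landmarks
  ging <- gingival_plane(lm)
  # generator builds the dento-gingival ring on z = 0 with the vault above
  expect_equal(abs(ging$normal[3]), 1, tolerance = 1e-9)
  expect_equal(ging$offset * sign(ging$normal[3]), 0, tolerance = 1e-9)
  # interior signed distance of the vault apex is positive
  apex <- lm$points["raphe_middle", ]
  expect_gt(ging$interior * (sum(ging$normal * apex) - ging$offset), 0)

  R <- random_rotation(7)
  tc <- transform_cast(g$mesh, lm, R, c(5, -3, 2))
  ging2 <- gingival_plane(tc$landmarks)
  expect_equal(abs(sum(ging2$normal * (ging$normal %*% R))), 1, tolerance = 1e-9)
})

test_that("mid-palatal plane contains the projected raphe line and is orthogonal", {
  lm <- landmark_set("c", "primary", rbind(
    dg_53 = c(-11, 5, 0.2), dg_63 = c(11, 5, -0.2),
    dg_54 = c(-12, 2.5, 0), dg_64 = c(12, 2.5, 0),
    dg_52 = c(-8, 7, 0), dg_62 = c(8, 7, 0),
    dg_55 = c(-13, 0, 0), dg_65 = c(13, 0, 0),
    dg_51 = c(-3, 9, 0), dg_61 = c(3, 9, 0),
    raphe_anterior = c(0, 10, 0), raphe_middle = c(0, 5, 2), raphe_posterior = c(0, 0, 3)
  ))
  ging <- gingival_plane(lm)
  mid <- midpalatal_plane(lm, ging)
  expect_lt(abs(sum(mid$normal * ging$normal)), 1e-9)
  # raphe points on the x = 0 plane; with near-z gingival normal the
  # mid-palatal plane should be near x = 0
  expect_equal(abs(mid$normal[1]), 1, tolerance = 1e-2)

  degen <- landmark_set("c", "primary", rbind(
    dg_53 = c(-11, 5, 0), dg_63 = c(11, 5, 0), dg_55 = c(-13, 0, 0), dg_65 = c(13, 0, 0),
    raphe_anterior = c(0, 5, 1), raphe_middle = c(0, 5, 1), raphe_posterior = c(0, 5, 1)
  ))
  g2 <- fit_plane(degen$points[1:4, ])
  g2$interior <- -1
  expect_error(midpalatal_plane(degen, g2), class = "palatwin_geometry_error")
})

test_that("posterior plane passes through the distal midpoint, orthogonal to both", {
  lm <- landmark_set("c", "primary", rbind(
    dg_53 = c(-11, -5, 0), dg_63 = c(11, -5, 0),
    dg_54 = c(-12, -12, 0), dg_64 = c(12, -12, 0),
    dg_52 = c(-8, -2, 0), dg_62 = c(8, -2, 0),
    dg_55 = c(-13, -20, 0), dg_65 = c(13, -20, 0),
    dg_51 = c(-3, 0, 0), dg_61 = c(3, 0, 0),
    raphe_anterior = c(0, 0.3, 0), raphe_middle = c(0, -5, 4), raphe_posterior = c(0, -20, 5),
    distal_55 = c(-14, -25, -2), distal_65 = c(14, -25, -2)
  ))
  ging <- gingival_plane(lm)
  mid <- midpalatal_plane(lm, ging)
  post <- posterior_plane(lm, ging, mid)
  expect_lt(abs(sum(post$normal * ging$normal)), 1e-9)
  expect_lt(abs(sum(post$normal * mid$normal)), 1e-9)
  expect_equal(abs(post$normal[2]), 1, tolerance = 1e-9)
  expect_equal(post$offset / post$normal[2], -25, tolerance = 1e-9)
  # anterior side (papilla) is interior
  s <- sum(post$normal * lm$points["raphe_anterior", ]) - post$offset
  expect_gt(post$interior * s, 0)

  # synthetic cast: plane offset within 0.1 mm of the generator's posterior limit
  g <- generate_palate()
  lm2 <- g$landmarks
  ging2 <- gingival_plane(lm2)
  mid2 <- midpalatal_plane(lm2, ging2)
  post2 <- posterior_plane(lm2, ging2, mid2)
  expect_lt(abs(signed_distance(post2, c(0, 0, 0))), 0.1)
})
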