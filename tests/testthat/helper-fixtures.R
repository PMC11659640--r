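# Programmatic fixtures: analytic meshes and small twin datasets.

# Unit cube [0,1]^3 as 12 consistently outward-oriented triangles.
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5), # x = 0
    c(2, 8, 4), c(2, 6, 8), # x = 1
    c(1, 5, 6), c(1, 6, 2), # y = 0
    c(3, 4, 8), c(3, 8, 7), # y = 1
    c(1, 2, 4), c(1, 4, 3), # z = 0
    c(5, 7, 8), c(5, 8, 6) # z = 1
  )
  palate_mesh(v, f)
}

# Longitude/latitude sphere of radius r, consistently oriented.
uv_sphere <- function(n, r = 1) {
  th <- seq(0, pi, length.out = n + 1)
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[-1]
  m <- length(ph)
  verts <- rbind(c(0, 0, r), c(0, 0, -r))
  ring_idx <- vector("list", n)
  for (i in 2:n) {
    ring <- cbind(r * sin(th[i]) * cos(ph), r * sin(th[i]) * sin(ph), r * cos(th[i]))
    ring_idx[[i]] <- nrow(verts) + seq_len(m)
    verts <- rbind(verts, ring)
  }
  nxt <- function(j) j %% m + 1
  faces <- list()
  for (j in 1:m) faces[[length(faces) + 1]] <- c(1, ring_idx[[2]][j], ring_idx[[2]][nxt(j)])
  for (i in 2:(n - 1)) {
    for (j in 1:m) {
      a <- ring_idx[[i]][j]
      b <- ring_idx[[i]][nxt(j)]
      cc <- ring_idx[[i + 1]][j]
      dd <- ring_idx[[i + 1]][nxt(j)]
      faces[[length(faces) + 1]] <- c(a, cc, dd)
      faces[[length(faces) + 1]] <- c(a, dd, b)
    }
  }
  for (j in 1:m) faces[[length(faces) + 1]] <- c(2, ring_idx[[n]][nxt(j)], ring_idx[[n]][j])
  palate_mesh(verts, do.call(rbind, faces))
}

# Ellipsoid with semi-axes (a, b, c): anisotropically scaled sphere.
uv_ellipsoid <- function(n, a, b, c) {
  s <- uv_sphere(n, r = 1)
  s$vertices <- sweep(s$vertices, 2L, c(a, b, c), "*")
  s
}

random_rotation <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

transform_cast <- function(mesh, lm, R, tr) {
  mesh$vertices <- sweep(mesh$vertices %*% R, 2L, tr, "+")
  pts <- sweep(lm$points %*% R, 2L, tr, "+")
  rownames(pts) <- rownames(lm$points)
  list(mesh = mesh, landmarks = landmark_set(lm$cast_id, lm$stage, pts, imputed = lm$imputed))
}

split_pairs <- function(tbl) {
  list(
    mz = tbl[tbl$zygosity == "MZ", c("value_1", "value_2")],
    dz = tbl[tbl$zygosity == "DZ", c("value_1", "value_2")]
  )
}

# raw-likelihood -2lnL of an AE model, evaluated directly from densities
# (used as the independent oracle for the concentrated optimizer)
m2ll_ae_direct <- function(mz, dz, a, e, mu) {
  per_group <- function(x, r, V) {
    d1 <- x[, 1] - mu
    d2 <- x[, 2] - mu
    q <- (d1^2 + d2^2 - 2 * r * d1 * d2) / (V * (1 - r^2))
    sum(log(V^2 * (1 - r^2)) + q + 2 * log(2 * pi))
  }
  V <- a^2 + e^2
  per_group(as.matrix(mz), a^2 / V, V) + per_group(as.matrix(dz), 0.5 * a^2 / V, V)
}
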