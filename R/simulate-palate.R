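# Parametric palate mesh + landmark generator with known ground truth.

# Along-arch stations of each tooth's dento-gingival landmark, as fractions
# of the antero-posterior length (0 = posterior limit, 1 = incisive papilla).
tooth_stations <- function(stage) {
  switch(stage,
    primary = c(
      "55" = 0.06, "54" = 0.35, "53" = 0.70, "52" = 0.86, "51" = 0.97,
      "65" = 0.06, "64" = 0.35, "63" = 0.70, "62" = 0.86, "61" = 0.97
    ),
    mixed = c(
      "16" = 0.06, "55" = 0.18, "54" = 0.42, "53" = 0.70, "12" = 0.86, "11" = 0.97,
      "26" = 0.06, "65" = 0.18, "64" = 0.42, "63" = 0.70, "22" = 0.86, "21" = 0.97
    ),
    permanent = c(
      "16" = 0.06, "15" = 0.22, "14" = 0.45, "13" = 0.70, "12" = 0.86, "11" = 0.97,
      "26" = 0.06, "25" = 0.22, "24" = 0.45, "23" = 0.70, "22" = 0.86, "21" = 0.97
    )
  )
}

#' Palate shape parameters
#'
#' Ground-truth dimensional parameters of the synthetic palate generator.
#' The defaults are the reference overall means of the primary dentition
#' (anterior width 22.1 mm, posterior width 27.4 mm, anterior depth 4.6 mm,
#' posterior depth 10.6 mm, antero-posterior length 25.3 mm).
#'
#' @param anterior_width,posterior_width Canine and terminal-molar
#'   dento-gingival widths (mm).
#' @param anterior_depth,posterior_depth Vault depths below the canine and
#'   molar dento-gingival lines (mm); anterior must be smaller than
#'   posterior.
#' @param ap_length Incisive papilla to posterior plane distance (mm).
#' @param edge_length Target tessellation edge length (mm).
#' @param asymmetry Maximum landmark displacement (mm) of a coherent
#'   one-sided perturbation: the right-side landmarks are rotated about the
#'   raphe axis by a random angle scaled so no landmark moves more than this
#'   distance. 0 gives an exactly bilaterally symmetric configuration.
#' @param vault_exponent Superellipse exponent of the vault cross-section.
#' @param seed Integer seed for the asymmetry perturbation.
#' @return A `palate_shape` parameter list.
#' @export
palate_shape <- function(anterior_width = 22.1, posterior_width = 27.4,
                         anterior_depth = 4.6, posterior_depth = 10.6,
                         ap_length = 25.3, edge_length = 0.5,
                         asymmetry = 0, vault_exponent = 2.5, seed = 1L) {
  dims <- c(
    anterior_width = anterior_width, posterior_width = posterior_width,
    anterior_depth = anterior_depth, posterior_depth = posterior_depth,
    ap_length = ap_length
  )
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    rlang::abort("All palate dimensions must be positive and finite.",
      class = "palatwin_spec_error"
    )
  }
  if (anterior_depth >= posterior_depth) {
    rlang::abort("`anterior_depth` must be smaller than `posterior_depth`.",
      class = "palatwin_spec_error"
    )
  }
  if (anterior_width >= posterior_width) {
    rlang::abort("`anterior_width` must be smaller than `posterior_width`.",
      class = "palatwin_spec_error"
    )
  }
  if (edge_length <= 0) {
    rlang::abort("`edge_length` must be positive.", class = "palatwin_spec_error")
  }
  structure(
    list(
      anterior_width = anterior_width, posterior_width = posterior_width,
      anterior_depth = anterior_depth, posterior_depth = posterior_depth,
      ap_length = ap_length, edge_length = edge_length,
      asymmetry = asymmetry, vault_exponent = vault_exponent, seed = seed
    ),
    class = "palate_shape"
  )
}

# Numerically exact enclosed volume of the generated vault between the
# gingival plane (z = 0) and posterior plane (y = 0): the superellipse
# cross-section at station y has area c_k * w(y) * d(y), integrated over y.
# Serves as an analytic oracle independent of the mesh pipeline.
palate_truth_volume <- function(w_fun, d_fun, L, k) {
  ck <- 2 * stats::integrate(function(t) (1 - t^k)^(1 / k), 0, 1,
    rel.tol = 1e-10
  )$value
  stats::integrate(function(y) ck * w_fun(y) * d_fun(y), 0, L,
    rel.tol = 1e-10, subdivisions = 500L
  )$value
}

#' Generate a synthetic palate mesh with known ground truth
#'
#' Builds a palatal vault as superellipse cross-sections lofted along the
#' raphe: monotone half-width and depth profiles interpolate the requested
#' widths/depths at the canine and terminal-molar stations, the incisive
#' papilla sits exactly `ap_length` anterior to the posterior plane, and a
#' short gingival skirt and posterior margin extend past the clipping planes
#' so that plane clipping is exercised. Landmarks are placed analytically:
#' canine and molar dento-gingival pairs exactly the requested widths apart,
#' vault apex exactly the requested depths below the dento-gingival lines.
#'
#' @param shape A [palate_shape()].
#' @param stage Dentition stage for landmark naming.
#' @param cast_id Identifier for the generated cast.
#' @return List with `mesh` (a [palate_mesh()]), `landmarks` (a
#'   [landmark_set()]), and `truth` (one-row tibble of ground-truth traits;
#'   `area` is `NA` — no closed form — while `volume` is the quadrature
#'   value of the lofted solid, exact up to numerical integration).
#' @export
generate_palate <- function(shape = palate_shape(), stage = "primary",
                            cast_id = "synthetic") {
  stage <- match.arg(stage, c("primary", "mixed", "permanent"))
  L <- shape$ap_length
  k <- shape$vault_exponent
  st <- tooth_stations(stage)
  f_molar <- min(st) # terminal tooth station
  f_canine <- 0.70
  y_m <- f_molar * L
  y_c <- f_canine * L

  # monotone half-width and depth profiles (clamped outside [0, L])
  aw2 <- shape$anterior_width / 2
  pw2 <- shape$posterior_width / 2
  w_sp <- stats::splinefun(
    c(0, y_m, y_c, L),
    c(pw2 + 0.4, pw2, aw2, 0.8 * aw2),
    method = "hyman"
  )
  d_sp <- stats::splinefun(
    c(0, y_m, y_c, L),
    c(shape$posterior_depth + 0.2, shape$posterior_depth, shape$anterior_depth, 0),
    method = "hyman"
  )
  w_fun <- function(y) w_sp(pmin(pmax(y, 0), L))
  d_fun <- function(y) d_sp(pmin(pmax(y, 0), L))

  h <- shape$edge_length
  margin <- 2
  skirt <- 2
  ys <- sort(unique(c(
    seq(-margin, L, by = h), L, 0,
    unique(st) * L
  )))
  n_arc <- max(2L * ceiling(1.2 * pw2 / h), 8L)
  if (n_arc %% 2L == 1L) n_arc <- n_arc + 1L
  t_arc <- seq(-1, 1, length.out = n_arc + 1L)
  n_skirt <- max(ceiling(skirt / h), 2L)
  z_skirt <- seq(-skirt, 0, length.out = n_skirt + 1L)[-(n_skirt + 1L)]

  section <- function(y) {
    w <- w_fun(y)
    d <- d_fun(y)
    xz_arc <- cbind(w * t_arc, d * (1 - abs(t_arc)^k)^(1 / k))
    left <- cbind(-w, z_skirt)
    right <- cbind(w, rev(z_skirt))
    xz <- rbind(left, xz_arc, right)
    cbind(xz[, 1], y, xz[, 2])
  }
  sections <- lapply(ys, section)
  n_p <- nrow(sections[[1]])
  vertices <- do.call(rbind, sections)
  n_y <- length(ys)
  idx <- function(i, j) (i - 1L) * n_p + j
  quads <- vector("list", n_y - 1L)
  for (i in seq_len(n_y - 1L)) {
    j <- seq_len(n_p - 1L)
    quads[[i]] <- rbind(
      cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
      cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    )
  }
  faces <- do.call(rbind, quads)
  mesh <- suppressMessages(palate_mesh(vertices, faces))

  # landmarks
  teeth <- names(st)
  dg <- lapply(teeth, function(tt) {
    y <- st[[tt]] * L
    side <- if (substr(tt, 1, 1) %in% c("1", "5")) 1 else -1
    c(side * w_fun(y), y, 0)
  })
  names(dg) <- paste0("dg_", teeth)
  distal_codes <- sub("^distal_", "", measurement_teeth(stage)$distal)
  distal <- lapply(distal_codes, function(tt) {
    side <- if (substr(tt, 1, 1) %in% c("1", "5")) 1 else -1
    c(side * w_fun(0), 0, 0)
  })
  names(distal) <- paste0("distal_", distal_codes)
  raphe <- list(
    raphe_anterior = c(0, L, 0),
    raphe_middle = c(0, y_c, d_fun(y_c)),
    raphe_posterior = c(0, y_m, d_fun(y_m))
  )
  pts <- do.call(rbind, c(dg, raphe, distal))
  if (shape$asymmetry > 0) {
    # coherent asymmetry: rotate the right-side landmarks about the raphe
    # axis by a random angle whose maximum displacement is `asymmetry` mm
    pts <- with_seed(shape$seed, {
      right <- pts[, 1] > 0
      rmax <- max(sqrt(pts[right, 1]^2 + pts[right, 3]^2))
      th <- stats::runif(1, -1, 1) * shape$asymmetry / rmax
      x <- pts[right, 1]
      z <- pts[right, 3]
      pts[right, 1] <- x * cos(th) - z * sin(th)
      pts[right, 3] <- x * sin(th) + z * cos(th)
      pts
    })
  }
  lm <- landmark_set(cast_id, stage, pts)

  truth <- tibble::tibble(
    cast_id = cast_id, stage = stage,
    anterior_width = shape$anterior_width,
    posterior_width = shape$posterior_width,
    anterior_depth = shape$anterior_depth,
    posterior_depth = shape$posterior_depth,
    ap_length = shape$ap_length,
    area = NA_real_,
    volume = palate_truth_volume(w_fun, d_fun, L, k)
  )
  list(mesh = mesh, landmarks = lm, truth = truth, shape = shape)
}

#' Remove named landmarks from a landmark set
#'
#' Utility for exercising the missing-landmark completion pathway. Refuses
#' to remove both members of an antimere pair, since completion would then
#' be impossible.
#'
#' @param lm A [landmark_set()].
#' @param names Landmark names to drop (may be empty).
#' @return A [landmark_set()] without the named landmarks.
#' @export
drop_landmarks <- function(lm, names) {
  stopifnot(inherits(lm, "landmark_set"))
  if (length(names) == 0L) {
    return(lm)
  }
  absent <- setdiff(names, rownames(lm$points))
  if (length(absent) > 0L) {
    rlang::abort(sprintf("Cannot drop absent landmark(s): %s", paste(absent, collapse = ", ")),
      class = "palatwin_spec_error"
    )
  }
  partners <- antimere_names(names)
  gone_after <- union(lm$missing, names)
  bad <- names[partners %in% gone_after & partners != names]
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "Refusing to drop both antimeres of: %s",
      paste(unique(pmin(bad, antimere_names(bad))), collapse = ", ")
    ), class = "palatwin_spec_error")
  }
  keep <- setdiff(rownames(lm$points), names)
  landmark_set(lm$cast_id, lm$stage,
    lm$points[keep, , drop = FALSE],
    imputed = setdiff(lm$imputed, names)
  )
}
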