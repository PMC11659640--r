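# Univariate classical-twin variance-component models (ACE/ADE family),
# fitted by maximum likelihood on MZ/DZ pair vectors.
#
# The pair covariance implied by path coefficients (a, c, d, e) is compound
# symmetric: total variance V = a^2+c^2+d^2+e^2 on the diagonal and
# r_z * V off-diagonal with r_MZ = (a^2+c^2+d^2)/V and
# r_DZ = (a^2/2 + c^2 + d^2/4)/V. Because the structure factorizes as
# V * R_z(proportions), the grand mean and V have closed-form ML solutions
# given the standardized proportions; only the 0-2 free proportions are
# optimized numerically, deterministically (coarse grid + box-constrained
# quasi-Newton from fixed starts). This is the same optimum as optimizing
# over raw paths, with exact boundary handling.

TWIN_MODELS <- list(
  ACE = c("A", "C"), ADE = c("A", "D"), AE = "A", CE = "C", E = character(0)
)

#' Model-implied twin-pair covariance matrix
#'
#' Builds the expected 2x2 phenotypic covariance matrix of a twin pair from
#' path coefficients. Latent correlations are 1 (MZ) and 0.5 (DZ) for
#' additive genetic effects, 1 and 0.25 for dominance, 1 for the shared
#' environment in both zygosities, and 0 for the non-shared environment.
#'
#' @param a,c,d,e Path coefficients (trait units); variance components are
#'   their squares.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return Symmetric positive semi-definite 2x2 matrix.
#' @export
twin_covariance <- function(a = 0, c = 0, d = 0, e = 1, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  V <- a^2 + c^2 + d^2 + e^2
  off <- if (zygosity == "MZ") {
    a^2 + c^2 + d^2
  } else {
    0.5 * a^2 + c^2 + 0.25 * d^2
  }
  matrix(c(V, off, off, V), 2L)
}

as_pair_matrix <- function(pairs) {
  if (is.data.frame(pairs)) {
    cols <- intersect(c("value_1", "value_2"), names(pairs))
    if (length(cols) == 2L) {
      pairs <- as.matrix(pairs[, cols])
    } else {
      pairs <- as.matrix(pairs)
    }
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || !all(is.finite(pairs))) {
    rlang::abort("Twin pairs must be a 2-column finite numeric matrix (or have value_1/value_2 columns).",
      class = "palatwin_spec_error"
    )
  }
  pairs
}

# Sufficient statistics of one zygosity group. All likelihood quantities
# depend on the data only through these symmetric functions, so the
# likelihood is exactly invariant under within-pair order swaps.
zyg_stats <- function(pairs) {
  x1 <- pairs[, 1]
  x2 <- pairs[, 2]
  list(
    n = nrow(pairs),
    S11 = sum(x1^2) + sum(x2^2),
    S12 = sum(x1 * x2),
    U = sum(x1) + sum(x2)
  )
}

twin_suffstats <- function(mz_pairs, dz_pairs) {
  list(mz = zyg_stats(as_pair_matrix(mz_pairs)), dz = zyg_stats(as_pair_matrix(dz_pairs)))
}

# sum over pairs of the Mahalanobis form under correlation r and unit V
q_sum <- function(st, r, mu) {
  sd2 <- st$S11 - 2 * mu * st$U + 2 * st$n * mu^2 # sum (d1^2 + d2^2)
  sdd <- st$S12 - mu * st$U + st$n * mu^2 # sum d1 * d2
  (sd2 - 2 * r * sdd) / (1 - r^2)
}

# -2 log-likelihood profiled over the grand mean and total variance, for
# given within-pair correlations. Returns the concentrated value and the
# closed-form mu and V at the optimum.
profiled_m2ll <- function(stats, r_mz, r_dz) {
  r_mz <- min(r_mz, 1 - 1e-12)
  r_dz <- min(r_dz, 1 - 1e-12)
  smz <- stats$mz
  sdz <- stats$dz
  mu <- (smz$U / (1 + r_mz) + sdz$U / (1 + r_dz)) /
    (2 * smz$n / (1 + r_mz) + 2 * sdz$n / (1 + r_dz))
  qq <- q_sum(smz, r_mz, mu) + q_sum(sdz, r_dz, mu)
  N <- smz$n + sdz$n
  V <- qq / (2 * N)
  m2ll <- smz$n * log(1 - r_mz^2) + sdz$n * log(1 - r_dz^2) +
    2 * N * log(V) + 2 * N + 2 * N * log(2 * pi)
  list(m2ll = m2ll, mu = mu, V = V)
}

# map the box parameterization (p = total familial proportion, q = share of
# p that is additive) to within-pair correlations for a given model
model_correlations <- function(model, p, q = 1) {
  switch(model,
    E = c(0, 0),
    AE = c(p, 0.5 * p),
    CE = c(p, p),
    ACE = c(p, p * (1 - q / 2)),
    ADE = c(p, p * (q / 2 + (1 - q) / 4))
  )
}

model_components <- function(model, p, q = 1) {
  comp <- c(A = 0, C = 0, D = 0, E = 1)
  if (model %in% c("AE")) {
    comp["A"] <- p
  } else if (model == "CE") {
    comp["C"] <- p
  } else if (model == "ACE") {
    comp["A"] <- p * q
    comp["C"] <- p * (1 - q)
  } else if (model == "ADE") {
    comp["A"] <- p * q
    comp["D"] <- p * (1 - q)
  }
  comp["E"] <- 1 - comp["A"] - comp["C"] - comp["D"]
  comp
}

# sample within-pair correlations (method-of-moments starting values)
sample_pair_correlation <- function(st) {
  mu <- st$U / (2 * st$n)
  v <- (st$S11 - 2 * st$n * mu^2) / (2 * st$n)
  cv <- (st$S12 - st$n * mu^2) / st$n
  if (v <= 0) {
    return(0)
  }
  max(min(cv / v, 0.99), -0.5)
}

fit_proportions <- function(stats, model) {
  p_hi <- 1 - 1e-9
  f1 <- function(p) {
    r <- model_correlations(model, p)
    profiled_m2ll(stats, r[1], r[2])$m2ll
  }
  if (model == "E") {
    return(list(p = 0, q = 1, m2ll = f1(0), converged = TRUE))
  }
  if (model %in% c("AE", "CE")) {
    grid <- seq(0, p_hi, length.out = 41L)
    vals <- vapply(grid, f1, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    opt <- stats::optimize(f1, c(lo, hi), tol = 1e-12)
    cand <- rbind(
      c(opt$minimum, opt$objective),
      c(0, f1(0)),
      c(grid[i], vals[i])
    )
    best <- cand[which.min(cand[, 2]), ]
    return(list(p = best[1], q = 1, m2ll = best[2], converged = TRUE))
  }
  # ACE / ADE: 2 free proportions via the (p, q) box
  f2 <- function(par) {
    r <- model_correlations(model, par[1], par[2])
    profiled_m2ll(stats, r[1], r[2])$m2ll
  }
  r1 <- sample_pair_correlation(stats$mz)
  r2 <- sample_pair_correlation(stats$dz)
  sA0 <- max(min(2 * (r1 - r2), 0.95), 0.02)
  p0 <- max(min(r1, 0.95), 0.05)
  starts <- rbind(
    c(p0, max(min(sA0 / p0, 0.98), 0.02)),
    c(0.5, 0.5),
    c(0.3, 0.9)
  )
  best <- NULL
  ok <- TRUE
  for (s in seq_len(nrow(starts))) {
    res <- stats::optim(starts[s, ], f2,
      method = "L-BFGS-B",
      lower = c(0, 0), upper = c(p_hi, 1),
      control = list(factr = 1e2, maxit = 500L)
    )
    if (is.null(best) || res$value < best$value) best <- res
    ok <- ok && res$convergence %in% c(0L, 52L)
  }
  # polish corners: exact boundary candidates
  corners <- rbind(best$par, c(best$par[1], 1), c(best$par[1], 0), c(0, 1))
  cv <- apply(corners, 1L, f2)
  j <- which.min(cv)
  list(p = corners[j, 1], q = corners[j, 2], m2ll = cv[j], converged = ok)
}

#' Fit a twin variance-component model by maximum likelihood
#'
#' Maximizes the joint bivariate-normal likelihood of MZ and DZ pair vectors
#' under the chosen model (`ACE`, `ADE`, `AE`, `CE` or `E`), with a common
#' grand mean and non-negative variance components (boundary estimates
#' allowed). Returns standardized components, -2 log-likelihood, AIC,
#' narrow-sense heritability and (optionally) profile-likelihood confidence
#' intervals.
#'
#' @param mz_pairs,dz_pairs Two-column matrices (or data frames with
#'   `value_1`/`value_2`) of twin-pair trait values.
#' @param model Model tag.
#' @param conf_int Compute 95% profile-likelihood CIs on the standardized
#'   components (see [twin_confint()]).
#' @return An object of class `twin_fit`: list with `model`, `standardized`
#'   (named A/C/D/E proportions), `paths` (a, c, d, e, in trait units),
#'   `mu`, `V`, `minus2ll`, `aic`, `n_free`, `h2`, `ci95`, `converged`,
#'   `n_mz`, `n_dz`.
#' @export
fit_twin_model <- function(mz_pairs, dz_pairs,
                           model = c("ACE", "ADE", "AE", "CE", "E"),
                           conf_int = TRUE) {
  model <- match.arg(model)
  mz <- as_pair_matrix(mz_pairs)
  dz <- as_pair_matrix(dz_pairs)
  if (nrow(mz) < 2L || nrow(dz) < 2L) {
    rlang::abort("Need at least 2 pairs per zygosity.", class = "palatwin_spec_error")
  }
  stats <- list(mz = zyg_stats(mz), dz = zyg_stats(dz))
  opt <- fit_proportions(stats, model)
  comp <- model_components(model, opt$p, opt$q)
  r <- model_correlations(model, opt$p, opt$q)
  prof <- profiled_m2ll(stats, r[1], r[2])
  n_free <- length(TWIN_MODELS[[model]]) + 2L # free non-E proportions + e + mu
  paths <- sqrt(pmax(comp, 0) * prof$V)
  names(paths) <- c("a", "c", "d", "e")
  fit <- structure(
    list(
      model = model,
      standardized = comp,
      paths = paths,
      mu = prof$mu,
      V = prof$V,
      minus2ll = opt$m2ll,
      aic = opt$m2ll + 2 * n_free,
      n_free = n_free,
      h2 = unname(comp["A"]),
      ci95 = NULL,
      converged = isTRUE(opt$converged),
      n_mz = nrow(mz),
      n_dz = nrow(dz),
      suffstats = stats
    ),
    class = "twin_fit"
  )
  if (conf_int) fit$ci95 <- twin_confint(fit)
  fit
}

#' @export
print.twin_fit <- function(x, ...) {
  comp <- x$standardized[x$standardized > 0 | names(x$standardized) == "E"]
  cat(sprintf(
    "<twin_fit %s: %s; -2lnL = %.2f, AIC = %.2f, h2 = %.3f (%d MZ + %d DZ pairs)>\n",
    x$model,
    paste(sprintf("%s = %.3f", names(comp), comp), collapse = ", "),
    x$minus2ll, x$aic, x$h2, x$n_mz, x$n_dz
  ))
  invisible(x)
}

#' Narrow-sense heritability of a fitted twin model
#'
#' The ratio of additive genetic variance to total phenotypic variance,
#' `a^2 / (a^2 + c^2 + d^2 + e^2)`. Dominance variance, when present,
#' contributes to the denominator but not the numerator.
#'
#' @param fit A `twin_fit`.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "twin_fit"))
  unname(fit$standardized["A"])
}

#' -2 log-likelihood of the saturated two-group model
#'
#' The reference model with unconstrained per-zygosity mean vectors and
#' covariance matrices (their sample MLEs); every structured twin model is
#' nested in it, so its -2lnL is a lower bound on any structured fit.
#'
#' @param mz_pairs,dz_pairs Two-column pair matrices.
#' @return Scalar -2 log-likelihood.
#' @export
saturated_m2ll <- function(mz_pairs, dz_pairs) {
  one <- function(pairs) {
    x <- as_pair_matrix(pairs)
    n <- nrow(x)
    ctr <- sweep(x, 2L, colMeans(x))
    S <- crossprod(ctr) / n
    dt <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (dt <= 0) {
      rlang::abort("Singular sample covariance; saturated model undefined.",
        class = "palatwin_spec_error"
      )
    }
    n * log(dt) + 2 * n + 2 * n * log(2 * pi)
  }
  one(mz_pairs) + one(dz_pairs)
}
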