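# Profile-likelihood confidence intervals on standardized variance
# components.

# -2lnL minimized subject to one standardized component being fixed at `s`,
# within the given model family. The remaining free proportion (if any) is
# profiled by 1-D optimization; mean and total variance are always profiled
# in closed form.
profile_component_m2ll <- function(stats, model, comp, s) {
  ev <- function(A = 0, C = 0, D = 0) {
    r_mz <- A + C + D
    r_dz <- 0.5 * A + C + 0.25 * D
    profiled_m2ll(stats, r_mz, r_dz)$m2ll
  }
  opt1 <- function(f, hi) {
    if (hi <= 1e-12) {
      return(f(0))
    }
    grid <- seq(0, hi, length.out = 21L)
    vals <- vapply(grid, f, numeric(1))
    i <- which.min(vals)
    o <- stats::optimize(f, c(grid[max(i - 1L, 1L)], grid[min(i + 1L, 21L)]), tol = 1e-10)
    min(o$objective, vals[i])
  }
  free <- 1 - s - 1e-12 # room left for the other non-E component
  switch(model,
    AE = switch(comp,
      A = ev(A = s),
      E = ev(A = 1 - s)
    ),
    CE = switch(comp,
      C = ev(C = s),
      E = ev(C = 1 - s)
    ),
    ACE = switch(comp,
      A = opt1(function(cc) ev(A = s, C = cc), free),
      C = opt1(function(aa) ev(A = aa, C = s), free),
      E = opt1(function(q) ev(A = q * (1 - s), C = (1 - q) * (1 - s)), 1)
    ),
    ADE = switch(comp,
      A = opt1(function(dd) ev(A = s, D = dd), free),
      D = opt1(function(aa) ev(A = aa, D = s), free),
      E = opt1(function(q) ev(A = q * (1 - s), D = (1 - q) * (1 - s)), 1)
    ),
    rlang::abort(sprintf("No profile available for component %s in model %s.", comp, model))
  )
}

#' Profile-likelihood confidence intervals for a twin fit
#'
#' For each standardized component of the fitted model (including E), finds
#' the values at which the profiled -2 log-likelihood rises by the
#' chi-squared(1) quantile above its minimum; bounds are clamped to
#' `[0, 1]`. A boundary at 0 or 1 whose profile never crosses the threshold
#' is reported as that boundary. The point estimate always lies inside the
#' interval.
#'
#' @param fit A `twin_fit` from [fit_twin_model()].
#' @param level Confidence level (default 0.95).
#' @return Matrix with one row per component (`A`, `C`, `D`, `E` as
#'   applicable) and columns `lower`, `upper`; `NULL` for the E-only model,
#'   whose single component is fixed at 1.
#' @export
twin_confint <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "twin_fit"))
  if (fit$model == "E") {
    return(NULL)
  }
  stats <- fit$suffstats
  crit <- stats::qchisq(level, df = 1L)
  target <- fit$minus2ll + crit
  comps <- c(TWIN_MODELS[[fit$model]], "E")
  upper_cap <- 1 - 1e-8
  out <- matrix(NA_real_, nrow = length(comps), ncol = 2L,
    dimnames = list(comps, c("lower", "upper"))
  )
  for (comp in comps) {
    shat <- unname(fit$standardized[comp])
    g <- function(s) profile_component_m2ll(stats, fit$model, comp, s) - target
    lo <- if (shat <= 1e-8 || g(0) <= 0) {
      0
    } else {
      stats::uniroot(g, c(0, shat), tol = 1e-7)$root
    }
    hi <- if (shat >= upper_cap || g(upper_cap) <= 0) {
      1
    } else {
      stats::uniroot(g, c(shat, upper_cap), tol = 1e-7)$root
    }
    out[comp, ] <- c(lo, hi)
  }
  out
}
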