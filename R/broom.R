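# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the standardized components of a twin fit
#'
#' @param x A `twin_fit`.
#' @param ... Unused.
#' @return Tibble with one row per component present in the model:
#'   `component`, `estimate`, `conf.low`, `conf.high`.
#' @method tidy twin_fit
#' @export
tidy.twin_fit <- function(x, ...) {
  comps <- c(TWIN_MODELS[[x$model]], "E")
  ci <- x$ci95
  tibble::tibble(
    component = comps,
    estimate = unname(x$standardized[comps]),
    conf.low = if (is.null(ci)) NA_real_ else ci[comps, "lower"],
    conf.high = if (is.null(ci)) NA_real_ else ci[comps, "upper"]
  )
}

#' One-row model summary of a twin fit
#'
#' @param x A `twin_fit`.
#' @param ... Unused.
#' @return Tibble: `model`, `minus2ll`, `aic`, `n_free`, `h2`, `mu`,
#'   `total_variance`, `n_mz`, `n_dz`, `converged`.
#' @method glance twin_fit
#' @export
glance.twin_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, minus2ll = x$minus2ll, aic = x$aic, n_free = x$n_free,
    h2 = x$h2, mu = x$mu, total_variance = x$V,
    n_mz = x$n_mz, n_dz = x$n_dz, converged = x$converged
  )
}

#' Tidy the decision trace of a model selection
#'
#' @param x A `twin_model_selection`.
#' @param ... Unused.
#' @return The likelihood-ratio comparison tibble with the per-model AIC
#'   table attached as the `aic` attribute.
#' @method tidy twin_model_selection
#' @export
tidy.twin_model_selection <- function(x, ...) {
  out <- x$comparisons
  attr(out, "aic") <- x$aic
  out
}

#' One-row summary of a model selection
#'
#' @param x A `twin_model_selection`.
#' @param ... Unused.
#' @return `glance()` of the selected fit plus `n_candidates`.
#' @method glance twin_model_selection
#' @export
glance.twin_model_selection <- function(x, ...) {
  dplyr::mutate(glance(x$selected), n_candidates = length(x$fits))
}

#' Tidy the fixed effects of a twin mixed model
#'
#' @param x A `twin_lmm`.
#' @param ... Unused.
#' @return Tibble of fixed-effect estimates.
#' @method tidy twin_lmm
#' @export
tidy.twin_lmm <- function(x, ...) {
  x$fixed
}

#' One-row summary of a twin mixed model
#'
#' @param x A `twin_lmm`.
#' @param ... Unused.
#' @return Tibble with the variance components and log-likelihood.
#' @method glance twin_lmm
#' @export
glance.twin_lmm <- function(x, ...) {
  tibble::tibble(
    var_family = x$var_family,
    var_residual = x$var_residual,
    icc_family = x$var_family / (x$var_family + x$var_residual),
    logLik = as.numeric(stats::logLik(x$model)),
    aic = stats::AIC(x$model)
  )
}
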