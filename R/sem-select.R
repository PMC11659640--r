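# Likelihood-ratio tests, model selection and the cohort-level fitting
# loop.

is_nested_in <- function(sub, full) {
  all(TWIN_MODELS[[sub]] %in% TWIN_MODELS[[full]]) &&
    length(TWIN_MODELS[[sub]]) < length(TWIN_MODELS[[full]])
}

#' Chi-squared likelihood-ratio test between nested twin models
#'
#' Refers the difference in -2 log-likelihood between a sub-model and the
#' full model it is nested in to a chi-squared distribution with degrees of
#' freedom equal to the difference in free parameters. The naive chi-squared
#' reference is used by default, as is conventional in twin modelling even
#' though components on the boundary make it conservative; the 50:50
#' boundary-mixture reference is available via `boundary_mixture = TRUE`
#' when a single component is dropped.
#'
#' @param full,sub `twin_fit` objects fitted to the same data; `sub` must be
#'   nested in `full`.
#' @param boundary_mixture Use the 0.5*chi2(df) + 0.5*chi2(df-1) mixture
#'   p-value.
#' @return One-row tibble: `full`, `sub`, `delta_m2ll`, `df`, `p`,
#'   `aic_full`, `aic_sub`.
#' @export
twin_lrt <- function(full, sub, boundary_mixture = FALSE) {
  stopifnot(inherits(full, "twin_fit"), inherits(sub, "twin_fit"))
  if (!is_nested_in(sub$model, full$model)) {
    rlang::abort(sprintf(
      "%s is not nested in %s; compare non-nested models by AIC instead.",
      sub$model, full$model
    ), class = "palatwin_spec_error")
  }
  delta <- max(sub$minus2ll - full$minus2ll, 0)
  df <- full$n_free - sub$n_free
  p <- if (boundary_mixture) {
    0.5 * stats::pchisq(delta, df, lower.tail = FALSE) +
      0.5 * if (df > 1L) stats::pchisq(delta, df - 1L, lower.tail = FALSE) else as.numeric(delta <= 0)
  } else {
    stats::pchisq(delta, df, lower.tail = FALSE)
  }
  tibble::tibble(
    full = .env$full$model, sub = .env$sub$model,
    delta_m2ll = delta, df = .env$df, p = .env$p,
    aic_full = .env$full$aic, aic_sub = .env$sub$aic
  )
}

#' Fit all candidate twin models and select the most parsimonious
#'
#' Fits the candidate set (by default ACE, ADE, AE, CE and E) to the same
#' pair data and applies the classical selection rule: a more complex model
#' is retained only if dropping to the simpler one causes a significant loss
#' of fit by chi-squared likelihood-ratio test at `alpha`; each sub-model is
#' tested against every fitted full model (ACE and/or ADE) containing it.
#' Among the surviving models, the fewest-parameter one is chosen, with AIC
#' breaking ties (AIC also arbitrates genuinely non-nested survivors such as
#' AE vs CE). The full decision trace is returned.
#'
#' @param mz_pairs,dz_pairs Two-column pair matrices.
#' @param candidates Model tags to fit. The DE model is excluded by default
#'   (dominance without additive variance is biologically implausible) but
#'   may not be requested here at all; fit it directly with
#'   [fit_twin_model()] if needed.
#' @param alpha Significance level of the likelihood-ratio ladder.
#' @param conf_int Compute profile CIs on the selected model.
#' @return An object of class `twin_model_selection`: list with `fits`
#'   (named list of `twin_fit`), `comparisons` (LRT trace tibble),
#'   `aic` (per-model tibble), and `selected` (a `twin_fit`).
#' @export
select_twin_model <- function(mz_pairs, dz_pairs,
                              candidates = c("ACE", "ADE", "AE", "CE", "E"),
                              alpha = 0.05, conf_int = TRUE) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  fits <- lapply(candidates, function(m) {
    fit_twin_model(mz_pairs, dz_pairs, model = m, conf_int = FALSE)
  })
  names(fits) <- candidates
  bad <- names(fits)[!vapply(fits, `[[`, logical(1), "converged")]
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "Model selection aborted; unconverged candidate(s): %s",
      paste(bad, collapse = ", ")
    ), class = "palatwin_spec_error")
  }
  full_models <- intersect(c("ACE", "ADE"), candidates)
  comparisons <- list()
  survives <- stats::setNames(rep(TRUE, length(candidates)), candidates)
  for (sub in candidates) {
    for (full in full_models) {
      if (is_nested_in(sub, full)) {
        cmp <- twin_lrt(fits[[full]], fits[[sub]])
        comparisons[[length(comparisons) + 1L]] <- cmp
        if (cmp$p < alpha) survives[sub] <- FALSE
      }
    }
  }
  comparisons <- if (length(comparisons)) dplyr::bind_rows(comparisons) else tibble::tibble()
  aic_tbl <- tibble::tibble(
    model = candidates,
    n_free = vapply(fits, `[[`, integer(1), "n_free"),
    minus2ll = vapply(fits, `[[`, numeric(1), "minus2ll"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    survives_lrt = unname(survives)
  )
  pool <- aic_tbl[aic_tbl$survives_lrt, , drop = FALSE]
  if (nrow(pool) == 0L) pool <- aic_tbl
  pool <- pool[order(pool$n_free, pool$aic, match(pool$model, candidates)), ]
  selected_tag <- pool$model[1]
  selected <- fits[[selected_tag]]
  if (conf_int) selected$ci95 <- twin_confint(selected)
  fits[[selected_tag]] <- selected
  structure(
    list(
      fits = fits, comparisons = comparisons, aic = aic_tbl,
      selected = selected, alpha = alpha
    ),
    class = "twin_model_selection"
  )
}

#' @export
print.twin_model_selection <- function(x, ...) {
  cat(sprintf("<twin_model_selection: %s selected>\n", x$selected$model))
  print(x$aic)
  invisible(x)
}

#' Extract twin-pair matrices from a cohort table
#'
#' @param cohort A validated cohort tibble.
#' @param trait Trait column name.
#' @param stage Dentition stage to extract.
#' @return List with `mz` and `dz` two-column matrices (twins ordered by
#'   `twin_id` within family; all model likelihoods are invariant to that
#'   order).
#' @export
cohort_pairs <- function(cohort, trait, stage) {
  sub <- cohort[cohort$stage == stage & is.finite(cohort[[trait]]), , drop = FALSE]
  sub <- sub[order(sub$family_id, sub$twin_id), , drop = FALSE]
  cnt <- table(sub$family_id)
  keep <- names(cnt)[cnt == 2L]
  sub <- sub[sub$family_id %in% keep, , drop = FALSE]
  per_zyg <- function(zyg) {
    z <- sub[sub$zygosity == zyg, , drop = FALSE]
    matrix(z[[trait]], ncol = 2L, byrow = TRUE)
  }
  list(mz = per_zyg("MZ"), dz = per_zyg("DZ"))
}

#' Fit and select twin models for every trait and stage of a cohort
#'
#' Runs [select_twin_model()] per trait-stage cell and assembles a results
#' table in the layout of a classical twin-study report: selected model,
#' AIC, standardized components with 95% profile CIs, and narrow-sense
#' heritability.
#'
#' @param cohort A validated cohort tibble.
#' @param traits Trait columns to analyse; defaults to the measured palatal
#'   traits present in the cohort.
#' @param candidates,alpha Passed to [select_twin_model()].
#' @param min_pairs Trait-stage cells with fewer pairs in either zygosity
#'   are skipped with a message.
#' @return Tibble with one row per trait-stage: columns `trait`, `stage`,
#'   `model`, `aic`, `A`, `A_lo`, `A_hi`, `C`, `C_lo`, `C_hi`, `D`, `D_lo`,
#'   `D_hi`, `E`, `E_lo`, `E_hi`, `h2`, plus a `selection` list-column with
#'   the full decision traces.
#' @export
fit_twin_models <- function(cohort, traits = NULL,
                            candidates = c("ACE", "ADE", "AE", "CE", "E"),
                            alpha = 0.05, min_pairs = 10L) {
  if (is.null(traits)) traits <- intersect(TRAIT_NAMES, names(cohort))
  stages <- intersect(c("primary", "mixed", "permanent"), unique(cohort$stage))
  grid <- tidyr::expand_grid(trait = traits, stage = stages)
  rows <- purrr::pmap(grid, function(trait, stage) {
    pairs <- cohort_pairs(cohort, trait, stage)
    if (nrow(pairs$mz) < min_pairs || nrow(pairs$dz) < min_pairs) {
      message(sprintf(
        "Skipping %s/%s: fewer than %d pairs per zygosity.", trait, stage, min_pairs
      ))
      return(NULL)
    }
    sel <- select_twin_model(pairs$mz, pairs$dz,
      candidates = candidates, alpha = alpha
    )
    fit <- sel$selected
    ci <- fit$ci95
    ci_of <- function(k, j) {
      if (!is.null(ci) && k %in% rownames(ci)) ci[k, j] else NA_real_
    }
    present <- c(TWIN_MODELS[[fit$model]], "E")
    val <- function(k) if (k %in% present) unname(fit$standardized[k]) else NA_real_
    tibble::tibble(
      trait = trait, stage = stage, model = fit$model, aic = fit$aic,
      A = val("A"), A_lo = ci_of("A", 1), A_hi = ci_of("A", 2),
      C = val("C"), C_lo = ci_of("C", 1), C_hi = ci_of("C", 2),
      D = val("D"), D_lo = ci_of("D", 1), D_hi = ci_of("D", 2),
      E = val("E"), E_lo = ci_of("E", 1), E_hi = ci_of("E", 2),
      h2 = fit$h2, selection = list(sel)
    )
  })
  dplyr::bind_rows(purrr::compact(rows))
}
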