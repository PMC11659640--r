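# Descriptive, reliability and comparison statistics for twin cohorts.

#' Descriptive table of palatal traits
#'
#' Mean, standard deviation (n-1 denominator) and count per dentition
#' stage, trait and group, where the groups are Overall, the sexes (M/F)
#' and the zygosities (MZ/DZ). Cells with fewer than two observations are
#' omitted with a message.
#'
#' @param cohort A validated cohort tibble.
#' @param traits Trait columns to summarize; defaults to the palatal traits
#'   present.
#' @return Tibble with columns `stage`, `trait`, `group`, `n`, `mean`, `sd`.
#' @export
descriptive_table <- function(cohort, traits = NULL) {
  if (is.null(traits)) traits <- intersect(TRAIT_NAMES, names(cohort))
  long <- tidyr::pivot_longer(
    dplyr::select(cohort, "stage", "sex", "zygosity", dplyr::all_of(traits)),
    dplyr::all_of(traits),
    names_to = "trait", values_to = "value"
  )
  long <- dplyr::filter(long, is.finite(.data$value))
  groupings <- list(
    Overall = rep(TRUE, nrow(long)),
    M = long$sex == "M",
    F = long$sex == "F",
    MZ = long$zygosity == "MZ",
    DZ = long$zygosity == "DZ"
  )
  out <- purrr::imap(groupings, function(sel, grp) {
    dplyr::summarise(
      dplyr::group_by(long[sel, , drop = FALSE], .data$stage, .data$trait),
      n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
      .groups = "drop"
    ) |>
      dplyr::mutate(group = grp)
  }) |>
    dplyr::bind_rows()
  small <- out$n < 2L
  if (any(small)) {
    message(sprintf("Omitted %d cell(s) with fewer than 2 observations.", sum(small)))
    out <- out[!small, , drop = FALSE]
  }
  stage_order <- c("primary", "mixed", "permanent")
  grp_order <- c("Overall", "M", "F", "MZ", "DZ")
  out <- out[order(
    match(out$stage, stage_order), out$trait, match(out$group, grp_order)
  ), c("stage", "trait", "group", "n", "mean", "sd")]
  tibble::as_tibble(out)
}

#' Percent change relative to the primary-dentition mean
#'
#' `100 * (mean_stage - mean_primary) / mean_primary`, rounded to one
#' decimal as conventionally reported.
#'
#' @param mean_stage,mean_primary Group means (same units); the baseline
#'   must be positive.
#' @return Percent change (one decimal).
#' @export
percent_change <- function(mean_stage, mean_primary) {
  if (any(!is.finite(mean_primary)) || any(mean_primary <= 0)) {
    rlang::abort("Baseline (primary-dentition) mean must be positive.",
      class = "palatwin_spec_error"
    )
  }
  round(100 * (mean_stage - mean_primary) / mean_primary, 1)
}

#' One-way random-effects intraclass correlation for paired data
#'
#' The classical twin-pair ICC from a one-way random-effects ANOVA with
#' pairs as groups: `(MS_between - MS_within) / (MS_between + MS_within)`.
#' Twin labels are exchangeable, and the estimator is exactly invariant
#' under within-pair order swaps.
#'
#' @param pairs Two-column matrix or data frame with `value_1`/`value_2`.
#' @return One-row tibble: `icc`, `n_pairs`, `var_between`, `var_within`,
#'   `ms_between`, `ms_within`. `icc` is `NA` (with a warning) when the
#'   total variance is zero.
#' @export
icc_oneway <- function(pairs) {
  x <- as_pair_matrix(pairs)
  n <- nrow(x)
  if (n < 2L) {
    rlang::abort("ICC needs at least 2 pairs.", class = "palatwin_spec_error")
  }
  m <- rowMeans(x)
  g <- mean(x)
  ms_b <- 2 * sum((m - g)^2) / (n - 1)
  ms_w <- sum((x - m)^2) / n
  if (ms_b + ms_w <= 0) {
    warning("Zero total variance; ICC undefined.")
    icc <- NA_real_
  } else {
    icc <- (ms_b - ms_w) / (ms_b + ms_w)
  }
  tibble::tibble(
    icc = icc, n_pairs = n,
    var_between = (ms_b - ms_w) / 2, var_within = ms_w,
    ms_between = ms_b, ms_within = ms_w
  )
}

#' Within-pair ICCs by trait, stage and zygosity
#'
#' @param cohort A validated cohort tibble.
#' @param traits Trait columns; defaults to the palatal traits present.
#' @return Tibble with `trait`, `stage`, `zygosity` and the [icc_oneway()]
#'   columns.
#' @export
twin_icc <- function(cohort, traits = NULL) {
  if (is.null(traits)) traits <- intersect(TRAIT_NAMES, names(cohort))
  stages <- intersect(c("primary", "mixed", "permanent"), unique(cohort$stage))
  grid <- tidyr::expand_grid(trait = traits, stage = stages, zygosity = c("MZ", "DZ"))
  purrr::pmap_dfr(grid, function(trait, stage, zygosity) {
    pairs <- cohort_pairs(cohort, trait, stage)[[tolower(zygosity)]]
    if (nrow(pairs) < 2L) {
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(trait = trait, stage = stage, zygosity = zygosity),
      icc_oneway(pairs)
    )
  })
}

#' Duplicate-measurement method error
#'
#' Random measurement error from two measurement sessions of the same items:
#' the Dahlberg estimator `sqrt(sum(d^2) / (2 n))` and the mean-corrected
#' method-of-moments estimator `sqrt(sum((d - mean(d))^2) / (2 (n - 1)))`,
#' where `d` are the per-item session differences. The Dahlberg value folds
#' any systematic session offset into the error; the mean-corrected
#' estimator removes it, so the two together separate random from
#' systematic error. Both are reported.
#'
#' @param session1,session2 Equal-length numeric vectors of duplicate
#'   measurements.
#' @return One-row tibble: `dahlberg`, `mme`, `mean_difference`,
#'   `n_replicated`, plus the per-item differences as a list-column `d`.
#' @export
method_error <- function(session1, session2) {
  if (length(session1) != length(session2)) {
    rlang::abort("Sessions must have equal length.", class = "palatwin_spec_error")
  }
  n <- length(session1)
  if (n < 2L) {
    rlang::abort("Method error needs at least 2 replicated items.",
      class = "palatwin_spec_error"
    )
  }
  d <- session1 - session2
  tibble::tibble(
    dahlberg = sqrt(sum(d^2) / (2 * n)),
    mme = sqrt(sum((d - mean(d))^2) / (2 * (n - 1))),
    mean_difference = mean(d),
    n_replicated = n,
    d = list(d)
  )
}

#' Two-group comparisons with Bonferroni correction
#'
#' Two-sample t-tests (Welch by default; `var_equal = TRUE` restores the
#' pooled-variance Student test) of trait means between MZ and DZ twins,
#' males and females, and — when stages beyond the mixed dentition are
#' present — between twins lost to follow-up after the mixed dentition and
#' those retained (comparing their mixed-dentition values). The Bonferroni
#' threshold is `alpha / m_tests`, with `m_tests` defaulting to the number
#' of traits tested. Twin observations are clustered within families; the
#' returned `clustered` flag marks comparisons where both groups come from
#' the same cohort and the nominal p-value is therefore anti-conservative.
#'
#' @param cohort A validated cohort tibble.
#' @param traits Trait columns; defaults to the palatal traits present.
#' @param comparisons Subset of `"MZ_vs_DZ"`, `"M_vs_F"`,
#'   `"attrited_vs_retained"`.
#' @param alpha Familywise significance level.
#' @param m_tests Number of tests for the Bonferroni correction.
#' @param var_equal Use the pooled-variance Student t-test.
#' @return Tibble with `stage`, `trait`, `comparison`, group means,
#'   `estimate`, `t`, `df`, `p`, `p_bonferroni`, `significant` (at the
#'   Bonferroni threshold) and `clustered`.
#' @export
group_comparisons <- function(cohort, traits = NULL,
                              comparisons = c("MZ_vs_DZ", "M_vs_F", "attrited_vs_retained"),
                              alpha = 0.05, m_tests = NULL, var_equal = FALSE) {
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  if (is.null(traits)) traits <- intersect(TRAIT_NAMES, names(cohort))
  if (is.null(m_tests)) m_tests <- length(traits)
  stages <- intersect(c("primary", "mixed", "permanent"), unique(cohort$stage))

  run_test <- function(x, y, stage, trait, comparison, g1, g2) {
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L || (stats::sd(x) == 0 && stats::sd(y) == 0)) {
      message(sprintf("Skipping degenerate comparison %s (%s, %s).", comparison, trait, stage))
      return(NULL)
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    tibble::tibble(
      stage = stage, trait = trait, comparison = comparison,
      group1 = g1, group2 = g2,
      mean1 = mean(x), mean2 = mean(y), estimate = mean(x) - mean(y),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, p_bonferroni = min(1, tt$p.value * m_tests),
      significant = tt$p.value < alpha / m_tests,
      clustered = TRUE
    )
  }

  out <- list()
  for (st in stages) {
    sub <- cohort[cohort$stage == st, , drop = FALSE]
    for (tr in traits) {
      if ("MZ_vs_DZ" %in% comparisons) {
        out[[length(out) + 1L]] <- run_test(
          sub[[tr]][sub$zygosity == "MZ"], sub[[tr]][sub$zygosity == "DZ"],
          st, tr, "MZ_vs_DZ", "MZ", "DZ"
        )
      }
      if ("M_vs_F" %in% comparisons) {
        out[[length(out) + 1L]] <- run_test(
          sub[[tr]][sub$sex == "M"], sub[[tr]][sub$sex == "F"],
          st, tr, "M_vs_F", "M", "F"
        )
      }
    }
  }
  if ("attrited_vs_retained" %in% comparisons &&
    all(c("mixed", "permanent") %in% stages)) {
    mixed <- cohort[cohort$stage == "mixed", , drop = FALSE]
    followed <- unique(cohort$family_id[cohort$stage == "permanent"])
    for (tr in traits) {
      out[[length(out) + 1L]] <- run_test(
        mixed[[tr]][!(mixed$family_id %in% followed)],
        mixed[[tr]][mixed$family_id %in% followed],
        "mixed", tr, "attrited_vs_retained", "attrited", "retained"
      )
    }
  }
  dplyr::bind_rows(purrr::compact(out))
}

#' Random-intercept linear mixed model for a palatal trait
#'
#' Maximum-likelihood fit of `trait ~ zygosity + sex + stage + (1 |
#' family_id)`: zygosity, sex and dentition stage as fixed effects with a
#' per-family random intercept absorbing the twin-pair clustering.
#'
#' @param cohort A validated cohort tibble.
#' @param trait Trait column name.
#' @param fixed Character vector of fixed-effect terms.
#' @return List of class `twin_lmm`: `model` (the `lmerMod`), `fixed`
#'   (coefficient tibble), `var_family`, `var_residual`.
#' @export
fit_twin_lmm <- function(cohort, trait,
                         fixed = c("zygosity", "sex", "stage")) {
  if (dplyr::n_distinct(cohort$family_id) < 2L) {
    rlang::abort("Need at least 2 families.", class = "palatwin_spec_error")
  }
  fixed <- fixed[vapply(fixed, function(f) dplyr::n_distinct(cohort[[f]]) > 1L, logical(1))]
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  form <- stats::as.formula(sprintf("%s ~ %s + (1 | family_id)", trait, rhs))
  fit <- lme4::lmer(form, data = cohort, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  coefs <- summary(fit)$coefficients
  structure(
    list(
      model = fit,
      fixed = tibble::tibble(
        term = rownames(coefs),
        estimate = coefs[, "Estimate"],
        std_error = coefs[, "Std. Error"],
        statistic = coefs[, "t value"]
      ),
      var_family = vc$vcov[vc$grp == "family_id"],
      var_residual = vc$vcov[vc$grp == "Residual"]
    ),
    class = "twin_lmm"
  )
}
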