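# Simulation of twin trait tables with exact zygosity covariance structure.

# Evaluate code with a temporary RNG state so simulation functions are
# deterministic given `seed` without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_components <- function(components) {
  comp <- c(A = 0, C = 0, D = 0, E = 0)
  if (is.null(names(components)) || !all(names(components) %in% names(comp))) {
    rlang::abort("`components` must be named with a subset of A, C, D, E.",
      class = "palatwin_spec_error"
    )
  }
  comp[names(components)] <- as.numeric(components)
  if (any(comp < 0) || abs(sum(comp) - 1) > 1e-12) {
    rlang::abort("Standardized components must be non-negative and sum to 1.",
      class = "palatwin_spec_error"
    )
  }
  if (comp["C"] > 0 && comp["D"] > 0) {
    rlang::abort(
      "C and D cannot both be positive: they are not simultaneously identifiable in twins raised together.",
      class = "palatwin_spec_error"
    )
  }
  comp
}

# Model-implied within-pair correlations for standardized components.
pair_correlations <- function(comp) {
  c(
    MZ = unname(comp["A"] + comp["C"] + comp["D"]),
    DZ = unname(0.5 * comp["A"] + comp["C"] + 0.25 * comp["D"])
  )
}

#' Simulate twin-pair trait values under the classical twin model
#'
#' Draws one trait for `n_mz` monozygotic and `n_dz` dizygotic pairs from a
#' bivariate normal with common mean and variance and the model-implied
#' within-pair correlations: `r_MZ = A + C + D`, `r_DZ = A/2 + C + D/4` for
#' standardized components A, C, D, E (additive genetic, shared environment,
#' dominance, non-shared environment). Traits are simulated directly at the
#' phenotype level: the classical twin model constrains only these second
#' moments.
#'
#' @param n_mz,n_dz Numbers of MZ and DZ pairs.
#' @param components Named numeric vector of standardized components (subset
#'   of A, C, D, E), non-negative, summing to 1; C and D may not both be
#'   positive.
#' @param mean,sd Trait mean and total phenotypic standard deviation.
#' @param seed Integer seed; the draw is fully deterministic given it.
#' @return Tibble with columns `family_id`, `zygosity`, `value_1`, `value_2`.
#' @export
simulate_twin_pairs <- function(n_mz, n_dz, components, mean = 0, sd = 1,
                                seed = 1L) {
  comp <- check_components(components)
  r <- pair_correlations(comp)
  with_seed(seed, {
    draw <- function(n, rho, zyg, offset) {
      shared <- stats::rnorm(n)
      e1 <- stats::rnorm(n)
      e2 <- stats::rnorm(n)
      x1 <- sqrt(rho) * shared + sqrt(1 - rho) * e1
      x2 <- sqrt(rho) * shared + sqrt(1 - rho) * e2
      tibble::tibble(
        family_id = sprintf("F%04d", offset + seq_len(n)),
        zygosity = zyg,
        value_1 = mean + sd * x1,
        value_2 = mean + sd * x2
      )
    }
    dplyr::bind_rows(
      draw(n_mz, r["MZ"], "MZ", 0L),
      draw(n_dz, r["DZ"], "DZ", n_mz)
    )
  })
}

#' Default longitudinal cohort specification
#'
#' One row per trait and stage combining the reference stage means and
#' standard deviations with the reference standardized variance components
#' (ACE for area and volume in the primary dentition, AE elsewhere). This is
#' the generating configuration for [simulate_cohort()]'s default cohort.
#'
#' @return Tibble with columns `trait`, `stage`, `mean`, `sd`, `A`, `C`,
#'   `D`, `E`.
#' @export
default_cohort_spec <- function() {
  means <- palatal_reference_means()
  comps <- palatal_reference_components()
  out <- dplyr::left_join(
    dplyr::select(means, "stage", "trait", "mean", "sd"),
    dplyr::select(comps, "stage", "trait", "A", "C", "E"),
    by = c("stage", "trait")
  )
  out$C[is.na(out$C)] <- 0
  out$D <- 0
  # renormalize printed (rounded) components to sum exactly to 1
  tot <- out$A + out$C + out$D + out$E
  out$A <- out$A / tot
  out$C <- out$C / tot
  out$E <- out$E / tot
  dplyr::select(out, "trait", "stage", "mean", "sd", "A", "C", "D", "E")
}

stage_age <- function(stage, n) {
  pars <- list(
    primary = c(5.8, 0.7, 3.5, 7.0),
    mixed = c(9.4, 1.0, 6.8, 12.6),
    permanent = c(14.3, 1.0, 11.6, 17.3)
  )[[stage]]
  pmin(pmax(stats::rnorm(n, pars[1], pars[2]), pars[3]), pars[4])
}

#' Simulate a longitudinal twin cohort
#'
#' Generates a long-format cohort (one row per twin per stage) whose traits
#' follow the classical twin model with per-trait, per-stage means, standard
#' deviations and standardized components. Family rosters are nested across
#' stages: when a stage has fewer pairs than the previous one, retained
#' families are chosen uniformly at random (attrition completely at random,
#' so attrited and retained pairs have identical population distributions);
#' when it has more, new families are recruited. Monozygotic co-twins share
#' a sex; dizygotic co-twin sexes are independent. Each trait-stage draw is
#' independent across stages (no within-person longitudinal correlation is
#' imposed; the per-stage analyses never use it).
#'
#' @param trait_spec Tibble like [default_cohort_spec()]: columns `trait`,
#'   `stage`, `mean`, `sd`, `A`, `C`, `D`, `E`.
#' @param n_pairs Named-by-stage list/tibble of pair counts. Default uses
#'   the reference cohort sizes: per-stage MZ/DZ pair counts
#'   104/124 (primary), 106/119 (mixed), 77/93 (permanent).
#' @param seed Integer seed; output is byte-identical given the same inputs.
#' @return A validated cohort tibble (see [validate_cohort()]).
#' @export
simulate_cohort <- function(trait_spec = default_cohort_spec(),
                            n_pairs = NULL, seed = 1L) {
  if (is.null(n_pairs)) {
    counts <- dplyr::distinct(
      palatal_reference_means(), .data$stage, .data$n_mz_pairs, .data$n_dz_pairs
    )
  } else {
    counts <- tibble::as_tibble(n_pairs)
    stopifnot(all(c("stage", "n_mz_pairs", "n_dz_pairs") %in% names(counts)))
  }
  stages <- intersect(c("primary", "mixed", "permanent"), unique(trait_spec$stage))
  counts <- counts[match(stages, counts$stage), , drop = FALSE]

  with_seed(seed, {
    roster_of <- function(zyg, n_prev_ids, n_now, prefix) {
      if (n_now <= length(n_prev_ids)) {
        sort(sample(n_prev_ids, n_now))
      } else {
        c(n_prev_ids, paste0(prefix, sprintf("%04d", length(n_prev_ids) + seq_len(n_now - length(n_prev_ids)))))
      }
    }
    mz_ids <- paste0("MZ", sprintf("%04d", seq_len(counts$n_mz_pairs[1])))
    dz_ids <- paste0("DZ", sprintf("%04d", seq_len(counts$n_dz_pairs[1])))
    all_ids <- c(mz_ids, dz_ids)
    sex1 <- stats::setNames(sample(c("M", "F"), length(all_ids), replace = TRUE), all_ids)
    sex2 <- sex1
    sex2[dz_ids] <- sample(c("M", "F"), length(dz_ids), replace = TRUE)

    out <- list()
    for (i in seq_along(stages)) {
      st <- stages[i]
      if (i > 1L) {
        mz_ids <- roster_of("MZ", mz_ids, counts$n_mz_pairs[i], "MZ")
        dz_ids <- roster_of("DZ", dz_ids, counts$n_dz_pairs[i], "DZ")
        new_ids <- setdiff(c(mz_ids, dz_ids), names(sex1))
        if (length(new_ids) > 0L) {
          s1 <- stats::setNames(sample(c("M", "F"), length(new_ids), replace = TRUE), new_ids)
          s2 <- s1
          is_dz <- startsWith(new_ids, "DZ")
          s2[is_dz] <- sample(c("M", "F"), sum(is_dz), replace = TRUE)
          sex1 <- c(sex1, s1)
          sex2 <- c(sex2, s2)
        }
      }
      fams <- c(mz_ids, dz_ids)
      zyg <- ifelse(startsWith(fams, "MZ"), "MZ", "DZ")
      n_mz <- length(mz_ids)
      n_dz <- length(dz_ids)
      age <- stage_age(st, length(fams))

      stage_tbl <- tibble::tibble(
        family_id = rep(fams, each = 2L),
        twin_id = paste0(rep(fams, each = 2L), "_", rep(1:2, length(fams))),
        zygosity = rep(zyg, each = 2L),
        sex = as.vector(rbind(sex1[fams], sex2[fams])),
        stage = st,
        age = round(rep(age, each = 2L) + rep(c(0, 0), length(fams)), 1)
      )
      spec_st <- trait_spec[trait_spec$stage == st, , drop = FALSE]
      for (j in seq_len(nrow(spec_st))) {
        row <- spec_st[j, ]
        comp <- c(A = row$A, C = row$C, D = row$D, E = row$E)
        r <- pair_correlations(check_components(comp))
        rho <- ifelse(zyg == "MZ", r["MZ"], r["DZ"])
        shared <- stats::rnorm(length(fams))
        e <- matrix(stats::rnorm(2L * length(fams)), ncol = 2L)
        vals <- row$mean + row$sd *
          (sqrt(rho) * cbind(shared, shared) + sqrt(1 - rho) * e)
        stage_tbl[[row$trait]] <- as.vector(t(vals))
      }
      out[[i]] <- stage_tbl
    }
    validate_cohort(dplyr::bind_rows(out))
  })
}
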