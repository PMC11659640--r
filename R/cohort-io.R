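TRAIT_NAMES <- c(
  "anterior_width", "posterior_width", "anterior_depth",
  "posterior_depth", "ap_length", "area", "volume"
)

#' Validate a twin cohort table
#'
#' A cohort table is long format: one row per twin per dentition stage, with
#' columns `twin_id`, `family_id`, `zygosity` (MZ/DZ), `sex` (M/F), `stage`
#' (primary/mixed/permanent), `age` (years) and one column per measured
#' palatal trait (mm, mm^2 or mm^3 as appropriate). Validation enforces the
#' twin-pair structure: zygosity must be constant within a family (an error,
#' since it indicates corrupted records), and any family contributing a
#' number of twins other than two at a stage is excluded from that stage with
#' a message. Validation is idempotent.
#'
#' @param cohort A data frame of cohort records.
#' @return A validated tibble.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  needed <- c("twin_id", "family_id", "zygosity", "sex", "stage")
  miss <- setdiff(needed, names(cohort))
  if (length(miss) > 0L) {
    rlang::abort(sprintf("Cohort table lacks column(s): %s", paste(miss, collapse = ", ")),
      class = "palatwin_format_error"
    )
  }
  if (!all(cohort$zygosity %in% c("MZ", "DZ"))) {
    rlang::abort("`zygosity` must be 'MZ' or 'DZ'.", class = "palatwin_format_error")
  }
  if (!all(cohort$stage %in% c("primary", "mixed", "permanent"))) {
    rlang::abort("`stage` must be primary/mixed/permanent.",
      class = "palatwin_format_error"
    )
  }
  zyg <- dplyr::summarise(dplyr::group_by(cohort, .data$family_id),
    n_zyg = dplyr::n_distinct(.data$zygosity), .groups = "drop"
  )
  if (any(zyg$n_zyg > 1L)) {
    bad <- zyg$family_id[zyg$n_zyg > 1L]
    rlang::abort(sprintf(
      "Zygosity differs within family/families: %s",
      paste(bad, collapse = ", ")
    ), class = "palatwin_validation_error")
  }
  sizes <- dplyr::count(cohort, .data$family_id, .data$stage, name = "n_twins")
  bad <- dplyr::filter(sizes, .data$n_twins != 2L)
  if (nrow(bad) > 0L) {
    message(sprintf(
      "Excluded %d family-stage group(s) without exactly two twins: %s",
      nrow(bad),
      paste(sprintf("%s/%s", bad$family_id, bad$stage), collapse = ", ")
    ))
    cohort <- dplyr::anti_join(cohort, bad, by = c("family_id", "stage"))
  }
  cohort
}

#' Read a twin cohort table from CSV
#'
#' @param path Path to a UTF-8 CSV file with a header row (see
#'   [validate_cohort()] for the column contract).
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(tbl)
}

#' Write a twin cohort table to CSV
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

fmt_ci <- function(lo, hi) {
  ifelse(is.na(lo) | is.na(hi), "", sprintf("%.6f–%.6f", lo, hi))
}

#' Write a variance-component fit report
#'
#' Writes one CSV row per fit with the layout of a classical twin-study
#' results table: trait, stage, model, AIC, the standardized A/C/D/E
#' components each followed by its 95% CI, and narrow-sense heritability.
#' Components absent from a model are left empty.
#'
#' @param fits A list of `twin_fit` objects (see [fit_twin_model()]), or a
#'   single `twin_fit`.
#' @param path Output CSV path.
#' @return The report tibble, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  if (inherits(fits, "twin_fit")) fits <- list(fits)
  if (length(fits) == 0L) {
    rlang::abort("Empty fit list; nothing to report.",
      class = "palatwin_format_error"
    )
  }
  rows <- purrr::map_dfr(fits, function(fit) {
    stopifnot(inherits(fit, "twin_fit"))
    comp <- fit$standardized
    ci <- fit$ci95
    present <- c(TWIN_MODELS[[fit$model]], "E")
    get <- function(k) if (k %in% present) unname(comp[k]) else NA_real_
    ci_of <- function(k) {
      if (!is.null(ci) && k %in% rownames(ci)) {
        fmt_ci(ci[k, 1], ci[k, 2])
      } else {
        ""
      }
    }
    tibble::tibble(
      trait = fit$trait %||% NA_character_,
      stage = fit$stage %||% NA_character_,
      model = fit$model,
      AIC = fit$aic,
      A = get("A"), A_CI = ci_of("A"),
      C = get("C"), C_CI = ci_of("C"),
      D = get("D"), D_CI = ci_of("D"),
      E = get("E"), E_CI = ci_of("E"),
      h2 = fit$h2
    )
  })
  readr::write_csv(rows, path, progress = FALSE, na = "")
  invisible(rows)
}

#' Read back a fit report written by [write_fit_report()]
#'
#' @param path CSV path.
#' @return A tibble with the report columns; CI strings are parsed into
#'   `<component>_lo` / `<component>_hi` numeric columns.
#' @export
read_fit_report <- function(path) {
  tbl <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      trait = "c", stage = "c", model = "c",
      A_CI = "c", C_CI = "c", D_CI = "c", E_CI = "c",
      .default = "d"
    )
  )
  for (k in c("A", "C", "D", "E")) {
    raw <- tbl[[paste0(k, "_CI")]]
    parts <- strsplit(ifelse(is.na(raw), "", raw), "–", fixed = TRUE)
    tbl[[paste0(k, "_lo")]] <- vapply(parts, function(p) {
      if (length(p) == 2L) as.numeric(p[1]) else NA_real_
    }, numeric(1))
    tbl[[paste0(k, "_hi")]] <- vapply(parts, function(p) {
      if (length(p) == 2L) as.numeric(p[2]) else NA_real_
    }, numeric(1))
  }
  tbl
}

#' Read a YAML run configuration
#'
#' @param path YAML file path.
#' @param allowed Character vector of permitted top-level keys; any other key
#'   is rejected so that typos never silently fall back to defaults.
#' @return Named list.
#' @export
read_run_config <- function(path, allowed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(allowed)) {
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown) > 0L) {
      rlang::abort(sprintf(
        "Unknown configuration key(s): %s",
        paste(unknown, collapse = ", ")
      ), class = "palatwin_format_error")
    }
  }
  cfg
}
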