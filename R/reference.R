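# Published summary statistics of a longitudinal twin study of palatal
# development, embedded as reference tibbles. These are the study conditions the
# synthetic-data generator emulates and the anchors for the
# parameter-recovery checks; they are inputs, never outputs, of this package.

#' Reference palatal trait means by dentition stage
#'
#' Overall mean and standard deviation of the seven palatal traits at the
#' primary, mixed and permanent dentition stages, with the published percent
#' change from the primary dentition and per-stage record counts
#' (individuals, and monozygotic/dizygotic pair counts).
#'
#' @return Tibble with columns `stage`, `trait`, `mean`, `sd`, `pct_change`,
#'   `n`, `n_mz_pairs`, `n_dz_pairs`. Units: mm for linear traits, mm^2 for
#'   `area`, mm^3 for `volume`.
#' @export
palatal_reference_means <- function() {
  counts <- tibble::tibble(
    stage = c("primary", "mixed", "permanent"),
    n = c(456L, 450L, 340L),
    n_mz_pairs = c(104L, 106L, 77L),
    n_dz_pairs = c(124L, 119L, 93L)
  )
  vals <- tibble::tribble(
    ~stage, ~trait, ~mean, ~sd, ~pct_change,
    "primary", "area", 753.7, 78.4, NA,
    "primary", "volume", 2630.1, 471.7, NA,
    "primary", "anterior_width", 22.1, 1.9, NA,
    "primary", "posterior_width", 27.4, 2.1, NA,
    "primary", "anterior_depth", 4.6, 1.2, NA,
    "primary", "posterior_depth", 10.6, 1.3, NA,
    "primary", "ap_length", 25.3, 1.6, NA,
    "mixed", "area", 1240.7, 116.2, 64.6,
    "mixed", "volume", 5338.2, 905.0, 103.0,
    "mixed", "anterior_width", 24.7, 1.9, 11.7,
    "mixed", "posterior_width", 31.9, 2.3, 16.5,
    "mixed", "anterior_depth", 4.5, 1.3, -1.3,
    "mixed", "posterior_depth", 10.6, 1.7, 0.5,
    "mixed", "ap_length", 35.8, 2.1, 41.1,
    "permanent", "area", 1266.8, 146.1, 68.1,
    "permanent", "volume", 6169.4, 1121.5, 134.6,
    "permanent", "anterior_width", 23.9, 2.1, 8.2,
    "permanent", "posterior_width", 33.5, 2.8, 22.3,
    "permanent", "anterior_depth", 4.7, 1.6, 2.4,
    "permanent", "posterior_depth", 13.2, 2.1, 25.1,
    "permanent", "ap_length", 34.9, 2.3, 37.8
  )
  dplyr::left_join(vals, counts, by = "stage")
}

#' Reference variance-component estimates by trait and stage
#'
#' Best-fitting model, AIC, standardized variance components with 95%
#' confidence intervals, and narrow-sense heritability for each palatal
#' trait at each dentition stage, as estimated on the twin cohort. The
#' ACE decomposition applies to area and volume in the primary dentition;
#' the AE model fits everywhere else.
#'
#' @return Tibble with columns `stage`, `trait`, `model`, `aic`, `A`,
#'   `A_lo`, `A_hi`, `C`, `C_lo`, `C_hi`, `E`, `E_lo`, `E_hi`, `h2`.
#' @export
palatal_reference_components <- function() {
  tibble::tribble(
    ~stage, ~trait, ~model, ~aic, ~A, ~A_lo, ~A_hi, ~C, ~C_lo, ~C_hi, ~E, ~E_lo, ~E_hi, ~h2,
    "primary", "area", "ACE", 3792.5, 0.37, 0.15, 0.51, 0.32, 0.16, 0.43, 0.31, 0.24, 0.41, 0.37,
    "primary", "volume", "ACE", 4968.6, 0.37, 0.22, 0.48, 0.38, 0.26, 0.46, 0.25, 0.19, 0.31, 0.37,
    "primary", "anterior_width", "AE", 1272.1, 0.84, 0.77, 0.88, NA, NA, NA, 0.16, 0.11, 0.23, 0.84,
    "primary", "posterior_width", "AE", 1342.7, 0.85, 0.78, 0.89, NA, NA, NA, 0.15, 0.11, 0.22, 0.85,
    "primary", "anterior_depth", "AE", 1039.4, 0.70, 0.59, 0.78, NA, NA, NA, 0.30, 0.22, 0.40, 0.70,
    "primary", "posterior_depth", "AE", 1038.8, 0.89, 0.84, 0.92, NA, NA, NA, 0.11, 0.07, 0.15, 0.89,
    "primary", "ap_length", "AE", 1243.3, 0.73, 0.63, 0.80, NA, NA, NA, 0.27, 0.19, 0.36, 0.73,
    "mixed", "area", "AE", 4586.2, 0.53, 0.41, 0.63, NA, NA, NA, 0.47, 0.36, 0.58, 0.53,
    "mixed", "volume", "AE", 6057.4, 0.68, 0.60, 0.74, NA, NA, NA, 0.32, 0.25, 0.39, 0.68,
    "mixed", "anterior_width", "AE", 1490.2, 0.76, 0.67, 0.82, NA, NA, NA, 0.24, 0.17, 0.32, 0.76,
    "mixed", "posterior_width", "AE", 1557.8, 0.82, 0.74, 0.86, NA, NA, NA, 0.18, 0.13, 0.25, 0.82,
    "mixed", "anterior_depth", "AE", 1177.6, 0.78, 0.71, 0.84, NA, NA, NA, 0.22, 0.15, 0.28, 0.78,
    "mixed", "posterior_depth", "AE", 1315.6, 0.89, 0.85, 0.92, NA, NA, NA, 0.11, 0.07, 0.14, 0.89,
    "mixed", "ap_length", "AE", 1508.9, 0.75, 0.66, 0.82, NA, NA, NA, 0.25, 0.17, 0.33, 0.75,
    "permanent", "area", "AE", 3562.5, 0.56, 0.44, 0.66, NA, NA, NA, 0.44, 0.33, 0.55, 0.56,
    "permanent", "volume", "AE", 4641.9, 0.82, 0.76, 0.86, NA, NA, NA, 0.18, 0.13, 0.23, 0.82,
    "permanent", "anterior_width", "AE", 1150.7, 0.69, 0.56, 0.78, NA, NA, NA, 0.31, 0.21, 0.43, 0.69,
    "permanent", "posterior_width", "AE", 1265.8, 0.86, 0.79, 0.90, NA, NA, NA, 0.14, 0.09, 0.20, 0.86,
    "permanent", "anterior_depth", "AE", 1023.6, 0.70, 0.58, 0.78, NA, NA, NA, 0.30, 0.21, 0.41, 0.70,
    "permanent", "posterior_depth", "AE", 1100.9, 0.86, 0.79, 0.89, NA, NA, NA, 0.14, 0.10, 0.20, 0.86,
    "permanent", "ap_length", "AE", 1191.5, 0.83, 0.75, 0.88, NA, NA, NA, 0.17, 0.11, 0.24, 0.83
  )
}
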