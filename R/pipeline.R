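# End-to-end pipeline commands: simulate -> measure -> describe -> fit.
# Each takes explicit arguments or a YAML configuration (every stochastic
# step requires an explicit seed; unknown configuration keys are rejected).

#' Simulate a synthetic dataset to disk
#'
#' Writes a simulated twin cohort CSV and, optionally, synthetic palate
#' casts (STL mesh + landmark JSON per cast), plus a manifest recording the
#' seed and a hash of the generating specification so that identical
#' configurations are recognizably identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; required, there is no implicit randomness.
#' @param trait_spec Generating spec tibble (see [default_cohort_spec()]).
#' @param n_pairs Optional per-stage pair counts (see [simulate_cohort()]).
#' @param n_casts Number of synthetic casts to write (0 for none).
#' @param cast_stage Dentition stage of the synthetic casts.
#' @param edge_length,asymmetry Mesh generator parameters (mm).
#' @return Invisibly, a list with the cohort tibble and the manifest.
#' @export
run_simulate <- function(out_dir, seed, trait_spec = default_cohort_spec(),
                         n_pairs = NULL, n_casts = 0L, cast_stage = "primary",
                         edge_length = 0.5, asymmetry = 0) {
  if (missing(seed) || is.null(seed)) {
    rlang::abort("`seed` is required; no implicit randomness.",
      class = "palatwin_spec_error"
    )
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(trait_spec = trait_spec, n_pairs = n_pairs, seed = seed)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  cast_files <- character()
  if (n_casts > 0L) {
    ref <- palatal_reference_means()
    for (i in seq_len(n_casts)) {
      sub_seed <- derive_seed(seed, i)
      dims <- with_seed(sub_seed, {
        ref_st <- ref[ref$stage == cast_stage, ]
        v <- stats::setNames(
          stats::rnorm(nrow(ref_st), ref_st$mean, ref_st$sd), ref_st$trait
        )
        # keep the sampled shape geometrically consistent
        v["anterior_depth"] <- min(v["anterior_depth"], v["posterior_depth"] - 0.5)
        v["anterior_width"] <- min(v["anterior_width"], v["posterior_width"] - 0.5)
        v
      })
      shape <- palate_shape(
        anterior_width = dims[["anterior_width"]],
        posterior_width = dims[["posterior_width"]],
        anterior_depth = dims[["anterior_depth"]],
        posterior_depth = dims[["posterior_depth"]],
        ap_length = dims[["ap_length"]],
        edge_length = edge_length, asymmetry = asymmetry, seed = sub_seed
      )
      cast_id <- sprintf("cast%03d", i)
      gen <- generate_palate(shape, stage = cast_stage, cast_id = cast_id)
      write_palate_mesh(gen$mesh, file.path(out_dir, paste0(cast_id, ".stl")),
        format = "binary"
      )
      write_landmarks(gen$landmarks, file.path(out_dir, paste0(cast_id, ".json")))
      cast_files <- c(cast_files, cast_id)
    }
  }
  manifest <- list(
    seed = seed,
    spec_hash = rlang::hash(list(trait_spec, n_pairs, n_casts, cast_stage, edge_length, asymmetry)),
    n_records = nrow(cohort),
    casts = as.list(cast_files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(list(cohort = cohort, manifest = manifest))
}

#' Measure palatal traits for a set of casts
#'
#' Pairs STL meshes with landmark JSON files by basename, measures each cast
#' with [measure_palate()], and writes one trait row per cast. Casts that
#' fail are skipped and named in messages; the `status` attribute of the
#' result is 0 if all casts succeeded, 1 if any was skipped.
#'
#' @param mesh_paths Character vector of STL paths.
#' @param landmark_paths Character vector of JSON paths (matched to
#'   `mesh_paths` by basename).
#' @param out Optional CSV output path.
#' @param eps Raphe band half-width for depth measurement (mm).
#' @return Tibble of per-cast traits with a `status` attribute.
#' @export
run_measure <- function(mesh_paths, landmark_paths, out = NULL, eps = 0.5) {
  if (length(mesh_paths) == 0L) {
    rlang::abort("Empty cast list.", class = "palatwin_spec_error")
  }
  key <- function(p) sub("\\.[^.]+$", "", basename(p))
  lm_idx <- match(key(mesh_paths), key(landmark_paths))
  if (anyNA(lm_idx)) {
    rlang::abort(sprintf(
      "No landmark file for cast(s): %s",
      paste(key(mesh_paths)[is.na(lm_idx)], collapse = ", ")
    ), class = "palatwin_spec_error")
  }
  status <- 0L
  rows <- purrr::map(seq_along(mesh_paths), function(i) {
    tryCatch(
      {
        mesh <- read_palate_mesh(mesh_paths[i])
        lm <- read_landmarks(landmark_paths[lm_idx[i]])
        measure_palate(mesh, lm, eps = eps)
      },
      error = function(e) {
        status <<- 1L
        message(sprintf(
          "skipped cast=%s reason=%s", key(mesh_paths)[i], conditionMessage(e)
        ))
        NULL
      }
    )
  })
  out_tbl <- dplyr::bind_rows(purrr::compact(rows))
  if (!is.null(out)) readr::write_csv(out_tbl, out, progress = FALSE)
  attr(out_tbl, "status") <- status
  out_tbl
}

#' Descriptive report of a cohort
#'
#' Produces the stage-by-trait descriptive table with a percent-change
#' column (overall means relative to the primary dentition) and the
#' Bonferroni-corrected group comparisons.
#'
#' @param cohort A validated cohort tibble (or a CSV path).
#' @param out_dir Optional directory for CSV outputs.
#' @param alpha,m_tests Passed to [group_comparisons()].
#' @return List with `descriptives` (including `pct_change`) and
#'   `comparisons`.
#' @export
run_describe <- function(cohort, out_dir = NULL, alpha = 0.05, m_tests = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  desc <- descriptive_table(cohort)
  overall <- desc[desc$group == "Overall", c("stage", "trait", "mean")]
  baseline <- overall[overall$stage == "primary", c("trait", "mean")]
  names(baseline)[2] <- "mean_primary"
  desc <- dplyr::left_join(desc, baseline, by = "trait")
  desc$pct_change <- ifelse(
    desc$group == "Overall" & desc$stage != "primary" & !is.na(desc$mean_primary),
    percent_change(desc$mean, desc$mean_primary), NA_real_
  )
  desc$mean_primary <- NULL
  cmps <- group_comparisons(cohort, alpha = alpha, m_tests = m_tests)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(desc, file.path(out_dir, "descriptives.csv"), progress = FALSE)
    readr::write_csv(cmps, file.path(out_dir, "comparisons.csv"), progress = FALSE)
  }
  list(descriptives = desc, comparisons = cmps)
}

#' Variance-component report of a cohort
#'
#' Fits and selects twin models for every trait and stage, writes the fit
#' report and a per-cell decision-trace log.
#'
#' @param cohort A validated cohort tibble (or a CSV path).
#' @param out_dir Optional directory for the report CSV and trace log.
#' @param candidates,alpha Passed to [fit_twin_models()].
#' @return The [fit_twin_models()] result tibble.
#' @export
run_fit <- function(cohort, out_dir = NULL,
                    candidates = c("ACE", "ADE", "AE", "CE", "E"), alpha = 0.05) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  res <- fit_twin_models(cohort, candidates = candidates, alpha = alpha)
  if (!is.null(out_dir) && nrow(res) > 0L) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fits <- purrr::pmap(res, function(trait, stage, selection, ...) {
      f <- selection$selected
      f$trait <- trait
      f$stage <- stage
      f
    })
    write_fit_report(fits, file.path(out_dir, "fit_report.csv"))
    trace_lines <- purrr::pmap(res, function(trait, stage, selection, ...) {
      cmp <- selection$comparisons
      c(
        sprintf("== %s / %s: selected %s ==", trait, stage, selection$selected$model),
        sprintf(
          "  LRT %s vs %s: delta=%.4f df=%d p=%.4g",
          cmp$full, cmp$sub, cmp$delta_m2ll, cmp$df, cmp$p
        ),
        sprintf(
          "  AIC %s: %.2f%s", selection$aic$model, selection$aic$aic,
          ifelse(selection$aic$survives_lrt, "", " (rejected by LRT)")
        )
      )
    })
    writeLines(unlist(trace_lines), file.path(out_dir, "decision_trace.txt"))
  }
  res
}
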