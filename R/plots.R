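# ggplot2 visualisations of fitted objects and result tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the standardized components of a twin fit
#'
#' Bar chart of the standardized A/C/D/E variance components with their 95%
#' profile-likelihood intervals.
#'
#' @param object A `twin_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twin_fit
#' @export
autoplot.twin_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Variance component", y = "Standardized proportion",
      title = sprintf("%s model (h² = %.2f)", object$model, object$h2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the AIC profile of a model selection
#'
#' @param object A `twin_model_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twin_model_selection
#' @export
autoplot.twin_model_selection <- function(object, ...) {
  tbl <- object$aic
  tbl$selected <- tbl$model == object$selected$model
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = stats::reorder(.data$model, .data$aic), y = .data$aic,
    fill = .data$selected
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60")) +
    ggplot2::labs(x = "Model", y = "AIC") +
    ggplot2::theme_minimal()
}

#' Heritability trajectories across dentition stages
#'
#' Line plot of narrow-sense heritability per trait across the primary,
#' mixed and permanent dentition stages, from a [fit_twin_models()] result
#' table (or any tibble with `trait`, `stage` and `h2` columns).
#'
#' @param fit_table Tibble with `trait`, `stage`, `h2`.
#' @return A ggplot object.
#' @export
plot_heritability <- function(fit_table) {
  fit_table$stage <- factor(fit_table$stage, c("primary", "mixed", "permanent"))
  ggplot2::ggplot(fit_table, ggplot2::aes(
    x = .data$stage, y = .data$h2, group = .data$trait, colour = .data$trait
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Dentition stage", y = expression(h^2),
      colour = "Trait"
    ) +
    ggplot2::theme_minimal()
}

#' Plot ICC by zygosity
#'
#' Dot plot of within-pair intraclass correlations for MZ and DZ twins per
#' trait and stage, from a [twin_icc()] table.
#'
#' @param icc_table Tibble with `trait`, `stage`, `zygosity`, `icc`.
#' @return A ggplot object.
#' @export
plot_twin_icc <- function(icc_table) {
  icc_table$stage <- factor(icc_table$stage, c("primary", "mixed", "permanent"))
  ggplot2::ggplot(icc_table, ggplot2::aes(
    x = .data$icc, y = .data$trait, colour = .data$zygosity
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Within-pair ICC", y = NULL, colour = "Zygosity") +
    ggplot2::theme_minimal()
}
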