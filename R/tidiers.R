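# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @exportS3Method generics::tidy
tidy.mdr_search_result <- function(x, ...) {
  x$pareto_front |>
    dplyr::select("snp_ids", "t_statistic", "interaction_info", "size",
                  "pareto_rank", "valid")
}

#' @exportS3Method generics::glance
glance.mdr_search_result <- function(x, ...) {
  tibble::tibble(
    engine = x$engine,
    evaluations = x$evaluations,
    front_size = nrow(x$pareto_front),
    best_t = if (nrow(x$pareto_front)) max(x$pareto_front$t_statistic) else NA_real_,
    best_model = if (nrow(x$pareto_front)) {
      x$pareto_front$snp_ids[[which.max(x$pareto_front$t_statistic)]]
    } else NA_character_,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' @exportS3Method generics::tidy
tidy.epistasis_experiment <- function(x, ...) x$cells

#' @exportS3Method generics::glance
glance.epistasis_experiment <- function(x, ...) {
  x$cells |>
    dplyr::group_by(.data$engine) |>
    dplyr::summarise(
      cells = dplyr::n(),
      mean_success_rate = mean(.data$success_rate),
      .groups = "drop"
    ) |>
    dplyr::mutate(criterion = x$criterion, budget = x$budget)
}

#' @exportS3Method generics::tidy
tidy.cell_result <- function(x, ...) x$detail

#' @exportS3Method generics::glance
glance.cell_result <- function(x, ...) {
  dplyr::bind_cols(spec_summary_cols(x$spec)[rep(1L, nrow(x$summary)), ],
                   x$summary)
}

#' Pareto-front scatter of a search result
#'
#' t-statistic against mean interaction information, point size mapped to
#' model order: the three objectives of the search on one panel.
#'
#' @param object An `mdr_search_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mdr_search_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_statistic,
                                   y = .data$interaction_info,
                                   size = .data$size)) +
    ggplot2::geom_point(alpha = 0.7, colour = "#d03d6c") +
    ggplot2::scale_size_continuous(breaks = function(lims) {
      unique(round(pretty(lims)))
    }) +
    ggplot2::labs(
      x = "QMDR t-statistic",
      y = "Mean interaction information (bits)",
      size = "Model size (K)",
      title = sprintf("Pareto front (%s search, %d models)",
                      object$engine, nrow(df))
    ) +
    ggplot2::theme_minimal()
}

#' Success-rate heatmap of a simulation study
#'
#' Detection success rate per grid cell, heritability by trait standard
#' deviation, faceted by engine and sample size (and gene count when the
#' grid varies it).
#'
#' @param object An `epistasis_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.epistasis_experiment <- function(object, ...) {
  df <- object$cells
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$trait_sd),
                                        y = factor(.data$heritability),
                                        fill = .data$success_rate)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Trait standard deviation", y = "Heritability",
                  fill = "Success rate",
                  title = sprintf("Detection success (criterion: %s)",
                                  object$criterion)) +
    ggplot2::theme_minimal()
  facets <- c("engine",
              if (dplyr::n_distinct(df$n_samples) > 1) "n_samples",
              if (dplyr::n_distinct(df$n_genes) > 1) "n_genes",
              if (dplyr::n_distinct(df$maf) > 1) "maf")
  p + ggplot2::facet_wrap(facets, labeller = ggplot2::label_both)
}
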