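#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_col
#'   geom_text scale_fill_viridis_c labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Heatmap of the tuning grid
#'
#' F-measure over the `(tau, lambda)` grid with the selected cell marked.
#'
#' @param object an `ehr_tuning` from [grid_tune()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ehr_tuning <- function(object, ...) {
  grid <- object$grid
  ggplot(grid, aes(x = factor(.data$tau), y = factor(.data$lambda),
                   fill = .data$f_measure)) +
    geom_tile() +
    geom_point(data = grid |>
                 filter(.data$tau == object$best_tau,
                        .data$lambda == object$best_lambda),
               shape = 21, size = 4, fill = "white") +
    scale_fill_viridis_c(name = "F") +
    labs(x = expression(tau ~ "(dissimilarity threshold)"),
         y = expression(lambda ~ "(confidence threshold)"),
         title = sprintf("Threshold tuning (%s, %s concepts)",
                         object$measure_config$measure, object$mode)) +
    theme_minimal()
}

#' Confidence profile of a prediction table
#'
#' @param object an `ehr_predictions` from [predict_concepts()].
#' @param top_n show at most this many concepts (highest confidence first).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ehr_predictions <- function(object, top_n = 25L, ...) {
  dat <- as_tibble(object) |>
    arrange(desc(.data$confidence)) |>
    head(top_n) |>
    mutate(concept = factor(.data$concept, levels = rev(.data$concept)))
  ggplot(dat, aes(x = .data$confidence, y = .data$concept)) +
    geom_col() +
    labs(x = "confidence |S'_c| / |S|", y = NULL,
         title = sprintf("Predicted concepts (%d matched suffixes)",
                         attr(object, "n_matches") %||% NA_integer_)) +
    theme_minimal()
}

#' Visit-length and concept-volume profile of a cohort
#'
#' @param object an `ehr_cohort_stats` from [cohort_statistics()].
#' @param ... unused.
#' @return A ggplot of the visit-length distribution annotated with the mean
#'   unique concepts per visit length.
#' @export
autoplot.ehr_cohort_stats <- function(object, ...) {
  dat <- object$visit_length_pct |>
    left_join(object$unique_by_length, by = "n_events")
  ggplot(dat, aes(x = factor(.data$n_events), y = .data$pct)) +
    geom_col() +
    geom_text(aes(label = sprintf("%.0f concepts", .data$mean_unique_concepts)),
              vjust = -0.4, size = 3) +
    labs(x = "events per visit", y = "% of visits",
         title = sprintf("%d visits; %.0f concepts/event on average",
                         object$n_visits, object$mean_concepts_per_event)) +
    theme_minimal()
}
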