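#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the tuning grid
#'
#' @param x an `ehr_tuning` from [grid_tune()].
#' @param ... unused.
#' @return The per-cell grid tibble (`tau`, `lambda`, pooled counts, metrics).
#' @export
tidy.ehr_tuning <- function(x, ...) x$grid

#' One-row summary of a tuning run
#'
#' @param x an `ehr_tuning` from [grid_tune()].
#' @param ... unused.
#' @return A one-row tibble with the selected thresholds and their pooled
#'   metrics.
#' @export
glance.ehr_tuning <- function(x, ...) {
  x$grid |>
    filter(.data$tau == x$best_tau, .data$lambda == x$best_lambda) |>
    mutate(measure = x$measure_config$measure, mode = x$mode,
           n_cases = x$n_cases, .before = 1L) |>
    select(-"undefined")
}

#' Tidy a match set
#'
#' @param x an `ehr_matchset` from [find_similar_records()].
#' @param ... unused.
#' @return A plain tibble with `visit_id`, `best_k`, `dissimilarity` and
#'   suffix sizes.
#' @export
tidy.ehr_matchset <- function(x, ...) {
  as_tibble(x) |>
    mutate(suffix_size = lengths(.data$suffix)) |>
    select("visit_id", "best_k", "dissimilarity", "suffix_size")
}

#' Tidy a prediction table
#'
#' @param x an `ehr_predictions` from [predict_concepts()].
#' @param ... unused.
#' @return A plain tibble with `concept`, `confidence`, `support`.
#' @export
tidy.ehr_predictions <- function(x, ...) {
  as_tibble(x) |> select("concept", "confidence", "support")
}

#' One-row summary of cohort descriptive statistics
#'
#' Flattens [cohort_statistics()] into the calibration quantities: the
#' percentage of 2- and 3-event visits, the mean concepts per event, the mean
#' unique concepts per visit (overall and for 2-event visits), and the
#' disorders share of per-visit unique concepts (when semantic groups were
#' available).
#'
#' @param x an `ehr_cohort_stats` from [cohort_statistics()].
#' @param ... unused.
#' @return A one-row tibble.
#' @export
glance.ehr_cohort_stats <- function(x, ...) {
  pct_of <- function(len) {
    r <- x$visit_length_pct |> filter(.data$n_events == len)
    if (nrow(r)) r$pct else 0
  }
  uniq_of <- function(len) {
    r <- x$unique_by_length |> filter(.data$n_events == len)
    if (nrow(r)) r$mean_unique_concepts else NA_real_
  }
  disorders <- NA_real_
  if (!is.null(x$group_shares)) {
    r <- x$group_shares |> filter(.data$semantic_group == "disorders")
    if (nrow(r)) disorders <- r$pct
  }
  tibble(n_visits = x$n_visits, n_events = x$n_events,
         pct_two_event = pct_of(2L), pct_three_event = pct_of(3L),
         mean_concepts_per_event = x$mean_concepts_per_event,
         mean_unique_per_visit = x$mean_unique_per_visit,
         mean_unique_two_event = uniq_of(2L),
         pct_disorders = disorders)
}
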