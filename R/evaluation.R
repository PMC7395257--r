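#' Build held-out query cases from a cohort
#'
#' Every visit with at least two events yields query cases: the prefix at
#' split `k` is the query, the suffix is the ground truth. `all_k` emits one
#' case per valid split per visit; `first_k_only` emits only `k = 1`.
#'
#' @param cohort an [ehr_cohort].
#' @param mode `"all_k"` (default) or `"first_k_only"`.
#' @return A tibble with columns `visit_id`, `k`, and list-columns
#'   `query_prefix`, `truth_suffix`.
#' @export
make_query_cases <- function(cohort, mode = c("all_k", "first_k_only")) {
  mode <- match.arg(mode)
  structs <- visit_structures(cohort)
  if (mode == "first_k_only") structs <- structs |> filter(.data$k == 1L)
  structs |>
    rename(query_prefix = "prefix", truth_suffix = "suffix") |>
    select("visit_id", "k", "query_prefix", "truth_suffix")
}

#' Confusion counts of a predicted concept set against a truth suffix
#'
#' In `all` mode: `TP = |predicted & truth|`, `FP = |predicted \ truth|`,
#' `FN = |truth \ predicted|`, `TN = |universe \ (predicted | truth)|`. In
#' `fresh` mode the query prefix's concepts are first removed from the
#' predicted set, the truth and the universe — concepts already present in the
#' prefix tend to persist into the suffix and would otherwise dominate the
#' accounting — and the same arithmetic is then applied. The four counts
#' always partition the (possibly reduced) universe.
#'
#' @param predicted character vector of predicted concept ids (must lie in
#'   `universe`).
#' @param truth character vector of true suffix concept ids (must lie in
#'   `universe`).
#' @param universe character vector: the concept universe `U`.
#' @param mode `"all"` or `"fresh"`.
#' @param prefix the query prefix concept set (required for `"fresh"`).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `universe_size`, `mode`.
#' @export
confusion_counts <- function(predicted, truth, universe,
                             mode = c("all", "fresh"), prefix = character(0)) {
  mode <- match.arg(mode)
  predicted <- as_concept_set(predicted)
  truth <- as_concept_set(truth)
  universe <- as_concept_set(universe)
  if (length(setdiff(truth, universe))) {
    abort("`truth` contains concepts outside the universe.")
  }
  if (length(setdiff(predicted, universe))) {
    abort("`predicted` contains concepts outside the universe.")
  }
  if (mode == "fresh") {
    prefix <- as_concept_set(prefix)
    predicted <- setdiff(predicted, prefix)
    truth <- setdiff(truth, prefix)
    universe <- setdiff(universe, prefix)
  }
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- length(universe) - tp - fp - fn
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         universe_size = length(universe), mode = mode)
}

#' Sensitivity, specificity, precision and F-measure from confusion counts
#'
#' `F` is the harmonic mean of sensitivity and precision (specificity is
#' reported but not used for model selection: a large concept universe makes
#' the true-negative count dominate it). Ratios with a zero denominator (0/0)
#' are reported as 0 and flagged in the `undefined` list-column.
#'
#' @param counts a tibble with columns `tp`, `fp`, `fn`, `tn` (one row per
#'   pooled evaluation).
#' @return `counts` with added columns `sensitivity`, `specificity`,
#'   `precision`, `f_measure` and list-column `undefined` naming any 0/0
#'   metrics.
#' @export
compute_metrics <- function(counts) {
  counts <- as_tibble(counts)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  sens <- safe_div(counts$tp, counts$tp + counts$fn)
  spec <- safe_div(counts$tn, counts$tn + counts$fp)
  prec <- safe_div(counts$tp, counts$tp + counts$fp)
  f <- ifelse(prec + sens == 0, 0, 2 * prec * sens / (prec + sens))
  undefined <- pmap(list(counts$tp + counts$fn, counts$tn + counts$fp,
                         counts$tp + counts$fp, prec + sens),
                    function(ds, dsp, dp, df) {
                      c("sensitivity", "specificity", "precision", "f_measure")[
                        c(ds == 0, dsp == 0, dp == 0, df == 0)]
                    })
  counts |>
    mutate(sensitivity = sens, specificity = spec, precision = prec,
           f_measure = f, undefined = undefined)
}

#' Random visit-level train/test split
#'
#' Uniform split without replacement at the visit level, reproducible by
#' seed. The default follows the tuning protocol of using 20% of admissions
#' for training and the remainder for testing.
#'
#' @param cohort an [ehr_cohort] with at least two visits.
#' @param train_fraction fraction of visits assigned to the training cohort.
#' @param seed integer seed.
#' @return A list with elements `train` and `test`, both [ehr_cohort]s.
#' @export
split_cohort <- function(cohort, train_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  assert_scalar_number(train_fraction, "train_fraction", min = 0, max = 1)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1.")
  }
  ids <- unique(cohort$visit_id)
  if (length(ids) < 2L) abort("Need at least 2 visits to split.")
  n_train <- max(1L, min(length(ids) - 1L, round(train_fraction * length(ids))))
  train_ids <- withr::with_seed(seed, sample(ids, n_train))
  tib <- as_tibble(cohort)
  list(train = new_ehr_cohort(tib |> filter(.data$visit_id %in% train_ids)),
       test = new_ehr_cohort(tib |> filter(!.data$visit_id %in% train_ids)))
}

# Score all query cases against a reference cohort. Reference prefix/suffix
# structures (and their integer index sets, when an index with a distance
# matrix is available) are computed once and shared across queries. Returns a
# list (per case) of best-per-visit tibbles.
run_case_scores <- function(cases, reference, config, context = NULL,
                            exclude_self = TRUE) {
  structs <- visit_structures(reference)
  if (nrow(structs) == 0L) abort("Reference cohort has no visit with >= 2 events.")
  if (config$measure %in% c("apl", "apl_sym")) {
    ctx <- resolve_distance_context(context)
    if (!is.null(ctx$dist)) {
      structs$prefix_idx <- index_concept_sets(structs$prefix, ctx$idx)
    }
  }
  map(seq_len(nrow(cases)), function(i) {
    st <- structs
    if (exclude_self) st <- st |> filter(.data$visit_id != cases$visit_id[i])
    scored <- score_prefixes(cases$query_prefix[[i]], st, config, context)
    best_per_visit(scored)
  })
}

predicted_from_scores <- function(best, tau, lambda) {
  matched <- best |> filter(.data$dissimilarity < tau)
  n <- nrow(matched)
  if (n == 0L) return(character(0))
  counts <- table(unlist(map(matched$suffix, unique)))
  as.character(names(counts)[as.vector(counts) / n > lambda])
}

#' Grid tuning of the dissimilarity and confidence thresholds
#'
#' Every training query case is run against the remaining training visits
#' (self excluded) for each `(tau, lambda)` pair; confusion counts are pooled
#' (micro-averaged) and the pair attaining the highest F-measure is selected,
#' ties broken toward smaller `tau` then smaller `lambda`. The candidate
#' dissimilarities are computed once and the thresholds swept over them.
#'
#' @param train the training [ehr_cohort].
#' @param measure_config a [measure_config()].
#' @param tau_grid,lambda_grid nonempty numeric grids.
#' @param mode confusion mode, `"all"` or `"fresh"`.
#' @param query_mode `"all_k"` or `"first_k_only"` (see [make_query_cases()]).
#' @param context an `ehr_index` for the ontology-aware measures.
#' @param universe concept universe; defaults to all concepts observed in
#'   `train`.
#' @return An `ehr_tuning` object with elements `best_tau`, `best_lambda`,
#'   `grid` (per-cell pooled counts and metrics), and the settings used.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
grid_tune <- function(train, measure_config, tau_grid, lambda_grid,
                      mode = c("all", "fresh"),
                      query_mode = c("all_k", "first_k_only"),
                      context = NULL, universe = NULL) {
  mode <- match.arg(mode)
  query_mode <- match.arg(query_mode)
  if (length(tau_grid) == 0L || length(lambda_grid) == 0L) {
    abort("`tau_grid` and `lambda_grid` must be nonempty.")
  }
  cases <- make_query_cases(train, query_mode)
  if (nrow(cases) == 0L) abort("No query cases: the training cohort has no visit with >= 2 events.")
  universe <- universe %||% as_concept_set(unlist(as_tibble(train)$concepts))
  scores <- run_case_scores(cases, train, measure_config, context, exclude_self = TRUE)

  tau_grid <- sort(unique(tau_grid))
  lambda_grid <- sort(unique(lambda_grid))
  grid <- tidyr::expand_grid(tau = tau_grid, lambda = lambda_grid) |>
    mutate(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  acc <- array(0L, dim = c(length(tau_grid), length(lambda_grid), 4L))
  for (i in seq_len(nrow(cases))) {
    truth <- cases$truth_suffix[[i]]
    prefix <- cases$query_prefix[[i]]
    best <- scores[[i]]
    for (ti in seq_along(tau_grid)) {
      matched <- best |> filter(.data$dissimilarity < tau_grid[ti])
      n <- nrow(matched)
      counts <- if (n) table(unlist(map(matched$suffix, unique))) else integer(0)
      conf <- if (n) as.vector(counts) / n else numeric(0)
      for (li in seq_along(lambda_grid)) {
        predicted <- if (n) as.character(names(counts)[conf > lambda_grid[li]]) else character(0)
        cc <- confusion_counts(predicted, truth, universe, mode, prefix)
        acc[ti, li, ] <- acc[ti, li, ] + c(cc$tp, cc$fp, cc$fn, cc$tn)
      }
    }
  }
  ti_vec <- match(grid$tau, tau_grid)
  li_vec <- match(grid$lambda, lambda_grid)
  for (m in 1:4) {
    grid[[c("tp", "fp", "fn", "tn")[m]]] <-
      as.integer(acc[cbind(ti_vec, li_vec, m)])
  }
  grid <- compute_metrics(grid)
  best_row <- grid |>
    arrange(desc(.data$f_measure), .data$tau, .data$lambda) |>
    slice(1L)
  structure(list(best_tau = best_row$tau, best_lambda = best_row$lambda,
                 grid = grid, measure_config = measure_config, mode = mode,
                 query_mode = query_mode, n_cases = nrow(cases),
                 universe_size = length(universe)),
            class = "ehr_tuning")
}

#' @export
print.ehr_tuning <- function(x, ...) {
  cat(sprintf("<ehr_tuning> measure %s, %s mode, %d cases: best tau = %g, lambda = %g (F = %.3f)\n",
              x$measure_config$measure, x$mode, x$n_cases, x$best_tau, x$best_lambda,
              max(x$grid$f_measure)))
  invisible(x)
}

#' Tuned parameters as a `prediction_params` object
#'
#' @param tuning an `ehr_tuning` from [grid_tune()].
#' @return A [prediction_params()] with the tuned thresholds.
#' @export
tuned_params <- function(tuning) {
  stopifnot(inherits(tuning, "ehr_tuning"))
  prediction_params(tuning$best_tau, tuning$best_lambda, tuning$measure_config)
}

#' Evaluate prediction quality on a test cohort, optionally by semantic group
#'
#' Runs every test query case against the reference cohort with the supplied
#' (typically tuned) parameters and reports pooled confusion counts and
#' metrics for all concepts together and per requested semantic-group
#' stratum. Stratified accounting restricts the predicted set, the truth and
#' the universe to the stratum's concepts; anatomy is omitted from the default
#' strata because predicting an anatomical site is rarely actionable.
#'
#' @param test the [ehr_cohort] supplying query cases.
#' @param reference the [ehr_cohort] searched for similar records (may be the
#'   same as `test`; self-matches are excluded by visit id when
#'   `exclude_self`).
#' @param params a [prediction_params()].
#' @param mode confusion mode, `"all"` or `"fresh"`.
#' @param strata character vector of strata among `"all"`, `"disorders"`,
#'   `"procedures"`, `"chemicals_drugs"`, `"physiology"`, `"anatomy"`.
#' @param query_mode `"all_k"` or `"first_k_only"`.
#' @param context an `ehr_index`; required for ontology-aware measures and for
#'   any stratum other than `"all"` (it supplies semantic groups).
#' @param universe concept universe; defaults to the union of concepts
#'   observed in `reference` and `test`.
#' @param aggregate `"micro"` (pool counts, default) or `"macro"` (mean of
#'   per-case metrics).
#' @param exclude_self exclude the query's own visit from matching?
#' @return A tibble with one row per stratum: `stratum`, `mode`, `tau`,
#'   `lambda`, `n_cases`, the pooled counts and the metrics.
#' @export
evaluate_cohort <- function(test, reference, params, mode = c("all", "fresh"),
                            strata = DEFAULT_STRATA,
                            query_mode = c("all_k", "first_k_only"),
                            context = NULL, universe = NULL,
                            aggregate = c("micro", "macro"),
                            exclude_self = TRUE) {
  mode <- match.arg(mode)
  query_mode <- match.arg(query_mode)
  aggregate <- match.arg(aggregate)
  bad <- setdiff(strata, c("all", EHR_GROUPS))
  if (length(bad)) abort(sprintf("Unknown stratum '%s'.", bad[1L]))
  needs_groups <- any(strata != "all")
  ont <- if (inherits(context, "ehr_index")) context$ontology else context
  if (needs_groups && !inherits(ont, "ehr_ontology")) {
    abort("Semantic-group strata need an `ehr_index` (or ontology) context.")
  }
  cases <- make_query_cases(test, query_mode)
  if (nrow(cases) == 0L) abort("No query cases: `test` has no visit with >= 2 events.")
  universe <- universe %||% as_concept_set(c(unlist(as_tibble(reference)$concepts),
                                             unlist(as_tibble(test)$concepts)))
  scores <- run_case_scores(cases, reference, params$measure_config, context,
                            exclude_self = exclude_self)
  predicted <- map(scores, predicted_from_scores, tau = params$tau,
                   lambda = params$lambda)

  groups <- if (needs_groups) setNames(ont$concepts$semantic_group, ont$concepts$id)
  restrict <- function(x, stratum) {
    if (stratum == "all") return(x)
    x[!is.na(groups[x]) & groups[x] == stratum]
  }
  rows <- map(strata, function(stratum) {
    uni_s <- restrict(universe, stratum)
    per_case <- map(seq_len(nrow(cases)), function(i) {
      confusion_counts(restrict(predicted[[i]], stratum),
                       restrict(cases$truth_suffix[[i]], stratum),
                       uni_s, mode,
                       prefix = restrict(cases$query_prefix[[i]], stratum))
    })
    if (aggregate == "micro") {
      pooled <- bind_rows(per_case) |>
        summarise(across(c("tp", "fp", "fn", "tn"), sum))
      out <- compute_metrics(pooled)
    } else {
      per <- compute_metrics(bind_rows(per_case))
      out <- per |>
        summarise(across(c("tp", "fp", "fn", "tn"), sum),
                  across(c("sensitivity", "specificity", "precision", "f_measure"),
                         mean)) |>
        mutate(undefined = list(unique(unlist(per$undefined))))
    }
    out |>
      mutate(stratum = stratum, mode = mode, tau = params$tau,
             lambda = params$lambda, n_cases = nrow(cases),
             universe_size = length(uni_s), .before = 1L)
  })
  bind_rows(rows)
}

#' Write an evaluation (or tuning grid) table as TSV
#'
#' Machine-readable twin of a per-stratum results table.
#'
#' @param metrics a tibble from [evaluate_cohort()] or an `ehr_tuning` grid.
#' @param path output path.
#' @return `metrics`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  out <- as_tibble(metrics)
  if ("undefined" %in% names(out)) {
    out$undefined <- map_chr(out$undefined, paste, collapse = ",")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(metrics)
}
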