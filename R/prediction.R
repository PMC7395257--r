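#' Parameters of the two-step concept prediction algorithm
#'
#' @param tau dissimilarity threshold: a record joins the match set only when
#'   its best prefix dissimilarity is strictly below `tau`. Lives on the scale
#'   of the configured measure (see [measure_config()]).
#' @param lambda confidence threshold in `[0, 1]`: a concept is predicted only
#'   when the fraction of matched suffixes containing it is strictly above
#'   `lambda`.
#' @param measure_config a [measure_config()].
#' @return A `prediction_params` object.
#' @export
prediction_params <- function(tau, lambda, measure_config = ehrmatch::measure_config("boc")) {
  assert_scalar_number(tau, "tau", min = 0)
  assert_scalar_number(lambda, "lambda", min = 0, max = 1)
  stopifnot(inherits(measure_config, "measure_config"))
  structure(list(tau = tau, lambda = lambda, measure_config = measure_config),
            class = "prediction_params")
}

#' @export
print.prediction_params <- function(x, ...) {
  cat(sprintf("<prediction_params> measure %s, tau = %g, lambda = %g\n",
              x$measure_config$measure, x$tau, x$lambda))
  invisible(x)
}

# Per-visit prefix/suffix structures for retrieval: only visits with >= 2
# events are usable (a single-event visit has no nonempty suffix to learn
# from). Prefixes/suffixes are cumulative unions over event ranges.
visit_structures <- function(cohort, exclude_visit = NULL) {
  tib <- as_tibble(cohort) |> arrange(.data$visit_id, .data$ordinal)
  if (!is.null(exclude_visit)) tib <- tib |> filter(!.data$visit_id %in% exclude_visit)
  by_visit <- split(tib$concepts, tib$visit_id)
  by_visit <- by_visit[lengths(by_visit) >= 2L]
  if (length(by_visit) == 0L) {
    return(tibble(visit_id = character(), k = integer(),
                  prefix = list(), suffix = list()))
  }
  rows <- imap(by_visit, function(evs, vid) {
    m <- length(evs)
    pref <- vector("list", m - 1L)
    acc <- character(0)
    for (k in seq_len(m - 1L)) {
      acc <- unique(c(acc, evs[[k]]))
      pref[[k]] <- acc
    }
    suff <- vector("list", m - 1L)
    acc <- character(0)
    for (k in rev(seq_len(m - 1L))) {
      acc <- unique(c(acc, evs[[k + 1L]]))
      suff[[k]] <- acc
    }
    tibble(visit_id = vid, k = seq_len(m - 1L), prefix = pref, suffix = suff)
  })
  bind_rows(rows)
}

index_concept_sets <- function(sets, idx) {
  map(sets, function(p) {
    ip <- idx[p]
    if (anyNA(ip)) abort(sprintf("Cohort concept '%s' is not in the ontology index.",
                                 p[which(is.na(ip))[1L]]))
    as.integer(unname(ip))
  })
}

# Dissimilarity DisSim(P_k, Q) of every candidate prefix against the query,
# vectorised per measure. Returns `structs` with a `dissimilarity` column.
score_prefixes <- function(query_prefix, structs, config, context = NULL) {
  query_prefix <- as_concept_set(query_prefix)
  if (nrow(structs) == 0L) return(mutate(structs, dissimilarity = numeric(0)))
  measure <- config$measure
  if (measure == "boc") {
    universe <- unique(c(query_prefix, unlist(structs$prefix)))
    qi <- sort(match(query_prefix, universe))
    sets <- map(structs$prefix, ~ sort(match(.x, universe)))
    ov <- cpp_set_overlap(as.integer(qi), sets)
    diss <- ifelse(ov[, 2] == 0, 0, (ov[, 2] - ov[, 1]) / ov[, 2])
  } else if (measure %in% c("apl", "apl_sym")) {
    if (length(query_prefix) == 0L) abort("Empty query prefix: APL measures need nonempty sets.")
    mp <- resolve_max_path(config, context)
    ctx <- resolve_distance_context(context)
    empty <- lengths(structs$prefix) == 0L
    if (!is.null(ctx$dist)) {
      qi <- ctx$idx[query_prefix]
      if (anyNA(qi)) {
        abort(sprintf("Query concept '%s' is not in the ontology index.",
                      query_prefix[which(is.na(qi))[1L]]))
      }
      sets <- structs[["prefix_idx"]] %||% index_concept_sets(structs$prefix, ctx$idx)
      sc <- cpp_apl_scores(ctx$dist, as.integer(unname(qi)), sets)
      # column 1: mean over query of min into prefix; column 2: the reverse,
      # i.e. apl(P, Q)
      ab <- sc[, 2]; ba <- sc[, 1]
    } else {
      ab <- map_dbl(structs$prefix, ~ if (length(.x)) apl_raw_mean(.x, query_prefix, context) else NA_real_)
      ba <- map_dbl(structs$prefix, ~ if (length(.x)) apl_raw_mean(query_prefix, .x, context) else NA_real_)
    }
    if (config$normalize_apl) { ab <- ab / mp; ba <- ba / mp }
    diss <- if (measure == "apl") ab else ab + ba
    diss[empty] <- Inf  # degenerate emptied-out prefix: never similar
  } else if (measure == "ca") {
    ont <- if (inherits(context, "ehr_index")) context$ontology else context
    if (!inherits(ont, "ehr_ontology")) abort("`ca` needs an `ehr_index` (or ontology) context.")
    q_ids <- closure_ids(query_prefix, ont)
    anc_cache <- new.env(parent = emptyenv())
    anc_of <- function(cc) {
      val <- anc_cache[[cc]]
      if (is.null(val)) {
        val <- ancestor_depths(ont, cc)
        anc_cache[[cc]] <- val
      }
      val
    }
    decay <- config$ancestor_decay
    diss <- map_dbl(structs$prefix, function(p) {
      if (length(p) == 0L) return(Inf)
      ancs <- lapply(p, anc_of)
      nm <- unlist(lapply(ancs, names))
      w <- if (length(nm)) decay(unlist(ancs)) else numeric(0)
      if (length(nm)) {
        agg <- vapply(split(w, nm), mean, numeric(1))
        agg <- agg[!names(agg) %in% p]
      } else agg <- numeric(0)
      wts <- c(setNames(rep(1, length(p)), p), agg)
      1 - sum(wts[names(wts) %in% q_ids]) / sum(wts)
    })
  } else {
    abort(sprintf("Unknown measure '%s'.", measure))
  }
  structs$dissimilarity <- as.numeric(diss)
  structs
}

best_per_visit <- function(scored) {
  scored |>
    arrange(.data$visit_id, .data$k) |>
    group_by(.data$visit_id) |>
    slice_min(.data$dissimilarity, n = 1L, with_ties = FALSE) |>  # ties -> smaller k
    ungroup() |>
    rename(best_k = "k")
}

#' Best-matching prefix of a single visit against a query
#'
#' Evaluates `DisSim(P_k, query_prefix)` for every valid split `k = 1..m-1` of
#' the visit and returns the minimiser; ties break toward smaller `k`.
#'
#' @param query_prefix character vector of concept ids (the query's prefix
#'   concept set).
#' @param cohort an [ehr_cohort] containing the visit.
#' @param visit_id which visit; may be omitted for a single-visit cohort.
#' @param config a [measure_config()].
#' @param context an `ehr_index` (needed for the ontology-aware measures).
#' @return A one-row tibble with `visit_id`, `best_k`, `dissimilarity`.
#' @export
best_prefix_match <- function(query_prefix, cohort, config, context = NULL,
                              visit_id = NULL) {
  v <- resolve_visit(cohort, visit_id)
  if (nrow(v) < 2L) {
    abort(sprintf("Visit '%s' has a single event: no valid prefix/suffix split.",
                  v$visit_id[1L]))
  }
  structs <- visit_structures(new_ehr_cohort(v))
  scored <- score_prefixes(query_prefix, structs, config, context)
  best_per_visit(scored) |> select("visit_id", "best_k", "dissimilarity")
}

#' Step 1: retrieve suffixes of records with similar prefixes
#'
#' For every visit with at least two events, finds its most similar prefix to
#' the query (per [best_prefix_match()]) and retains the visit's corresponding
#' suffix when that best dissimilarity is strictly below `tau`. When
#' evaluating a held-out query built from a visit of the same cohort, pass its
#' id as `exclude_visit` so the record never matches itself; in deployment
#' (an external query) no exclusion applies.
#'
#' @param query_prefix character vector of concept ids.
#' @param cohort the reference [ehr_cohort] searched for similar records.
#' @param params a [prediction_params()].
#' @param context an `ehr_index` built on the ontology (required for the
#'   `ca`/`apl`/`apl_sym` measures).
#' @param exclude_visit visit id(s) excluded from matching.
#' @return An `ehr_matchset`: a tibble with one row per matched visit
#'   (`visit_id`, `best_k`, `dissimilarity`, list-column `suffix`), carrying
#'   the query prefix and parameters as attributes. May have zero rows.
#' @export
find_similar_records <- function(query_prefix, cohort, params, context = NULL,
                                 exclude_visit = NULL) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(params, "prediction_params"))
  query_prefix <- as_concept_set(query_prefix)
  structs <- visit_structures(cohort, exclude_visit = exclude_visit)
  scored <- score_prefixes(query_prefix, structs, params$measure_config, context)
  matches <- best_per_visit(scored) |>
    filter(.data$dissimilarity < params$tau) |>
    select("visit_id", "best_k", "dissimilarity", "suffix")
  new_matchset(matches, query_prefix, params)
}

new_matchset <- function(matches, query_prefix, params) {
  attr(matches, "query_prefix") <- query_prefix
  attr(matches, "params") <- params
  class(matches) <- c("ehr_matchset", class(tibble()))
  matches
}

#' @export
print.ehr_matchset <- function(x, ...) {
  cat(sprintf("<ehr_matchset> %d matched visits (tau = %g, measure = %s)\n",
              nrow(x), attr(x, "params")$tau,
              attr(x, "params")$measure_config$measure))
  NextMethod()
}

#' Step 2: predict concepts appearing with high confidence in matched suffixes
#'
#' For every concept in the union of the matched suffixes, its confidence is
#' the fraction of matched suffixes containing it; concepts with confidence
#' strictly above `lambda` are returned, ordered by descending confidence then
#' concept id. An empty match set yields an empty prediction table.
#'
#' @param matches an `ehr_matchset` from [find_similar_records()].
#' @param params a [prediction_params()]; `lambda` is used (defaults to the
#'   parameters carried by `matches`).
#' @return An `ehr_predictions` tibble with columns `concept`, `confidence`,
#'   `support` and list-column `supporting_visits`.
#' @export
predict_concepts <- function(matches, params = attr(matches, "params")) {
  stopifnot(inherits(matches, "ehr_matchset"))
  n <- nrow(matches)
  empty <- tibble(concept = character(), confidence = numeric(),
                  support = integer(), supporting_visits = list())
  if (n == 0L) return(new_predictions(empty, matches))
  long <- tibble(visit_id = rep(matches$visit_id, lengths(matches$suffix)),
                 concept = unlist(matches$suffix))
  preds <- long |>
    group_by(.data$concept) |>
    summarise(support = dplyr::n(),
              supporting_visits = list(.data$visit_id), .groups = "drop") |>
    mutate(confidence = .data$support / n) |>
    filter(.data$confidence > params$lambda) |>
    arrange(desc(.data$confidence), .data$concept) |>
    select("concept", "confidence", "support", "supporting_visits")
  new_predictions(preds, matches)
}

new_predictions <- function(preds, matches) {
  attr(preds, "n_matches") <- nrow(matches)
  attr(preds, "query_prefix") <- attr(matches, "query_prefix")
  class(preds) <- c("ehr_predictions", class(tibble()))
  preds
}

#' @export
print.ehr_predictions <- function(x, ...) {
  cat(sprintf("<ehr_predictions> %d concepts from %d matched suffixes\n",
              nrow(x), attr(x, "n_matches") %||% NA_integer_))
  NextMethod()
}

#' Convenience wrapper: retrieve and predict in one call
#'
#' Runs [find_similar_records()] then [predict_concepts()].
#'
#' @inheritParams find_similar_records
#' @return An `ehr_predictions` tibble (see [predict_concepts()]).
#' @export
predict_future_concepts <- function(query_prefix, cohort, params, context = NULL,
                                    exclude_visit = NULL) {
  matches <- find_similar_records(query_prefix, cohort, params, context,
                                  exclude_visit = exclude_visit)
  predict_concepts(matches, params)
}

#' Explain a prediction by highlighting contributing query-prefix concepts
#'
#' A query-prefix concept is highlighted with the number of supporting visits
#' (matched visits whose suffix contains the predicted concept) whose best
#' matched prefix also contains that concept — the prefix concepts that
#' co-occur with the prediction across the retrieved records, reconstructing
#' the highlight counts a reviewer sees next to a prediction.
#'
#' @param predictions an `ehr_predictions` table.
#' @param matches the `ehr_matchset` the predictions were derived from.
#' @param cohort the reference [ehr_cohort] (to rebuild matched prefixes).
#' @param concept which predicted concept to explain; defaults to all.
#' @return A tibble with columns `concept`, `prefix_concept`, `n_support`
#'   (visits supporting the prediction whose matched prefix contains
#'   `prefix_concept`), restricted to query-prefix concepts with nonzero
#'   counts.
#' @export
explain_prediction <- function(predictions, matches, cohort, concept = NULL) {
  stopifnot(inherits(predictions, "ehr_predictions"),
            inherits(matches, "ehr_matchset"),
            inherits(cohort, "ehr_cohort"))
  query_prefix <- attr(matches, "query_prefix")
  concepts <- concept %||% predictions$concept
  missing <- setdiff(concepts, predictions$concept)
  if (length(missing)) {
    abort(sprintf("Concept '%s' was not emitted by these predictions.", missing[1L]))
  }
  if ((attr(predictions, "n_matches") %||% -1L) != nrow(matches)) {
    abort("`predictions` do not derive from `matches` (match counts differ).")
  }
  matched_prefix <- map2(matches$visit_id, matches$best_k,
                         ~ prefix_concepts(cohort, .y, visit_id = .x))
  rows <- map(concepts, function(cc) {
    supp <- map_lgl(matches$suffix, ~ cc %in% .x)
    if (!any(supp)) return(tibble(concept = character(), prefix_concept = character(),
                                  n_support = integer()))
    counts <- map_int(query_prefix, function(q) {
      sum(map_lgl(matched_prefix[supp], ~ q %in% .x))
    })
    tibble(concept = cc, prefix_concept = query_prefix, n_support = counts) |>
      filter(.data$n_support > 0L) |>
      arrange(desc(.data$n_support), .data$prefix_concept)
  })
  bind_rows(rows)
}

#' Write predictions as a JSON Lines report
#'
#' One object per predicted concept with its confidence, support and
#' supporting visit ids; when an explanation table is supplied, the highlight
#' map is embedded per concept.
#'
#' @param predictions an `ehr_predictions` table.
#' @param path output path.
#' @param explanation optional [explain_prediction()] result.
#' @return `predictions`, invisibly.
#' @export
write_predictions <- function(predictions, path, explanation = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(predictions))) {
    obj <- list(concept = predictions$concept[i],
                confidence = predictions$confidence[i],
                support = predictions$support[i],
                supporting_visits = as.list(predictions$supporting_visits[[i]]))
    if (!is.null(explanation)) {
      hl <- explanation |> filter(.data$concept == predictions$concept[i])
      obj$highlighted <- setNames(as.list(hl$n_support), hl$prefix_concept)
    }
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(predictions)
}
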