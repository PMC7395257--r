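#' Construct a cohort of visits from an event-level data frame
#'
#' A cohort is stored tidily as one row per census event with list-columns for
#' the event's concept set and its negated mentions. Event order (the
#' `ordinal`) is the only temporal structure used downstream; optional
#' timestamps in source files are accepted and preserved in `ward`-style extra
#' columns but never interpreted.
#'
#' @param events data frame with columns `patient_id`, `visit_id`, `ordinal`
#'   (1-based event index), optional `ward`, and list-columns `concepts` and
#'   (optionally) `negated` of character concept-id vectors.
#' @return An `ehr_cohort`: a tibble subclass with one row per event, events
#'   sorted by visit then ordinal, concept sets deduplicated.
#' @examples
#' ehr_cohort(tibble::tibble(
#'   patient_id = "p1", visit_id = "v1", ordinal = 1:2, ward = NA_character_,
#'   concepts = list(c("A", "B"), c("B", "C")), negated = list(character(), "D")))
#' @export
ehr_cohort <- function(events) {
  events <- as_tibble(events)
  required <- c("patient_id", "visit_id", "ordinal", "concepts")
  missing <- setdiff(required, names(events))
  if (length(missing)) {
    abort(sprintf("Cohort events need column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (!"ward" %in% names(events)) events$ward <- NA_character_
  if (!"negated" %in% names(events)) events$negated <- list(character(0))
  events <- events |>
    mutate(patient_id = as.character(.data$patient_id),
           visit_id = as.character(.data$visit_id),
           ordinal = as.integer(.data$ordinal),
           ward = as.character(.data$ward),
           concepts = map(.data$concepts, as_concept_set),
           negated = map(.data$negated, as_concept_set)) |>
    arrange(.data$visit_id, .data$ordinal)
  validate_cohort_events(events)
  new_ehr_cohort(events)
}

new_ehr_cohort <- function(events) {
  class(events) <- c("ehr_cohort", class(tibble()))
  events
}

validate_cohort_events <- function(events) {
  if (nrow(events) == 0L) return(invisible(events))
  by_visit <- split(events$ordinal, events$visit_id)
  for (vid in names(by_visit)) {
    ords <- sort(by_visit[[vid]])
    if (!identical(ords, seq_along(ords))) {
      abort(sprintf("Visit '%s' has event ordinals {%s}; they must be consecutive 1..m.",
                    vid, paste(ords, collapse = ",")))
    }
  }
  multi_patient <- events |>
    distinct(.data$visit_id, .data$patient_id) |>
    count(.data$visit_id) |>
    filter(.data$n > 1L)
  if (nrow(multi_patient)) {
    abort(sprintf("Visit '%s' is assigned to more than one patient.",
                  multi_patient$visit_id[1L]))
  }
  invisible(events)
}

#' @export
print.ehr_cohort <- function(x, ...) {
  nv <- dplyr::n_distinct(x$visit_id)
  cat(sprintf("<ehr_cohort> %d visits, %d events, %d unique concepts\n",
              nv, nrow(x), length(unique(unlist(x$concepts)))))
  NextMethod()
}

#' Number of events per visit
#'
#' @param cohort an [ehr_cohort].
#' @return Tibble with columns `visit_id`, `n_events`.
#' @export
visit_lengths <- function(cohort) {
  cohort |>
    as_tibble() |>
    count(.data$visit_id, name = "n_events")
}

#' Read a cohort from a JSON Lines file
#'
#' One visit object per line:
#' `{"patient_id": str, "visit_id": str, "events": [{"ordinal": int,
#' "ward": str|null, "concepts": [str], "negated": [str]}]}`.
#' Negated mentions are dropped from each event's `concepts` at load time
#' (absent concepts are not informative for similarity) but kept in the
#' `negated` column for audit.
#'
#' @param path path to a JSONL cohort file.
#' @return An [ehr_cohort].
#' @export
load_cohort <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(new_ehr_cohort(tibble(
      patient_id = character(), visit_id = character(), ordinal = integer(),
      ward = character(), concepts = list(), negated = list())))
  }
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) {
                      abort(sprintf("Malformed JSON on line %d of '%s': %s",
                                    i, path, conditionMessage(e)))
                    })
    if (is.null(obj$visit_id) || is.null(obj$events)) {
      abort(sprintf("Line %d of '%s': visit object needs `visit_id` and `events`.", i, path))
    }
    rows[[i]] <- tibble(
      patient_id = as.character(obj$patient_id %||% obj$visit_id),
      visit_id = as.character(obj$visit_id),
      ordinal = map_int(obj$events, ~ as.integer(.x$ordinal)),
      ward = map_chr(obj$events, ~ as.character(.x$ward %||% NA_character_)),
      concepts = map(obj$events, ~ as_concept_set(unlist(.x$concepts))),
      negated = map(obj$events, ~ as_concept_set(unlist(.x$negated))))
  }
  events <- bind_rows(rows)
  line_vids <- vapply(rows, function(r) r$visit_id[1L], character(1))
  if (anyDuplicated(line_vids)) {
    abort(sprintf("Duplicate visit_id '%s' in '%s'.",
                  line_vids[duplicated(line_vids)][1L], path))
  }
  # negated mentions removed from the working concept sets
  events$concepts <- map2(events$concepts, events$negated, setdiff)
  ehr_cohort(events)
}

#' Write a cohort to a JSON Lines file
#'
#' Inverse of [load_cohort()]; loading the written file round-trips to an
#' identical cohort.
#'
#' @param cohort an [ehr_cohort].
#' @param path output path.
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  visits <- split(as_tibble(cohort), as_tibble(cohort)$visit_id)
  # keep first-appearance order
  order_ids <- unique(cohort$visit_id)
  con <- file(path, open = "w")
  on.exit(close(con))
  for (vid in order_ids) {
    v <- visits[[vid]]
    obj <- list(
      patient_id = v$patient_id[1L],
      visit_id = vid,
      events = pmap(list(v$ordinal, v$ward, v$concepts, v$negated),
                    function(o, w, cc, nn) {
                      list(ordinal = o,
                           ward = if (is.na(w)) NULL else w,
                           concepts = as.list(cc),
                           negated = as.list(nn))
                    }))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(cohort)
}

get_visit <- function(cohort, visit_id) {
  v <- as_tibble(cohort) |> filter(.data$visit_id == !!visit_id)
  if (nrow(v) == 0L) abort(sprintf("Unknown visit_id '%s'.", visit_id))
  v |> arrange(.data$ordinal)
}

resolve_visit <- function(cohort, visit_id) {
  if (is.null(visit_id)) {
    ids <- unique(cohort$visit_id)
    if (length(ids) != 1L) {
      abort("`visit_id` must be given when the cohort holds more than one visit.")
    }
    visit_id <- ids
  }
  get_visit(cohort, visit_id)
}

#' Concept set of a visit's time-based prefix
#'
#' The prefix at split `k` is the union of the concept sets of events
#' `1..k`. With `k = m` (all events) this is the whole-record query used in
#' deployment, where the goal is to predict what comes after the current
#' state.
#'
#' @param cohort an [ehr_cohort] (or a single-visit subset of one).
#' @param k split point, `1 <= k <= m`.
#' @param visit_id which visit; may be omitted for a single-visit cohort.
#' @return Character vector of concept ids.
#' @export
prefix_concepts <- function(cohort, k, visit_id = NULL) {
  v <- resolve_visit(cohort, visit_id)
  m <- nrow(v)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > m) {
    abort(sprintf("`k` must be in 1..%d (visit has %d events).", m, m))
  }
  as_concept_set(unlist(v$concepts[seq_len(k)]))
}

#' Concept set of a visit's time-based suffix
#'
#' The suffix at split `k` is the union of the concept sets of events
#' `k+1..m`; an empty suffix (`k = m`) is not permitted.
#'
#' @inheritParams prefix_concepts
#' @return Character vector of concept ids.
#' @export
suffix_concepts <- function(cohort, k, visit_id = NULL) {
  v <- resolve_visit(cohort, visit_id)
  m <- nrow(v)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > m - 1L) {
    abort(sprintf("`k` must be in 1..%d: the suffix of events k+1..m may not be empty.",
                  m - 1L))
  }
  as_concept_set(unlist(v$concepts[seq(k + 1L, m)]))
}

#' Restrict a cohort to concepts of selected semantic groups
#'
#' Mirrors the preparation step of keeping only the semantic groups that
#' matter for interpatient similarity. Events whose concept sets empty out are
#' retained (with empty sets) so event ordinals stay intact.
#'
#' @param cohort an [ehr_cohort].
#' @param ontology an [ehr_ontology] supplying semantic groups.
#' @param keep_groups semantic groups to keep; defaults to disorders,
#'   physiology, chemicals & drugs, procedures and anatomy.
#' @param unresolved what to do with concept ids absent from the ontology:
#'   `"drop"` (default; dropped with one warning) or `"error"`.
#' @return A filtered [ehr_cohort].
#' @export
filter_cohort <- function(cohort, ontology,
                          keep_groups = DEFAULT_KEEP_GROUPS,
                          unresolved = c("drop", "error")) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(ontology, "ehr_ontology"))
  unresolved <- match.arg(unresolved)
  bad <- setdiff(keep_groups, EHR_GROUPS)
  if (length(bad)) abort(sprintf("Unknown semantic group(s): %s.", paste(bad, collapse = ", ")))
  groups <- setNames(ontology$concepts$semantic_group, ontology$concepts$id)
  all_ids <- unique(unlist(cohort$concepts))
  unknown <- setdiff(all_ids, names(groups))
  if (length(unknown)) {
    if (unresolved == "error") {
      abort(sprintf("%d concept id(s) not in the ontology (first: '%s').",
                    length(unknown), unknown[1L]))
    }
    warn(sprintf("Dropping %d concept id(s) not resolvable in the ontology (first: '%s').",
                 length(unknown), unknown[1L]))
  }
  keep <- names(groups)[groups %in% keep_groups]
  out <- as_tibble(cohort)
  out$concepts <- map(out$concepts, ~ .x[.x %in% keep])
  new_ehr_cohort(out)
}
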