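#' Configuration for an interpatient dissimilarity measure
#'
#' Selects one of the four set dissimilarity measures and its parameters:
#'
#' * `boc` — bag of concepts: symmetric set difference over union (the Jaccard
#'   complement). Range `[0, 1]`, symmetric.
#' * `ca` — common ancestors: each concept and its ISA ancestors receive
#'   weights decaying with distance; the dissimilarity from `A` to `B` is one
#'   minus the weight of `A`'s closure found again in `B`'s closure, over the
#'   total weight of `A`'s closure. Range `[0, 1]`, directional.
#' * `apl` — average path length: mean over `A` of the minimum ISA path length
#'   to any concept of `B`; by default divided by the maximum path length so
#'   the value lies in `[0, 1]`. Directional.
#' * `apl_sym` — sum of `apl(A, B)` and `apl(B, A)`. Range `[0, 2]` under the
#'   default normalisation, symmetric.
#'
#' For every measure `0` is maximum similarity. Note that the dissimilarity
#' threshold `tau` of the prediction step lives on the scale implied by
#' `normalize_apl`: with normalisation off, `apl`-family scores are raw mean
#' edge counts and `tau` must be chosen on that scale.
#'
#' @param measure one of `"boc"`, `"ca"`, `"apl"`, `"apl_sym"`.
#' @param ancestor_decay weight given to an ancestor at distance `d` from a
#'   source concept (CA only); a function of `d`, default `1 / (1 + d)`.
#' @param normalize_apl divide `apl`-family scores by `max_path`? Default `TRUE`.
#' @param max_path normaliser for the `apl` family; when `NULL` it is taken
#'   from the ontology via [max_path_length()].
#' @return A `measure_config` object.
#' @export
measure_config <- function(measure = c("boc", "ca", "apl", "apl_sym"),
                           ancestor_decay = function(d) 1 / (1 + d),
                           normalize_apl = TRUE,
                           max_path = NULL) {
  measure <- match.arg(measure)
  if (!is.function(ancestor_decay)) abort("`ancestor_decay` must be a function of the distance d.")
  if (!is.null(max_path)) assert_scalar_number(max_path, "max_path", min = 1)
  structure(list(measure = measure, ancestor_decay = ancestor_decay,
                 normalize_apl = isTRUE(normalize_apl), max_path = max_path),
            class = "measure_config")
}

#' @export
print.measure_config <- function(x, ...) {
  cat(sprintf("<measure_config> %s%s\n", x$measure,
              if (x$measure %in% c("apl", "apl_sym"))
                sprintf(" (normalize = %s, max_path = %s)", x$normalize_apl,
                        x$max_path %||% "from ontology") else ""))
  invisible(x)
}

#' Bag-of-concepts dissimilarity
#'
#' `(|A \ B| + |B \ A|) / |A union B|`, the Jaccard complement: 0 is maximum
#' similarity, 1 minimum. Two empty sets are treated as identical (returns 0).
#'
#' @param A,B character vectors of concept ids (treated as sets).
#' @return A value in `[0, 1]`.
#' @examples
#' boc_dissimilarity(c("x1", "x2"), c("x2", "y1"))  # 2/3
#' @export
boc_dissimilarity <- function(A, B) {
  A <- as_concept_set(A); B <- as_concept_set(B)
  if (length(A) == 0L && length(B) == 0L) {
    inform("boc_dissimilarity: both sets empty; returning 0 by the identity convention.",
           .frequency = "once", .frequency_id = "ehrmatch_boc_empty")
    return(0)
  }
  inter <- length(intersect(A, B))
  uni <- length(A) + length(B) - inter
  (uni - inter) / uni
}

#' Distance-decayed ancestor closure of a concept set
#'
#' Every source concept gets weight 1; an ancestor at minimum ISA distance `d`
#' from a source gets `ancestor_decay(d)` (default `1 / (1 + d)`); a node
#' reached from several sources (or at several distances) receives the
#' arithmetic mean of its assigned weights. Source membership always wins: a
#' source concept keeps weight 1 even when it is also an ancestor of another
#' source.
#'
#' @param A character vector of concept ids.
#' @param ontology an [ehr_ontology].
#' @param ancestor_decay weight function of distance `d`.
#' @return A tibble with columns `concept`, `weight`, `is_source`, class
#'   `weighted_closure`.
#' @export
ancestor_closure_weights <- function(A, ontology,
                                     ancestor_decay = function(d) 1 / (1 + d)) {
  stopifnot(inherits(ontology, "ehr_ontology"))
  A <- as_concept_set(A)
  unknown <- setdiff(A, ontology$ids)
  if (length(unknown)) abort(sprintf("Unknown concept id '%s'.", unknown[1L]))
  anc <- map(A, ~ ancestor_depths(ontology, .x))
  tab <- tibble(concept = unlist(map(anc, names)) %||% character(0),
                weight = ancestor_decay(unlist(anc) %||% numeric(0))) |>
    group_by(.data$concept) |>
    summarise(weight = mean(.data$weight), .groups = "drop") |>
    filter(!.data$concept %in% A) |>
    mutate(is_source = FALSE)
  out <- bind_rows(tibble(concept = A, weight = 1, is_source = TRUE), tab) |>
    arrange(desc(.data$is_source), .data$concept)
  class(out) <- c("weighted_closure", class(out))
  out
}

#' Common-ancestors dissimilarity (directional)
#'
#' With `A'`, `B'` the weighted ancestor closures of `A` and `B`, returns
#' `1 - sum(w_A(c) for c in A' also present in B') / sum(w_A(c) for c in A')`.
#' Zero iff every member of `A'` appears (as an id) in `B'`; by definition not
#' symmetric.
#'
#' @param A,B character vectors of concept ids; `A` must be nonempty.
#' @param ontology an [ehr_ontology].
#' @param config a [measure_config()]; only `ancestor_decay` is used.
#' @return A value in `[0, 1]`.
#' @export
ca_dissimilarity <- function(A, B, ontology, config = measure_config("ca")) {
  A <- as_concept_set(A); B <- as_concept_set(B)
  if (length(A) == 0L) abort("`A` must be nonempty: the CA normaliser is undefined for an empty set.")
  wa <- ancestor_closure_weights(A, ontology, config$ancestor_decay)
  ids_b <- closure_ids(B, ontology)
  1 - sum(wa$weight[wa$concept %in% ids_b]) / sum(wa$weight)
}

closure_ids <- function(B, ontology) {
  B <- as_concept_set(B)
  if (length(B) == 0L) return(character(0))
  unknown <- setdiff(B, ontology$ids)
  if (length(unknown)) abort(sprintf("Unknown concept id '%s'.", unknown[1L]))
  unique(c(B, unlist(map(B, ~ names(ancestor_depths(ontology, .x))))))
}

resolve_distance_context <- function(context) {
  if (inherits(context, "ehr_index")) return(context)
  if (inherits(context, "dewey_codebook")) {
    return(list(codebook = context, dist = NULL, idx = context$idx))
  }
  abort("`context` must be an `ehr_index` (see build_ehr_index()) or a `dewey_codebook`.")
}

apl_raw_mean <- function(A, B, context) {
  ctx <- resolve_distance_context(context)
  if (!is.null(ctx$dist)) {
    ia <- ctx$idx[A]; ib <- ctx$idx[B]
    if (anyNA(ia)) abort(sprintf("Unknown concept id '%s'.", A[which(is.na(ia))[1L]]))
    if (anyNA(ib)) abort(sprintf("Unknown concept id '%s'.", B[which(is.na(ib))[1L]]))
    sub <- ctx$dist[ia, ib, drop = FALSE]
    return(mean(apply(sub, 1L, min)))
  }
  cb <- ctx$codebook
  mean(vapply(A, function(a) {
    min(vapply(B, function(b) concept_distance(cb, a, b), numeric(1)))
  }, numeric(1)))
}

resolve_max_path <- function(config, context) {
  if (!is.null(config$max_path)) return(config$max_path)
  ctx <- resolve_distance_context(context)
  if (!is.null(ctx$max_path)) return(ctx$max_path)
  2 * max(ctx$codebook$depth)
}

#' Average-path-length dissimilarity (directional)
#'
#' Mean over concepts of `A` of the minimum ISA path length to any concept of
#' `B`, divided (by default) by the ontology's maximum path length so values
#' lie in `[0, 1]`. Zero iff `A` is a subset of `B`. Distances come from the
#' Dewey codebook; with a truncated (inexact) codebook they are upper bounds.
#'
#' @param A,B nonempty character vectors of concept ids.
#' @param context an `ehr_index` (preferred; see [build_ehr_index()]) or a
#'   [build_dewey_codebook()] result.
#' @param config a [measure_config()].
#' @return A nonnegative value; in `[0, 1]` when normalised.
#' @export
apl_dissimilarity <- function(A, B, context, config = measure_config("apl")) {
  A <- as_concept_set(A); B <- as_concept_set(B)
  if (length(A) == 0L || length(B) == 0L) {
    abort("`A` and `B` must both be nonempty for the APL measures.")
  }
  raw <- apl_raw_mean(A, B, context)
  if (config$normalize_apl) raw / resolve_max_path(config, context) else raw
}

#' Symmetric average-path-length dissimilarity
#'
#' `apl(A, B) + apl(B, A)`; symmetric, in `[0, 2]` under the default
#' normalisation.
#'
#' @inheritParams apl_dissimilarity
#' @return A nonnegative value; in `[0, 2]` when normalised.
#' @export
apl_sym_dissimilarity <- function(A, B, context, config = measure_config("apl_sym")) {
  apl_dissimilarity(A, B, context, config) + apl_dissimilarity(B, A, context, config)
}

#' Dissimilarity of two concept sets under a configured measure
#'
#' Dispatcher used by the retrieval pipeline; see [measure_config()] for the
#' measures.
#'
#' @param A,B character vectors of concept ids.
#' @param config a [measure_config()].
#' @param context an `ehr_index` (required for `ca`/`apl`/`apl_sym`; the
#'   ontology inside it supplies ancestors and distances). Ignored for `boc`.
#' @return A nonnegative dissimilarity; 0 is maximum similarity.
#' @export
set_dissimilarity <- function(A, B, config, context = NULL) {
  switch(config$measure,
    boc = boc_dissimilarity(A, B),
    ca = {
      ont <- if (inherits(context, "ehr_index")) context$ontology else context
      if (!inherits(ont, "ehr_ontology")) abort("`ca` needs an `ehr_index` (or ontology) context.")
      ca_dissimilarity(A, B, ont, config)
    },
    apl = apl_dissimilarity(A, B, context, config),
    apl_sym = apl_sym_dissimilarity(A, B, context, config))
}
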