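#' Build a retrieval index over an ontology
#'
#' Bundles the Dewey codebook, the concept-to-integer map, the maximum path
#' length, and (optionally) the precomputed pairwise concept-distance matrix
#' that makes whole-cohort retrieval with the path-length measures fast. Build
#' it once per ontology and pass it to [find_similar_records()],
#' [grid_tune()] and [evaluate_cohort()].
#'
#' The dense distance matrix needs `O(V^2)` integers; for a 4,000-concept
#' ontology that is ~64 MB. Set `build_matrix = FALSE` to fall back to
#' per-pair Dewey comparisons (fine for small ontologies and the `boc`/`ca`
#' measures, which do not use the matrix).
#'
#' @param ontology an [ehr_ontology].
#' @param cap Dewey encodings retained per concept (see
#'   [build_dewey_codebook()]).
#' @param build_matrix precompute the full pairwise distance matrix?
#' @return An `ehr_index` object.
#' @export
build_ehr_index <- function(ontology, cap = 16L, build_matrix = TRUE) {
  stopifnot(inherits(ontology, "ehr_ontology"))
  codebook <- build_dewey_codebook(ontology, cap = cap)
  dist <- NULL
  if (isTRUE(build_matrix)) {
    if (!codebook$exact) {
      inform("Dewey codebook is inexact (encoding cap hit); distances are upper bounds and the path-length measures are approximations.")
    }
    # index paths, in codebook order
    dist <- cpp_pair_dist_matrix(unname(codebook$paths))
  }
  structure(
    list(ontology = ontology, codebook = codebook, idx = ontology$idx,
         ids = ontology$ids, dist = dist,
         max_path = max_path_length(ontology)),
    class = "ehr_index")
}

#' @export
print.ehr_index <- function(x, ...) {
  cat(sprintf("<ehr_index> %d concepts, max_path %d, distance matrix: %s, codebook exact: %s\n",
              length(x$ids), x$max_path,
              if (is.null(x$dist)) "not built" else "built", x$codebook$exact))
  invisible(x)
}
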