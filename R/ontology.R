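#' Construct a medical concept ontology from an ISA edge list
#'
#' Builds a validated, rooted ISA directed acyclic graph (DAG) from a
#' child-to-parent edge table plus optional concept metadata. The ontology is
#' the substrate for the semantic dissimilarity measures: ancestor retrieval,
#' lowest-common-ancestor path distances, and semantic-group lookups all run
#' against it.
#'
#' Concepts appearing in `edges` but absent from `metadata` are auto-registered
#' with their id as label and semantic group `"other"`. If several parentless
#' concepts exist, a virtual root is inserted above them so that every concept
#' reaches a single root; real SNOMED-style hierarchies are single-rooted, but
#' synthetic or excerpted hierarchies need not be.
#'
#' @param edges data frame with columns `child`, `parent` (concept ids), one
#'   row per ISA edge.
#' @param metadata optional data frame with columns `id`, `label`,
#'   `semantic_group`; `semantic_group` must be one of `"disorders"`,
#'   `"procedures"`, `"chemicals_drugs"`, `"physiology"`, `"anatomy"`,
#'   `"other"`.
#' @param virtual_root id to use for the inserted root when the edge list has
#'   several parentless concepts.
#' @return An object of class `ehr_ontology`: a list with a `concepts` tibble
#'   (`id`, `label`, `semantic_group`, `depth`), the `edges` tibble, the `root`
#'   id, and parent/child adjacency used by the query functions.
#' @examples
#' edges <- tibble::tribble(~child, ~parent,
#'   "x1", "X", "x2", "X", "y1", "Y", "y2", "Y", "X", "R", "Y", "R")
#' ont <- ehr_ontology(edges)
#' ont$root
#' ancestor_depths(ont, "x1")
#' @export
ehr_ontology <- function(edges, metadata = NULL, virtual_root = "ROOT") {
  edges <- as_tibble(edges)
  if (nrow(edges) == 0L) abort("Empty edge list: an ontology needs at least one ISA edge.")
  if (!all(c("child", "parent") %in% names(edges))) {
    abort("`edges` must have columns `child` and `parent`.")
  }
  edges <- edges |>
    transmute(child = as.character(.data$child),
              parent = as.character(.data$parent)) |>
    distinct()
  if (any(edges$child == edges$parent)) {
    bad <- edges$child[edges$child == edges$parent][1L]
    abort(sprintf("Cycle detected: concept '%s' is its own parent.", bad))
  }

  ids <- unique(c(edges$child, edges$parent))

  # Multiple parentless concepts: insert a virtual root above them.
  roots <- setdiff(ids, edges$child)
  if (length(roots) == 0L) {
    abort("Cycle detected: every concept has a parent, so no root exists.")
  }
  if (length(roots) > 1L) {
    while (virtual_root %in% ids) virtual_root <- paste0(virtual_root, "_")
    edges <- bind_rows(edges, tibble(child = roots, parent = virtual_root))
    ids <- c(ids, virtual_root)
    root <- virtual_root
  } else {
    root <- roots
  }

  meta <- normalise_metadata(metadata, ids, root)

  idx <- setNames(seq_along(ids), ids)
  parents <- split(idx[edges$parent], edges$child)   # by child id -> parent indices
  children <- split(idx[edges$child], edges$parent)
  parent_list <- vector("list", length(ids))
  child_list <- vector("list", length(ids))
  parent_list[idx[names(parents)]] <- lapply(parents, unname)
  child_list[idx[names(children)]] <- lapply(children, unname)
  empty <- integer(0)
  parent_list[vapply(parent_list, is.null, TRUE)] <- list(empty)
  child_list[vapply(child_list, is.null, TRUE)] <- list(empty)

  topo <- topological_order(parent_list, child_list, ids, edges)

  depth <- bfs_depth_from_root(child_list, idx[[root]], length(ids))
  if (anyNA(depth)) {
    orphan <- ids[which(is.na(depth))[1L]]
    abort(sprintf("Concept '%s' cannot reach the root '%s' by following parent edges.",
                  orphan, root))
  }

  concepts <- tibble(id = ids) |>
    left_join(meta, by = "id") |>
    mutate(depth = as.integer(depth))

  structure(
    list(concepts = concepts, edges = edges, root = root, ids = ids, idx = idx,
         parents = parent_list, children = child_list, topo = topo,
         depth = setNames(as.integer(depth), ids)),
    class = "ehr_ontology")
}

normalise_metadata <- function(metadata, ids, root) {
  if (is.null(metadata)) {
    return(tibble(id = ids, label = ids,
                  semantic_group = ifelse(ids == root, "other", "other")))
  }
  metadata <- as_tibble(metadata)
  if (!all(c("id", "label", "semantic_group") %in% names(metadata))) {
    abort("`metadata` must have columns `id`, `label`, `semantic_group`.")
  }
  metadata <- metadata |>
    transmute(id = as.character(.data$id), label = as.character(.data$label),
              semantic_group = as.character(.data$semantic_group))
  if (anyDuplicated(metadata$id)) {
    abort(sprintf("Duplicate concept id in metadata: '%s'.",
                  metadata$id[duplicated(metadata$id)][1L]))
  }
  bad <- setdiff(unique(metadata$semantic_group), EHR_GROUPS)
  if (length(bad)) {
    abort(sprintf("Unknown semantic group(s): %s. Valid groups: %s.",
                  paste0("'", bad, "'", collapse = ", "),
                  paste(EHR_GROUPS, collapse = ", ")))
  }
  missing <- setdiff(ids, metadata$id)
  if (length(missing)) {
    metadata <- bind_rows(metadata,
                          tibble(id = missing, label = missing, semantic_group = "other"))
  }
  metadata[match(ids, metadata$id), , drop = FALSE]
}

# Kahn's algorithm over child->parent edges; parents come before children in
# the returned order. Detects cycles and names one participating edge.
topological_order <- function(parent_list, child_list, ids, edges) {
  n <- length(ids)
  indeg <- vapply(parent_list, length, integer(1))  # unresolved parents per node
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in child_list[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    leftover <- ids[setdiff(seq_len(n), order)]
    bad <- edges |> filter(.data$child %in% leftover, .data$parent %in% leftover)
    abort(sprintf("Cycle detected in ISA hierarchy involving edge '%s' -> '%s'.",
                  bad$child[1L], bad$parent[1L]))
  }
  order
}

bfs_depth_from_root <- function(child_list, root_i, n) {
  depth <- rep(NA_integer_, n)
  depth[root_i] <- 0L
  frontier <- root_i
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (ch in child_list[[v]]) {
        if (is.na(depth[ch]) || depth[ch] > depth[v] + 1L) {
          depth[ch] <- depth[v] + 1L
          nxt <- c(nxt, ch)
        }
      }
    }
    frontier <- unique(nxt)
  }
  depth
}

#' Load an ontology from tab-separated edge and metadata files
#'
#' The edge file is a two-column headerless TSV `child_id<TAB>parent_id`; the
#' metadata file is a three-column headerless TSV
#' `id<TAB>label<TAB>semantic_group`.
#'
#' @param edge_file path to the ISA edge TSV.
#' @param metadata_file optional path to the concept metadata TSV.
#' @inheritParams ehr_ontology
#' @return An [ehr_ontology] object.
#' @export
load_ontology <- function(edge_file, metadata_file = NULL, virtual_root = "ROOT") {
  edges <- utils::read.table(edge_file, sep = "\t", header = FALSE,
                             col.names = c("child", "parent"),
                             colClasses = "character", quote = "",
                             comment.char = "")
  metadata <- NULL
  if (!is.null(metadata_file)) {
    metadata <- utils::read.table(metadata_file, sep = "\t", header = FALSE,
                                  col.names = c("id", "label", "semantic_group"),
                                  colClasses = "character", quote = "",
                                  comment.char = "")
  }
  ehr_ontology(edges, metadata, virtual_root = virtual_root)
}

#' Write an ontology to the TSV interchange formats
#'
#' @param ontology an [ehr_ontology].
#' @param edge_file,metadata_file output paths (either may be `NULL` to skip).
#' @return `ontology`, invisibly.
#' @export
write_ontology <- function(ontology, edge_file, metadata_file = NULL) {
  stopifnot(inherits(ontology, "ehr_ontology"))
  utils::write.table(ontology$edges, edge_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(metadata_file)) {
    utils::write.table(ontology$concepts[, c("id", "label", "semantic_group")],
                       metadata_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(ontology)
}

#' @export
print.ehr_ontology <- function(x, ...) {
  cat(sprintf("<ehr_ontology> %d concepts, %d ISA edges, root '%s', max depth %d\n",
              nrow(x$concepts), nrow(x$edges), x$root, max(x$depth)))
  grp <- table(x$concepts$semantic_group)
  cat("  semantic groups:",
      paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.ehr_ontology <- function(x, ...) x$concepts

#' Semantic group of each concept
#'
#' @param ontology an [ehr_ontology].
#' @param ids concept ids (defaults to all concepts).
#' @return A named character vector of semantic groups.
#' @export
semantic_groups <- function(ontology, ids = NULL) {
  stopifnot(inherits(ontology, "ehr_ontology"))
  out <- setNames(ontology$concepts$semantic_group, ontology$concepts$id)
  if (is.null(ids)) return(out)
  unknown <- setdiff(ids, names(out))
  if (length(unknown)) {
    abort(sprintf("Unknown concept id(s): %s.",
                  paste0("'", head(unknown, 3), "'", collapse = ", ")))
  }
  out[ids]
}

#' Minimum-edge-distance ancestors of a concept
#'
#' Breadth-first search up the ISA hierarchy. The concept itself is excluded;
#' the root is included (unless the concept *is* the root). The distance to an
#' ancestor is the minimum number of ISA edges on any upward path.
#'
#' @param ontology an [ehr_ontology].
#' @param concept a concept id.
#' @return A named integer vector mapping ancestor id to minimum edge distance;
#'   empty for the root.
#' @examples
#' ont <- ehr_ontology(tibble::tribble(~child, ~parent,
#'   "x1", "X", "x2", "X", "y1", "Y", "y2", "Y", "X", "R", "Y", "R"))
#' ancestor_depths(ont, "x1")  # X = 1, R = 2
#' @export
ancestor_depths <- function(ontology, concept) {
  stopifnot(inherits(ontology, "ehr_ontology"))
  i <- unname(ontology$idx[concept])
  if (length(i) != 1L || is.na(i)) abort(sprintf("Unknown concept id '%s'.", concept))
  dist <- rep(NA_integer_, length(ontology$ids))
  dist[i] <- 0L
  frontier <- i
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (p in ontology$parents[[v]]) {
        if (is.na(dist[p]) || dist[p] > dist[v] + 1L) {
          dist[p] <- dist[v] + 1L
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  found <- which(!is.na(dist))
  found <- found[found != i]
  setNames(dist[found], ontology$ids[found])[order(dist[found], ontology$ids[found])]
}

#' Build a Dewey codebook for fast ancestor and LCA-distance queries
#'
#' Every concept receives one encoding per root path: the sequence of
#' child-ordinal labels from the root down to the concept, where ordinals are
#' assigned by lexicographic child id so the codebook (and everything computed
#' from it) is reproducible. A proper prefix of an encoding is always an
#' encoding of an ancestor, so the distance between two concepts through their
#' lowest common ancestor reduces to a comparison of encoding prefixes.
#'
#' Multi-parent concepts have several root paths; paths are enumerated
#' shortest-first and at most `cap` are retained per concept. The `exact` flag
#' is `TRUE` only when no concept was truncated (directly or through a
#' truncated ancestor); with an exact codebook [concept_distance()] equals the
#' minimum path length through a common ancestor, otherwise it is an upper
#' bound.
#'
#' @param ontology an [ehr_ontology].
#' @param cap maximum number of encodings retained per concept (>= 1).
#' @return An object of class `dewey_codebook`.
#' @export
build_dewey_codebook <- function(ontology, cap = 16L) {
  stopifnot(inherits(ontology, "ehr_ontology"))
  cap <- as.integer(cap)
  if (is.na(cap) || cap < 1L) abort("`cap` must be a count >= 1.")
  n <- length(ontology$ids)

  # child ordinal of node v under parent p: rank of v's id among p's children ids
  ordinal <- vector("list", n)
  for (p in seq_len(n)) {
    ch <- ontology$children[[p]]
    if (length(ch)) {
      ord <- rank(ontology$ids[ch], ties.method = "first")
      for (j in seq_along(ch)) {
        ordinal[[ch[j]]] <- c(ordinal[[ch[j]]], setNames(ord[j], p))
      }
    }
  }

  # paths[[v]]: list of integer vectors of node indices root..v (index paths);
  # ordpaths[[v]]: matching ordinal label sequences. Node-index paths and
  # ordinal paths are in bijection; distances use index paths.
  paths <- vector("list", n)
  exact_node <- rep(TRUE, n)
  root_i <- ontology$idx[[ontology$root]]
  for (v in ontology$topo) {
    if (v == root_i) { paths[[v]] <- list(v); next }
    cand <- list()
    ex <- TRUE
    for (p in ontology$parents[[v]]) {
      ex <- ex && exact_node[p]
      for (pp in paths[[p]]) cand[[length(cand) + 1L]] <- c(pp, v)
    }
    lens <- vapply(cand, length, integer(1))
    keys <- vapply(cand, function(z) paste(z, collapse = "."), character(1))
    ord <- order(lens, keys)
    if (length(cand) > cap) { ex <- FALSE; ord <- ord[seq_len(cap)] }
    paths[[v]] <- cand[ord]
    exact_node[v] <- ex
  }

  structure(
    list(paths = setNames(paths, ontology$ids),
         ids = ontology$ids, idx = ontology$idx,
         cap = cap, exact = all(exact_node),
         exact_by_concept = setNames(exact_node, ontology$ids),
         ordinal = ordinal,
         depth = ontology$depth, root = ontology$root),
    class = "dewey_codebook")
}

#' @export
print.dewey_codebook <- function(x, ...) {
  np <- vapply(x$paths, length, integer(1))
  cat(sprintf("<dewey_codebook> %d concepts, cap %d, exact: %s (max %d encodings/concept)\n",
              length(x$ids), x$cap, x$exact, max(np)))
  invisible(x)
}

#' Human-readable Dewey encodings of a concept
#'
#' @param codebook a [build_dewey_codebook()] result.
#' @param id a concept id.
#' @return Character vector of `$`-rooted dot-separated ordinal encodings.
#' @export
dewey_encodings <- function(codebook, id) {
  stopifnot(inherits(codebook, "dewey_codebook"))
  ps <- codebook$paths[[id]]
  if (is.null(ps)) abort(sprintf("Concept '%s' is not encoded.", id))
  vapply(ps, function(p) {
    if (length(p) == 1L) return("$")
    ords <- vapply(seq(2L, length(p)), function(i) {
      codebook$ordinal[[p[i]]][[as.character(p[i - 1L])]]
    }, numeric(1))
    paste(c("$", ords), collapse = ".")
  }, character(1))
}

#' Minimum ISA path length between two concepts via their Dewey encodings
#'
#' The distance is the minimum over encoding pairs of
#' `(|e1| - lcp) + (|e2| - lcp)` where `lcp` is the longest common encoding
#' prefix, i.e. the path length through the lowest common ancestor realised by
#' those root paths. With an exact codebook this equals the minimum
#' common-ancestor path length in the DAG; with a truncated codebook it is an
#' upper bound.
#'
#' @param codebook a [build_dewey_codebook()] result.
#' @param c1,c2 concept ids.
#' @return Integer edge count; `0` iff `c1 == c2`.
#' @export
concept_distance <- function(codebook, c1, c2) {
  stopifnot(inherits(codebook, "dewey_codebook"))
  p1 <- codebook$paths[[c1]]
  p2 <- codebook$paths[[c2]]
  if (is.null(p1)) abort(sprintf("Unknown concept id '%s'.", c1))
  if (is.null(p2)) abort(sprintf("Unknown concept id '%s'.", c2))
  best <- Inf
  for (a in p1) for (b in p2) {
    m <- min(length(a), length(b))
    neq <- which(a[seq_len(m)] != b[seq_len(m)])
    lcp <- if (length(neq)) neq[1L] - 1L else m
    d <- (length(a) - lcp) + (length(b) - lcp)
    if (d < best) best <- d
  }
  as.integer(best)
}

#' Upper bound on any lowest-common-ancestor path length in the ontology
#'
#' Returns twice the maximum concept depth (minimum edge distance from the
#' root), the natural normaliser for the average-path-length dissimilarities:
#' any path through a common ancestor is at most `depth(a) + depth(b)`. For
#' small ontologies the realised diameter can be requested instead.
#'
#' @param ontology an [ehr_ontology].
#' @param method `"depth_bound"` (default, O(V)) or `"diameter"` (exact
#'   all-pairs maximum, quadratic; only sensible for small ontologies).
#' @param codebook required for `method = "diameter"`.
#' @return Integer edge count.
#' @export
max_path_length <- function(ontology, method = c("depth_bound", "diameter"),
                            codebook = NULL) {
  stopifnot(inherits(ontology, "ehr_ontology"))
  method <- match.arg(method)
  if (method == "depth_bound") return(2L * max(ontology$depth))
  if (is.null(codebook)) codebook <- build_dewey_codebook(ontology)
  ids <- ontology$ids
  best <- 0L
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    d <- concept_distance(codebook, ids[i], ids[j])
    if (d > best) best <- d
  }
  best
}
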