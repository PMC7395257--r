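# Shared fixtures and independent oracles for the test suite.

# Toy two-branch hierarchy used throughout: x1,x2 -> X; y1,y2 -> Y; X,Y -> R.
t1_edges <- function() {
  tibble::tribble(~child, ~parent,
                  "x1", "X", "x2", "X", "y1", "Y", "y2", "Y", "X", "R", "Y", "R")
}

t1_ontology <- function() ehr_ontology(t1_edges())

diamond_ontology <- function() {
  ehr_ontology(tibble::tribble(~child, ~parent,
                               "a", "p", "a", "q", "p", "r", "q", "r"))
}

# Independent random-DAG generator (deliberately unrelated to the package's
# layered simulator): node i > 1 picks 1-2 parents among nodes 1..i-1.
random_dag_edges <- function(n_nodes, seed, two_parent_prob = 0.35) {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n_nodes))
    rows <- lapply(seq(2L, n_nodes), function(i) {
      np <- 1L + (stats::runif(1) < two_parent_prob && i > 2L)
      parents <- sample(seq_len(i - 1L), np)
      tibble::tibble(child = ids[i], parent = ids[parents])
    })
    dplyr::bind_rows(rows)
  })
}

# BFS common-ancestor distance oracle via igraph: d(a, b) = min over common
# ancestors c of d_up(a, c) + d_up(b, c), with d_up shortest directed
# child->parent distances.
oracle_distance_matrix <- function(ontology) {
  g <- igraph::graph_from_data_frame(ontology$edges, directed = TRUE,
                                     vertices = ontology$ids)
  up <- igraph::distances(g, mode = "out")  # rows: from, following child->parent
  up <- up[ontology$ids, ontology$ids]
  n <- length(ontology$ids)
  best <- matrix(Inf, n, n)
  for (a in seq_len(n)) {
    best <- pmin(best, outer(up[, a], up[, a], `+`))
  }
  dimnames(best) <- list(ontology$ids, ontology$ids)
  best
}

# Package-side full distance matrix from the Dewey codebook (via the same
# kernel the retrieval path uses).
dewey_distance_matrix <- function(codebook) {
  D <- ehrmatch:::cpp_pair_dist_matrix(unname(codebook$paths))
  dimnames(D) <- list(codebook$ids, codebook$ids)
  D
}

# Small random cohort over an explicit concept vocabulary.
random_cohort <- function(n_visits, vocab, seed, max_events = 4L,
                          concepts_per_event = 4L) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_visits), function(v) {
      m <- sample(2:max_events, 1L)
      tibble::tibble(
        patient_id = sprintf("p%02d", v), visit_id = sprintf("v%02d", v),
        ordinal = seq_len(m),
        concepts = lapply(seq_len(m), function(.)
          sample(vocab, sample.int(concepts_per_event, 1L) + 1L)),
        negated = list(character(0)))
    })
    ehr_cohort(dplyr::bind_rows(rows))
  })
}

# Naive transliteration of the two-step prediction algorithm: enumerate every
# prefix split of every visit, score it with the scalar measure functions
# (codebook-only slow path for the APL family -- independent of the compiled
# kernel), keep each visit's most similar prefix, threshold, and count
# confidences directly.
naive_predict <- function(query_prefix, cohort, params, ontology, codebook,
                          exclude_visit = NULL) {
  tib <- tibble::as_tibble(cohort)
  vids <- setdiff(unique(tib$visit_id), exclude_visit)
  cfg <- params$measure_config
  matches <- list()
  for (vid in vids) {
    ev <- tib$concepts[tib$visit_id == vid][order(tib$ordinal[tib$visit_id == vid])]
    m <- length(ev)
    if (m < 2L) next
    best_k <- NA_integer_; best_d <- Inf
    for (k in seq_len(m - 1L)) {
      P <- unique(unlist(ev[seq_len(k)]))
      d <- switch(cfg$measure,
        boc = boc_dissimilarity(P, query_prefix),
        ca = if (length(P)) ca_dissimilarity(P, query_prefix, ontology, cfg) else Inf,
        apl = if (length(P)) apl_dissimilarity(P, query_prefix, codebook, cfg) else Inf,
        apl_sym = if (length(P)) apl_sym_dissimilarity(P, query_prefix, codebook, cfg) else Inf)
      if (d < best_d) { best_d <- d; best_k <- k }
    }
    if (best_d < params$tau) {
      matches[[vid]] <- unique(unlist(ev[seq(best_k + 1L, m)]))
    }
  }
  n <- length(matches)
  if (n == 0L) {
    return(tibble::tibble(concept = character(), confidence = numeric()))
  }
  all_concepts <- sort(unique(unlist(matches)))
  conf <- vapply(all_concepts,
                 function(cc) mean(vapply(matches, function(s) cc %in% s, logical(1))),
                 numeric(1))
  keep <- conf > params$lambda
  out <- tibble::tibble(concept = all_concepts[keep], confidence = unname(conf[keep]))
  out[order(-out$confidence, out$concept), ]
}

# Small planted-association fixture: two archetypes over the generated
# ontology with visits of 2-3 events; used by tuning/evaluation tests.
planted_fixture <- function(n_visits = 40L, seed = 11L, noise_rate = 0.05,
                            signal_strength = 0.9, concepts_per_event = 8) {
  ont <- generate_ontology(ontology_sim_config(depth = 3, branching = 4,
                                               multi_parent_prob = 0.05,
                                               seed = seed))
  cfg <- cohort_sim_config(
    n_visits = n_visits, concepts_per_event = concepts_per_event,
    prefix_pool_size = 12L, suffix_pool_size = 6L, n_archetypes = 2L,
    novelty_per_event = 3, noise_rate = noise_rate,
    signal_strength = signal_strength, seed = seed + 1L)
  sim <- generate_cohort(ont, cfg)
  list(ontology = ont, index = build_ehr_index(ont), sim = sim, config = cfg)
}
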