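#' Configuration for the synthetic ontology generator
#'
#' The generated ontology is a layered, rooted DAG: below the root sit
#' `branching^level` concepts per level down to `depth`. Every concept has one
#' primary parent in the level above (balanced assignment) and, with
#' probability `multi_parent_prob`, one extra parent from the same level, so
#' the hierarchy is a wide DAG rather than a tree — the shape that makes the
#' Dewey multi-path machinery non-trivial. Leaf concepts receive semantic
#' groups with exact per-subtree proportions given by `group_mix`, whose
#' default follows the observed mix in ICU records: disorders 36%, procedures
#' 22%, anatomy 20%, drugs 12%, physiology 10%.
#'
#' @param depth number of levels below the root (>= 2).
#' @param branching children per node (>= 1; leaves number `branching^depth`).
#' @param multi_parent_prob probability a non-root concept gains a second
#'   parent.
#' @param group_mix named proportions over semantic groups (must sum to 1).
#' @param seed integer seed.
#' @return An `ontology_sim_config` list.
#' @export
ontology_sim_config <- function(depth = 5L, branching = 5L,
                                multi_parent_prob = 0.05,
                                group_mix = c(disorders = 0.36, procedures = 0.22,
                                              anatomy = 0.20, chemicals_drugs = 0.12,
                                              physiology = 0.10),
                                seed = 1L) {
  depth <- as.integer(depth); branching <- as.integer(branching)
  if (is.na(depth) || depth < 2L) abort("`depth` must be >= 2.")
  if (is.na(branching) || branching < 1L) abort("`branching` must be >= 1.")
  assert_scalar_number(multi_parent_prob, "multi_parent_prob", min = 0, max = 1)
  if (is.null(names(group_mix)) || length(setdiff(names(group_mix), EHR_GROUPS))) {
    abort("`group_mix` must be named with valid semantic groups.")
  }
  if (abs(sum(group_mix) - 1) > 1e-8) abort("`group_mix` proportions must sum to 1.")
  structure(list(depth = depth, branching = branching,
                 multi_parent_prob = multi_parent_prob,
                 group_mix = group_mix, seed = as.integer(seed)),
            class = "ontology_sim_config")
}

# Exact-count allocation of `n` items to groups with proportions `mix`
# (largest-remainder rounding), returned shuffled.
allocate_groups <- function(n, mix) {
  base <- floor(n * mix)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * mix - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(names(mix), base))
}

#' Generate a synthetic layered ISA ontology
#'
#' @param config an [ontology_sim_config()].
#' @return An [ehr_ontology]; deterministic given the config (including its
#'   seed).
#' @export
generate_ontology <- function(config = ontology_sim_config()) {
  stopifnot(inherits(config, "ontology_sim_config"))
  withr::with_seed(config$seed, {
    b <- config$branching
    L <- config$depth
    level_ids <- c(list("ROOT"),
                   map(seq_len(L), function(l) sprintf("C%d_%05d", l, seq_len(b^l))))
    edges <- list()
    for (l in seq_len(L)) {
      child <- level_ids[[l + 1L]]
      parent_idx <- ceiling(seq_along(child) / b)
      edges[[length(edges) + 1L]] <-
        tibble(child = child, parent = level_ids[[l]][parent_idx])
      if (config$multi_parent_prob > 0 && length(level_ids[[l]]) > 1L) {
        extra <- which(runif(length(child)) < config$multi_parent_prob)
        if (length(extra)) {
          alt <- map_int(parent_idx[extra], function(p) {
            choices <- setdiff(seq_along(level_ids[[l]]), p)
            choices[sample.int(length(choices), 1L)]
          })
          edges[[length(edges) + 1L]] <-
            tibble(child = child[extra], parent = level_ids[[l]][alt])
        }
      }
    }
    edges <- bind_rows(edges)
    leaves <- level_ids[[L + 1L]]
    # exact group proportions within each top-level subtree (primary-parent
    # anchoring), so any subtree-anchored concept pool inherits the global mix
    block <- ceiling(seq_along(leaves) / b^(L - 1L))
    groups <- character(length(leaves))
    for (j in unique(block)) {
      sel <- which(block == j)
      groups[sel] <- allocate_groups(length(sel), config$group_mix)
    }
    internal <- setdiff(unlist(level_ids), leaves)
    metadata <- bind_rows(
      tibble(id = internal, label = internal, semantic_group = "other"),
      tibble(id = leaves, label = leaves, semantic_group = groups))
    ehr_ontology(edges, metadata)
  })
}

#' Default archetype specifications over a generated ontology
#'
#' An archetype is a latent clinical condition driving both what a patient's
#' record starts with and what follows: a prefix concept pool (what similar
#' patients present with) and a disjoint suffix signature pool (what tends to
#' happen next), plus the probability (`signal_strength`) that each signature
#' concept actually appears in a given patient's suffix. Prefix pools are
#' anchored at distinct top-level subtrees of the ontology — conditions are
#' ontologically coherent, which is what gives the path-length measures their
#' advantage — and suffix pools are drawn disjointly from a reserved subtree.
#' All pools are sampled with exact semantic-group stratification.
#'
#' @param ontology an [ehr_ontology] (typically from [generate_ontology()]).
#' @param n_archetypes number of archetypes.
#' @param prefix_pool_size,suffix_pool_size concepts per pool.
#' @param signal_strength probability a suffix-pool concept appears in a
#'   suffix, in `(0, 1]`.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return A tibble with columns `id`, `prefix_pool`, `suffix_pool`
#'   (list-columns) and `signal_strength`.
#' @export
generate_archetypes <- function(ontology, n_archetypes = 4L,
                                prefix_pool_size = 240L, suffix_pool_size = 106L,
                                signal_strength = 0.9, seed = NULL) {
  stopifnot(inherits(ontology, "ehr_ontology"))
  run <- function() {
    leaves <- leaf_concepts(ontology)
    groups <- setNames(ontology$concepts$semantic_group, ontology$concepts$id)
    top <- top_ancestor_blocks(ontology, leaves)
    blocks <- split(leaves, top)
    usable <- blocks[lengths(blocks) >= prefix_pool_size]
    anchored <- length(usable) >= n_archetypes + 1L
    if (!anchored) {
      warn("Not enough top-level subtrees to anchor archetypes; falling back to disjoint random pools.")
    }
    taken <- character(0)
    draw_pool <- function(cands, n) {
      cands <- setdiff(cands, taken)
      if (length(cands) < n) abort("Ontology too small for the requested archetype pools.")
      pool <- sample_stratified(cands, groups[cands], n)
      taken <<- c(taken, pool)
      pool
    }
    prefix_pools <- map(seq_len(n_archetypes), function(i) {
      cands <- if (anchored) usable[[i]] else leaves
      draw_pool(cands, prefix_pool_size)
    })
    reserve <- if (anchored) usable[[n_archetypes + 1L]] else leaves
    suffix_pools <- map(seq_len(n_archetypes), function(i) {
      draw_pool(reserve, suffix_pool_size)
    })
    tibble(id = sprintf("A%d", seq_len(n_archetypes)),
           prefix_pool = prefix_pools, suffix_pool = suffix_pools,
           signal_strength = signal_strength)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

leaf_concepts <- function(ontology) {
  ontology$ids[lengths(ontology$children) == 0L]
}

# Top-level ancestor block of each leaf: the root child reached by always
# following the minimum-depth parent (the primary parent in generated
# ontologies).
top_ancestor_blocks <- function(ontology, leaves) {
  root_i <- ontology$idx[[ontology$root]]
  top_of <- rep(NA_character_, length(ontology$ids))
  for (v in ontology$topo) {
    ps <- ontology$parents[[v]]
    if (length(ps) == 0L) next
    if (any(ps == root_i)) { top_of[v] <- ontology$ids[v]; next }
    best <- ps[which.min(ontology$depth[ps])]
    top_of[v] <- top_of[best]
  }
  top_of[ontology$idx[leaves]]
}

# Sample n items from cands preserving the group composition of cands
# (largest-remainder exact counts per group).
sample_stratified <- function(cands, groups, n) {
  by_g <- split(cands, groups)
  props <- lengths(by_g) / length(cands)
  counts <- floor(n * props)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * props - counts
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  counts <- pmin(counts, lengths(by_g))
  out <- unlist(map2(by_g, counts, ~ sample(.x, .y)), use.names = FALSE)
  # if capping left a shortfall, fill from anything unused
  if (length(out) < n) out <- c(out, sample(setdiff(cands, out), n - length(out)))
  sample(out)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults are calibrated to the printed descriptive statistics of the ICU
#' cohort the method was developed on: 80% two-event and 15% three-event
#' visits (the remaining 5% spread over 4-6 events), a mean of 187 concepts
#' per census event and 291 unique concepts per two-event visit. The
#' `persistence` default is derived from the latter pair: with 187 concepts
#' per event and 291 unique per two-event visit, consecutive events share
#' `2*187 - 291 = 83` concepts, so each concept of the previous event recurs
#' with probability `83/187 ~= 0.444`. `novelty_per_event` (new background
#' concepts introduced by each event after the second) is calibrated so the
#' cohort-wide mean of unique concepts per visit approaches the printed 325
#' while keeping the suffix content of longer visits predominantly
#' archetype-driven.
#'
#' @param n_visits number of visits to generate.
#' @param visit_length_mix named proportions over event counts (all >= 2,
#'   summing to 1).
#' @param concepts_per_event mean concept-set size per event.
#' @param persistence probability a concept of the previous event recurs in
#'   the next event.
#' @param signal_strength probability a suffix-pool concept appears in a
#'   visit's suffix (used when archetypes are generated here).
#' @param noise_rate probability mass of off-archetype concepts per event.
#' @param novelty_per_event mean count of previously unseen background
#'   concepts introduced by each event after the second.
#' @param n_archetypes,prefix_pool_size,suffix_pool_size archetype pool shape
#'   (used when `archetypes` is `NULL`).
#' @param archetypes optional archetype table from [generate_archetypes()].
#' @param seed integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_visits = 4000L,
                              visit_length_mix = c(`2` = 0.80, `3` = 0.15,
                                                   `4` = 0.03, `5` = 0.01, `6` = 0.01),
                              concepts_per_event = 187,
                              persistence = 83 / 187,
                              signal_strength = 0.9,
                              noise_rate = 0.05,
                              novelty_per_event = 70,
                              n_archetypes = 4L,
                              prefix_pool_size = 240L,
                              suffix_pool_size = 106L,
                              archetypes = NULL,
                              seed = 1L) {
  lengths_ <- as.integer(names(visit_length_mix))
  if (anyNA(lengths_) || any(lengths_ < 2L)) {
    abort("`visit_length_mix` must be named by integer event counts >= 2.")
  }
  if (abs(sum(visit_length_mix) - 1) > 1e-8) abort("`visit_length_mix` must sum to 1.")
  assert_scalar_number(concepts_per_event, "concepts_per_event", min = 1)
  assert_scalar_number(persistence, "persistence", min = 0, max = 1)
  assert_scalar_number(signal_strength, "signal_strength", min = 0, max = 1)
  if (signal_strength == 0) abort("`signal_strength` must be in (0, 1].")
  assert_scalar_number(noise_rate, "noise_rate", min = 0, max = 1)
  assert_scalar_number(novelty_per_event, "novelty_per_event", min = 0)
  structure(list(n_visits = as.integer(n_visits),
                 visit_length_mix = visit_length_mix,
                 concepts_per_event = concepts_per_event,
                 persistence = persistence, signal_strength = signal_strength,
                 noise_rate = noise_rate, novelty_per_event = novelty_per_event,
                 n_archetypes = as.integer(n_archetypes),
                 prefix_pool_size = as.integer(prefix_pool_size),
                 suffix_pool_size = as.integer(suffix_pool_size),
                 archetypes = archetypes, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Generate a synthetic cohort with planted prefix-to-suffix associations
#'
#' Each visit is assigned a latent archetype uniformly at random and an event
#' count from `visit_length_mix`. Event 1 (the planted prefix) draws its
#' concepts from the archetype's prefix pool plus a `noise_rate` fraction of
#' background leaves. Event 2 (the planted suffix signature) contains each
#' suffix-pool concept with probability `signal_strength`, each event-1
#' concept again with probability `persistence`, and background noise. Later
#' events carry concepts forward with `persistence`, introduce
#' `novelty_per_event` previously unseen background concepts (clinical
#' progression that no archetype explains), and re-mention earlier visit
#' concepts to keep the event size near `concepts_per_event`.
#'
#' Because similar prefixes share an archetype — and hence a suffix signature
#' — the method's core premise holds by construction, which is what makes
#' parameter-recovery experiments meaningful.
#'
#' @param ontology an [ehr_ontology]; its leaf concepts form the vocabulary.
#' @param config a [cohort_sim_config()].
#' @return A list with `cohort` (an [ehr_cohort]), `truth` (tibble `visit_id`,
#'   `archetype`; attribute `"archetypes"` holds the archetype table with each
#'   archetype's expected fresh suffix pool), and `archetypes`.
#' @export
generate_cohort <- function(ontology, config = cohort_sim_config()) {
  stopifnot(inherits(ontology, "ehr_ontology"),
            inherits(config, "cohort_sim_config"))
  withr::with_seed(config$seed, {
    archetypes <- config$archetypes %||%
      generate_archetypes(ontology, config$n_archetypes,
                          config$prefix_pool_size, config$suffix_pool_size,
                          config$signal_strength)
    leaves <- leaf_concepts(ontology)
    bad_pool <- setdiff(unique(unlist(c(archetypes$prefix_pool, archetypes$suffix_pool))),
                        ontology$ids)
    if (length(bad_pool)) abort("Archetype pools contain concepts outside the ontology.")
    mu <- config$concepts_per_event
    if (min(lengths(archetypes$prefix_pool)) < ceiling(mu * (1 - config$noise_rate))) {
      abort("Prefix pools are too small for `concepts_per_event`.")
    }
    lens <- as.integer(names(config$visit_length_mix))
    n <- config$n_visits
    arch_i <- sample.int(nrow(archetypes), n, replace = TRUE)
    m_v <- if (length(lens) == 1L) rep(lens, n)
           else sample(lens, n, replace = TRUE, prob = config$visit_length_mix)

    rows_vid <- character(0); rows_ord <- integer(0); rows_concepts <- list()
    p <- config$persistence
    for (v in seq_len(n)) {
      a <- archetypes[arch_i[v], ]
      ppool <- a$prefix_pool[[1L]]
      spool <- a$suffix_pool[[1L]]
      m <- m_v[v]
      events <- vector("list", m)
      # event 1: archetype presentation
      n1 <- rpois(1L, mu)
      n_noise <- rbinom(1L, n1, config$noise_rate)
      events[[1L]] <- unique(c(sample(ppool, min(n1 - n_noise, length(ppool))),
                               if (n_noise) sample(leaves, n_noise)))
      if (m >= 2L) {
        # event 2: suffix signature + persistence + noise
        carried <- events[[1L]][runif(length(events[[1L]])) < p]
        sig <- spool[runif(length(spool)) < a$signal_strength]
        n_noise <- rpois(1L, config$noise_rate * mu)
        events[[2L]] <- unique(c(carried, sig,
                                 if (n_noise) sample(leaves, n_noise)))
      }
      if (m >= 3L) {
        union_so_far <- unique(c(events[[1L]], events[[2L]]))
        for (j in 3:m) {
          prev <- events[[j - 1L]]
          carried <- prev[runif(length(prev)) < p]
          n_novel <- rpois(1L, config$novelty_per_event)
          novel <- if (n_novel) sample(setdiff(leaves, union_so_far),
                                       min(n_novel, length(leaves))) else character(0)
          n_noise <- rpois(1L, config$noise_rate * mu)
          noise <- if (n_noise) sample(leaves, n_noise) else character(0)
          ev <- unique(c(carried, novel, noise))
          target <- rpois(1L, mu)
          deficit <- target - length(ev)
          if (deficit > 0L) {
            avail <- setdiff(union_so_far, ev)
            if (length(avail)) ev <- c(ev, sample(avail, min(deficit, length(avail))))
          }
          events[[j]] <- ev
          union_so_far <- unique(c(union_so_far, ev))
        }
      }
      rows_vid <- c(rows_vid, rep(sprintf("V%05d", v), m))
      rows_ord <- c(rows_ord, seq_len(m))
      rows_concepts <- c(rows_concepts, events)
    }
    cohort <- ehr_cohort(tibble(
      patient_id = sub("^V", "P", rows_vid), visit_id = rows_vid,
      ordinal = rows_ord, ward = NA_character_,
      concepts = rows_concepts, negated = list(character(0))))
    truth <- tibble(visit_id = sprintf("V%05d", seq_len(n)),
                    archetype = archetypes$id[arch_i])
    attr(truth, "archetypes") <- archetypes
    list(cohort = cohort, truth = truth, archetypes = archetypes)
  })
}

#' Write the simulation ground truth as a JSONL sidecar
#'
#' @param truth the `truth` tibble from [generate_cohort()].
#' @param path output path.
#' @return `truth`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(truth))) {
    writeLines(jsonlite::toJSON(list(visit_id = truth$visit_id[i],
                                     archetype = truth$archetype[i]),
                                auto_unbox = TRUE), con)
  }
  archetypes <- attr(truth, "archetypes")
  if (!is.null(archetypes)) {
    for (i in seq_len(nrow(archetypes))) {
      writeLines(jsonlite::toJSON(list(
        archetype = archetypes$id[i],
        expected_fresh_suffix = as.list(archetypes$suffix_pool[[i]])),
        auto_unbox = TRUE), con)
    }
  }
  invisible(truth)
}

#' Descriptive statistics of a cohort
#'
#' Reports the statistics used to calibrate (and check) the simulator: the
#' visit-length distribution, mean concepts per event, mean unique concepts
#' per visit (overall and by visit length), and — when an ontology is
#' supplied — the semantic-group shares of per-visit unique concepts.
#'
#' @param cohort a nonempty [ehr_cohort].
#' @param ontology optional [ehr_ontology] for semantic-group shares.
#' @return An `ehr_cohort_stats` list; see [glance.ehr_cohort_stats()] for a
#'   one-row summary.
#' @export
cohort_statistics <- function(cohort, ontology = NULL) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  tib <- as_tibble(cohort)
  if (nrow(tib) == 0L) abort("Empty cohort.")
  per_visit <- tib |>
    group_by(.data$visit_id) |>
    summarise(n_events = dplyr::n(),
              unique_concepts = dplyr::n_distinct(unlist(.data$concepts)),
              .groups = "drop")
  length_pct <- per_visit |>
    count(.data$n_events, name = "n_visits") |>
    mutate(pct = 100 * .data$n_visits / sum(.data$n_visits))
  by_length <- per_visit |>
    group_by(.data$n_events) |>
    summarise(mean_unique_concepts = mean(.data$unique_concepts), .groups = "drop")
  group_shares <- NULL
  if (!is.null(ontology)) {
    ont <- if (inherits(ontology, "ehr_index")) ontology$ontology else ontology
    groups <- setNames(ont$concepts$semantic_group, ont$concepts$id)
    mentions <- tib |>
      group_by(.data$visit_id) |>
      summarise(concept = list(unique(unlist(.data$concepts))), .groups = "drop") |>
      pull(.data$concept) |> unlist()
    g <- groups[mentions]
    g[is.na(g)] <- "other"
    tabg <- table(factor(g, levels = EHR_GROUPS))
    group_shares <- tibble(semantic_group = names(tabg),
                           n = as.integer(tabg),
                           pct = 100 * as.integer(tabg) / sum(tabg))
  }
  structure(list(
    n_visits = nrow(per_visit), n_events = nrow(tib),
    visit_length_pct = length_pct,
    mean_concepts_per_event = mean(lengths(tib$concepts)),
    mean_unique_per_visit = mean(per_visit$unique_concepts),
    unique_by_length = by_length,
    group_shares = group_shares), class = "ehr_cohort_stats")
}

#' @export
print.ehr_cohort_stats <- function(x, ...) {
  cat(sprintf("<ehr_cohort_stats> %d visits, %d events\n", x$n_visits, x$n_events))
  cat(sprintf("  mean concepts/event: %.1f; mean unique concepts/visit: %.1f\n",
              x$mean_concepts_per_event, x$mean_unique_per_visit))
  cat("  visits by event count: ",
      paste(sprintf("%d: %.1f%%", x$visit_length_pct$n_events,
                    x$visit_length_pct$pct), collapse = ", "), "\n", sep = "")
  if (!is.null(x$group_shares)) {
    gs <- x$group_shares |> filter(.data$n > 0)
    cat("  concept groups: ",
        paste(sprintf("%s %.1f%%", gs$semantic_group, gs$pct), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
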