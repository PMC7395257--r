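test_that("ontology construction validates the ISA DAG", {
  ont <- t1_ontology()
  expect_s3_class(ont, "ehr_ontology")
  expect_equal(nrow(ont$concepts), 7L)
  expect_equal(ont$root, "R")

  # two-node cycle
  expect_error(ehr_ontology(tibble::tibble(child = c("a", "b"), parent = c("b", "a"))),
               "Cycle")
  # self-loop
  expect_error(ehr_ontology(tibble::tibble(child = "a", parent = "a")), "Cycle")
  # empty input
  expect_error(ehr_ontology(tibble::tibble(child = character(), parent = character())),
               "Empty")
  # several parentless concepts get a virtual root
  multi <- ehr_ontology(tibble::tibble(child = c("a", "b"), parent = c("r1", "r2")))
  expect_equal(multi$root, "ROOT")
  expect_equal(nrow(multi$concepts), 5L)
  expect_equal(unname(ancestor_depths(multi, "a")[["ROOT"]]), 2L)
})

test_that("metadata assigns labels and semantic groups, defaulting to other", {
  meta <- tibble::tibble(id = c("x1", "X"), label = c("pneumonia", "lung disorder"),
                         semantic_group = c("disorders", "disorders"))
  ont <- ehr_ontology(t1_edges(), meta)
  g <- semantic_groups(ont, c("x1", "y1"))
  expect_equal(unname(g), c("disorders", "other"))
  expect_error(semantic_groups(ont, "nope"), "Unknown concept")
  expect_error(
    ehr_ontology(t1_edges(), tibble::tibble(id = "x1", label = "a", semantic_group = "bogus")),
    "Unknown semantic group")
})

test_that("ancestor_depths returns minimum edge distances, excluding self", {
  ont <- t1_ontology()
  expect_equal(ancestor_depths(ont, "x1"), c(X = 1L, R = 2L))
  expect_equal(ancestor_depths(ont, "R"), setNames(integer(0), character(0)))
  expect_error(ancestor_depths(ont, "zz"), "Unknown concept")
  dia <- diamond_ontology()
  expect_equal(sort(ancestor_depths(dia, "a")), c(p = 1L, q = 1L, r = 2L))
})

test_that("Dewey codebook enumerates root paths and flags truncation", {
  ont <- t1_ontology()
  cb <- build_dewey_codebook(ont)
  expect_true(cb$exact)
  expect_true(all(lengths(cb$paths) == 1L))  # a tree: one root path per node
  expect_equal(dewey_encodings(cb, "x1"), "$.1.1")

  dia <- diamond_ontology()
  cbd <- build_dewey_codebook(dia, cap = 16L)
  expect_true(cbd$exact)
  expect_length(cbd$paths[["a"]], 2L)

  expect_error(build_dewey_codebook(ont, cap = 0), "cap")

  # stacked diamonds: 2^4 root paths for the bottom node; cap 8 truncates
  edges <- dplyr::bind_rows(lapply(1:4, function(l) {
    tibble::tibble(child = c(paste0("u", l), paste0("v", l), paste0("b", l), paste0("b", l)),
                   parent = c(paste0("b", l - 1), paste0("b", l - 1),
                              paste0("u", l), paste0("v", l)))
  }))
  edges$parent[edges$parent == "b0"] <- "top"
  dense <- ehr_ontology(edges)
  cb_full <- build_dewey_codebook(dense, cap = 32L)
  cb_trunc <- build_dewey_codebook(dense, cap = 8L)
  expect_true(cb_full$exact)
  expect_false(cb_trunc$exact)
  expect_length(cb_full$paths[["b4"]], 16L)
  expect_lte(length(cb_trunc$paths[["b4"]]), 8L)
  # truncated distances stay upper bounds on the exact ones
  oracle <- oracle_distance_matrix(dense)
  for (pair in list(c("b4", "u1"), c("u4", "v4"), c("b4", "top"))) {
    expect_gte(concept_distance(cb_trunc, pair[1], pair[2]),
               oracle[pair[1], pair[2]])
    expect_equal(concept_distance(cb_full, pair[1], pair[2]),
                 unname(oracle[pair[1], pair[2]]))
  }
})

test_that("concept_distance matches hand-checked values and axioms", {
  cb <- build_dewey_codebook(t1_ontology())
  expect_equal(concept_distance(cb, "x1", "x2"), 2L)
  expect_equal(concept_distance(cb, "x1", "y1"), 4L)
  expect_equal(concept_distance(cb, "x1", "x1"), 0L)
  expect_equal(concept_distance(cb, "x1", "X"), 1L)
  expect_equal(concept_distance(cb, "x1", "y1"), concept_distance(cb, "y1", "x1"))
  expect_error(concept_distance(cb, "x1", "zz"), "Unknown concept")
})

test_that("concept_distance equals the BFS common-ancestor oracle on random DAGs", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    n <- sample(5:30, 1L)
    ont <- ehr_ontology(random_dag_edges(n, seed = 1000L + s))
    cb <- build_dewey_codebook(ont, cap = 64L)
    if (!cb$exact) next
    expect_equal(unname(dewey_distance_matrix(cb)),
                 unname(oracle_distance_matrix(ont)),
                 info = sprintf("seed %d", s))
  }
})

test_that("ancestor depths agree with shortest encoding-prefix chains", {
  for (s in 1:10) {
    ont <- ehr_ontology(random_dag_edges(20L, seed = 2000L + s))
    cb <- build_dewey_codebook(ont, cap = 64L)
    cid <- sample(ont$ids, 1L)
    depths <- ancestor_depths(ont, cid)
    for (a in names(depths)) {
      # shortest suffix length below the ancestor across encoding pairs
      best <- Inf
      for (p in cb$paths[[cid]]) {
        pos <- which(ont$ids[p] == a)
        if (length(pos)) best <- min(best, length(p) - max(pos))
      }
      expect_equal(unname(depths[[a]]), best)
    }
  }
})

test_that("triangle-through-root bound holds", {
  ont <- ehr_ontology(random_dag_edges(25L, seed = 77L))
  cb <- build_dewey_codebook(ont, cap = 64L)
  mp <- max_path_length(ont)
  D <- dewey_distance_matrix(cb)
  depth <- ont$depth[ont$ids]
  bound <- outer(depth, depth, `+`)
  expect_true(all(D <= bound))
  expect_true(all(bound <= mp))
})

test_that("max_path_length doubles the maximum depth; diameter option exact", {
  expect_equal(max_path_length(t1_ontology()), 4L)
  star <- ehr_ontology(tibble::tibble(child = letters[1:5], parent = "root"))
  expect_equal(max_path_length(star), 2L)
  chain <- ehr_ontology(tibble::tibble(child = paste0("c", 1:5),
                                       parent = c("c0", paste0("c", 1:4))))
  expect_equal(max_path_length(chain), 10L)
  # depth bound can exceed the realised diameter (chain: diameter is 5)
  expect_equal(max_path_length(chain, method = "diameter"), 5L)
  expect_equal(max_path_length(t1_ontology(), method = "diameter"), 4L)
})

test_that("ontology TSV files round-trip", {
  ont <- ehr_ontology(t1_edges(),
                      tibble::tibble(id = "x1", label = "pneumonia",
                                     semantic_group = "disorders"))
  ef <- withr::local_tempfile(fileext = ".tsv")
  mf <- withr::local_tempfile(fileext = ".tsv")
  write_ontology(ont, ef, mf)
  ont2 <- load_ontology(ef, mf)
  expect_equal(ont2$concepts, ont$concepts)
  expect_equal(dplyr::arrange(ont2$edges, child, parent),
               dplyr::arrange(ont$edges, child, parent))
})
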