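worked_example_cohort <- function() {
  ehr_cohort(dplyr::bind_rows(
    tibble::tibble(patient_id = "p1", visit_id = "v1", ordinal = 1:2,
                   concepts = list("Trauma", "Intubated")),
    tibble::tibble(patient_id = "p2", visit_id = "v2", ordinal = 1:2,
                   concepts = list(c("Fever", "Cough"), c("Intubated", "Seizure"))),
    tibble::tibble(patient_id = "p3", visit_id = "v3", ordinal = 1:2,
                   concepts = list(c("Fracture", "Bleeding"), "Seizure")),
    tibble::tibble(patient_id = "p4", visit_id = "v4", ordinal = 1:2,
                   concepts = list("Jaundice", "Phototherapy")),
    tibble::tibble(patient_id = "p5", visit_id = "v5", ordinal = 1:2,
                   concepts = list(c("Fever", "Cough", "Apnea"),
                                   c("Intubated", "Seizure", "Edema")))))
}

test_that("best_prefix_match minimises over splits, ties to smaller k", {
  co <- ehr_cohort(tibble::tibble(
    patient_id = "p", visit_id = "v", ordinal = 1:3,
    concepts = list(c("a", "b", "c", "d"), c("x", "y"), "z")))
  q <- c("a", "b", "c", "d", "e")
  bm <- best_prefix_match(q, co, measure_config("boc"))
  expect_equal(bm$best_k, 1L)
  expect_equal(bm$dissimilarity, 0.2)

  # a visit whose full prefix equals the query scores 0 at some k
  co2 <- ehr_cohort(tibble::tibble(patient_id = "p", visit_id = "v", ordinal = 1:3,
                                   concepts = list("a", "b", "c")))
  bm2 <- best_prefix_match(c("a", "b"), co2, measure_config("boc"))
  expect_equal(bm2$best_k, 2L)
  expect_equal(bm2$dissimilarity, 0)

  # tie between k = 1 and k = 2 resolves to k = 1
  co3 <- ehr_cohort(tibble::tibble(patient_id = "p", visit_id = "v", ordinal = 1:3,
                                   concepts = list("a", "a", "b")))
  bm3 <- best_prefix_match(c("a", "x"), co3, measure_config("boc"))
  expect_equal(bm3$best_k, 1L)

  single <- ehr_cohort(tibble::tibble(patient_id = "p", visit_id = "v", ordinal = 1L,
                                      concepts = list("a")))
  expect_error(best_prefix_match("a", single, measure_config("boc")), "single event")
})

test_that("the worked example returns exactly the full-confidence concepts", {
  co <- worked_example_cohort()
  params <- prediction_params(0.5, 0.7, measure_config("boc"))
  q <- c("Fever", "Cough")
  matches <- find_similar_records(q, co, params)
  expect_setequal(matches$visit_id, c("v2", "v5"))
  preds <- predict_concepts(matches, params)
  expect_setequal(preds$concept, c("Intubated", "Seizure"))
  expect_equal(preds$confidence, c(1, 1))
  # nothing at or below the threshold is emitted: Edema has confidence 0.5
  expect_false("Edema" %in% preds$concept)
})

test_that("threshold inequalities are strict on both steps", {
  co <- worked_example_cohort()
  q <- c("Fever", "Cough")
  # tau = 0: even an exact prefix match (dissimilarity 0) is excluded
  expect_equal(nrow(find_similar_records(q, co, prediction_params(0, 0.5, measure_config("boc")))), 0L)
  # tau above the maximum score matches every eligible visit
  all_m <- find_similar_records(q, co, prediction_params(1.01, 0.5, measure_config("boc")))
  expect_equal(nrow(all_m), 5L)
  # lambda = 1 emits nothing even for confidence 1
  params <- prediction_params(0.5, 1, measure_config("boc"))
  expect_equal(nrow(predict_concepts(find_similar_records(q, co, params), params)), 0L)
})

test_that("confidence is the fraction of matched suffixes containing the concept", {
  sets <- list(c("c", "u1"), c("c", "u2"), "c", "u3", "u4")
  co <- ehr_cohort(dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::tibble(patient_id = sprintf("p%d", i), visit_id = sprintf("v%d", i),
                   ordinal = 1:2, concepts = list(c("q1", "q2"), sets[[i]]))
  })))
  q <- c("q1", "q2")
  m <- find_similar_records(q, co, prediction_params(0.5, 0.5, measure_config("boc")))
  expect_equal(nrow(m), 5L)
  p5 <- predict_concepts(m, prediction_params(0.5, 0.5, measure_config("boc")))
  expect_true("c" %in% p5$concept)
  expect_equal(p5$confidence[p5$concept == "c"], 0.6)
  expect_equal(p5$support[p5$concept == "c"], 3L)
  p7 <- predict_concepts(m, prediction_params(0.5, 0.7, measure_config("boc")))
  expect_false("c" %in% p7$concept)
  # deterministic ordering: confidence descending, then concept id
  expect_equal(p5$concept, p5$concept[order(-p5$confidence, p5$concept)])
  # empty match set predicts nothing, without error
  empty <- find_similar_records(q, co, prediction_params(0, 0.5, measure_config("boc")))
  expect_equal(nrow(predict_concepts(empty)), 0L)
})

test_that("self-exclusion removes the query's own visit", {
  co <- worked_example_cohort()
  q <- prefix_concepts(co, 1, visit_id = "v2")
  params <- prediction_params(1.01, 0.5, measure_config("boc"))
  m <- find_similar_records(q, co, params, exclude_visit = "v2")
  expect_false("v2" %in% m$visit_id)
  m2 <- find_similar_records(q, co, params)
  expect_true("v2" %in% m2$visit_id)
})

test_that("raising tau never shrinks matches; raising lambda never grows predictions", {
  fix <- planted_fixture(n_visits = 15L, seed = 21L)
  co <- fix$sim$cohort
  q <- prefix_concepts(co, 1, visit_id = "V00003")
  cfg <- measure_config("apl_sym")
  prev_n <- -1L
  for (tau in c(0.1, 0.3, 0.6, 1, 2.1)) {
    m <- find_similar_records(q, co, prediction_params(tau, 0.5, cfg), fix$index,
                              exclude_visit = "V00003")
    expect_gte(nrow(m), prev_n)
    prev_n <- nrow(m)
  }
  m <- find_similar_records(q, co, prediction_params(1, 0, cfg), fix$index,
                            exclude_visit = "V00003")
  prev <- Inf
  for (lam in c(0.1, 0.3, 0.5, 0.8)) {
    p <- predict_concepts(m, prediction_params(1, lam, cfg))
    expect_lte(nrow(p), prev)
    expect_true(all(p$confidence > lam & p$confidence <= 1))
    expect_true(all(p$support <= nrow(m)))
    prev <- nrow(p)
  }
})

test_that("explanations count supporting visits sharing each query concept", {
  co <- ehr_cohort(dplyr::bind_rows(
    tibble::tibble(patient_id = "p1", visit_id = "v1", ordinal = 1:2,
                   concepts = list(c("A", "C"), "T")),
    tibble::tibble(patient_id = "p2", visit_id = "v2", ordinal = 1:2,
                   concepts = list(c("A", "B"), "T"))))
  params <- prediction_params(1.01, 0.5, measure_config("boc"))
  q <- c("A", "B")
  m <- find_similar_records(q, co, params)
  p <- predict_concepts(m, params)
  ex <- explain_prediction(p, m, co, concept = "T")
  expect_equal(setNames(ex$n_support, ex$prefix_concept), c(A = 2L, B = 1L))
  expect_error(explain_prediction(p, m, co, concept = "nope"), "not emitted")

  # no supporting visit shares any query concept -> empty highlight map
  co2 <- ehr_cohort(dplyr::bind_rows(
    tibble::tibble(patient_id = "p1", visit_id = "v1", ordinal = 1:2,
                   concepts = list("X", "T")),
    tibble::tibble(patient_id = "p2", visit_id = "v2", ordinal = 1:2,
                   concepts = list("Y", "T"))))
  m2 <- find_similar_records("Q", co2, params)
  p2 <- predict_concepts(m2, params)
  expect_equal(nrow(explain_prediction(p2, m2, co2, concept = "T")), 0L)
})

test_that("pipeline equals the naive transliteration on random cohorts", {
  vocab_ont <- ehr_ontology(random_dag_edges(15L, seed = 400L))
  idx <- build_ehr_index(vocab_ont)
  cb <- build_dewey_codebook(vocab_ont)
  for (s in 1:10) {
    co <- random_cohort(sample(5:12, 1L), vocab_ont$ids, seed = 500L + s)
    q <- withr::with_seed(600L + s, sample(vocab_ont$ids, 4L))
    for (meas in c("boc", "apl_sym", "ca")) {
      params <- prediction_params(
        tau = withr::with_seed(700L + s, stats::runif(1, 0.2, 1.2)),
        lambda = withr::with_seed(800L + s, stats::runif(1, 0.1, 0.8)),
        measure_config(meas))
      got <- predict_concepts(
        find_similar_records(q, co, params, idx), params)
      want <- naive_predict(q, co, params, vocab_ont, cb)
      expect_equal(got$concept, want$concept,
                   info = sprintf("seed %d measure %s", s, meas))
      expect_equal(got$confidence, want$confidence,
                   info = sprintf("seed %d measure %s", s, meas))
    }
  }
})

test_that("prediction reports serialise to JSONL", {
  co <- worked_example_cohort()
  params <- prediction_params(0.5, 0.7, measure_config("boc"))
  m <- find_similar_records(c("Fever", "Cough"), co, params)
  p <- predict_concepts(m, params)
  ex <- explain_prediction(p, m, co)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_predictions(p, path, explanation = ex)
  lines <- readLines(path)
  expect_length(lines, 2L)
  obj <- jsonlite::fromJSON(lines[[1]])
  expect_equal(obj$confidence, 1)
  expect_true(all(c("concept", "support", "supporting_visits", "highlighted") %in% names(obj)))
})
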