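mini_eval_cohort <- function() {
  # three visits with identical single-event prefixes and unequal suffixes
  ehr_cohort(dplyr::bind_rows(
    tibble::tibble(patient_id = "p1", visit_id = "v1", ordinal = 1:2,
                   concepts = list("q", "t1")),
    tibble::tibble(patient_id = "p2", visit_id = "v2", ordinal = 1:2,
                   concepts = list("q", c("t1", "t2", "t3", "t4"))),
    tibble::tibble(patient_id = "p3", visit_id = "v3", ordinal = 1:2,
                   concepts = list("q", "t1"))))
}

test_that("query cases enumerate valid splits", {
  co <- ehr_cohort(dplyr::bind_rows(
    tibble::tibble(patient_id = "p1", visit_id = "v1", ordinal = 1:3,
                   concepts = list("a", "b", "c")),
    tibble::tibble(patient_id = "p2", visit_id = "v2", ordinal = 1:2,
                   concepts = list("a", "b")),
    tibble::tibble(patient_id = "p3", visit_id = "v3", ordinal = 1L,
                   concepts = list("a"))))
  all_k <- make_query_cases(co, "all_k")
  expect_equal(nrow(all_k), 3L)  # two splits for v1, one for v2, none for v3
  expect_equal(all_k$k[all_k$visit_id == "v1"], 1:2)
  first <- make_query_cases(co, "first_k_only")
  expect_equal(nrow(first), 2L)
  expect_true(all(first$k == 1L))
  expect_setequal(
    all_k$query_prefix[[which(all_k$visit_id == "v1" & all_k$k == 2)]], c("a", "b"))
  # truth suffixes are nonempty by construction
  expect_true(all(lengths(all_k$truth_suffix) > 0))
})

test_that("confusion counts partition the universe in both modes", {
  U <- sprintf("u%02d", 1:10)
  cc <- confusion_counts(predicted = U[1:3], truth = U[2:4], universe = U)
  expect_equal(cc[, c("tp", "fp", "fn", "tn")],
               tibble::tibble(tp = 2L, fp = 1L, fn = 1L, tn = 6L))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, cc$universe_size)

  # fresh mode removes the prefix from every set, universe included
  ccf <- confusion_counts(predicted = c("a", "b", "c"), truth = c("b", "c", "d"),
                          universe = c(letters[1:4], sprintf("u%d", 1:6)),
                          mode = "fresh", prefix = "c")
  expect_equal(ccf[, c("tp", "fp", "fn", "tn")],
               tibble::tibble(tp = 1L, fp = 1L, fn = 1L, tn = 6L))
  expect_equal(ccf$universe_size, 9L)

  cc0 <- confusion_counts(character(0), character(0), U)
  expect_equal(unlist(cc0[, c("tp", "fp", "fn", "tn")]),
               c(tp = 0L, fp = 0L, fn = 0L, tn = 10L))

  expect_error(confusion_counts("a", "zz", universe = letters[1:5]), "outside the universe")
  expect_error(confusion_counts("zz", "a", universe = letters[1:5]), "outside the universe")

  # property: random sets always partition; fresh universe is exactly U minus prefix
  withr::with_seed(123L, {
    for (i in 1:25) {
      uni <- sprintf("c%02d", 1:20)
      pred <- sample(uni, sample.int(8, 1))
      tru <- sample(uni, sample.int(8, 1))
      pre <- sample(uni, sample.int(6, 1))
      a <- confusion_counts(pred, tru, uni, "all", pre)
      f <- confusion_counts(pred, tru, uni, "fresh", pre)
      expect_equal(a$tp + a$fp + a$fn + a$tn, a$universe_size)
      expect_equal(f$tp + f$fp + f$fn + f$tn, f$universe_size)
      expect_equal(f$universe_size, length(setdiff(uni, pre)))
    }
  })
})

test_that("metrics follow the harmonic-mean definition with 0/0 flagged as 0", {
  m <- compute_metrics(tibble::tibble(tp = 2L, fp = 1L, fn = 1L, tn = 6L))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
  expect_equal(m$f_measure, 2 / 3)
  expect_length(m$undefined[[1]], 0L)

  perfect <- compute_metrics(tibble::tibble(tp = 5L, fp = 0L, fn = 0L, tn = 5L))
  expect_equal(unlist(perfect[, c("sensitivity", "specificity", "precision", "f_measure")]),
               c(sensitivity = 1, specificity = 1, precision = 1, f_measure = 1))

  zero <- compute_metrics(tibble::tibble(tp = 0L, fp = 2L, fn = 3L, tn = 5L))
  expect_equal(zero$sensitivity, 0)
  expect_equal(zero$precision, 0)
  expect_equal(zero$f_measure, 0)
  expect_true("f_measure" %in% zero$undefined[[1]])

  degenerate <- compute_metrics(tibble::tibble(tp = 0L, fp = 0L, fn = 0L, tn = 0L))
  expect_setequal(degenerate$undefined[[1]],
                  c("sensitivity", "specificity", "precision", "f_measure"))
})

test_that("cohort splits are reproducible visit-level partitions", {
  co <- random_cohort(100L, sprintf("c%02d", 1:30), seed = 50L)
  sp <- split_cohort(co, 0.2, seed = 7L)
  train_ids <- unique(sp$train$visit_id)
  test_ids <- unique(sp$test$visit_id)
  expect_length(train_ids, 20L)
  expect_length(test_ids, 80L)
  expect_length(intersect(train_ids, test_ids), 0L)
  expect_setequal(c(train_ids, test_ids), unique(co$visit_id))
  sp2 <- split_cohort(co, 0.2, seed = 7L)
  expect_identical(sp, sp2)
  sp8 <- split_cohort(co, 0.8, seed = 7L)
  expect_length(unique(sp8$train$visit_id), 80L)
  expect_error(split_cohort(co, 0), "strictly between")
  one <- ehr_cohort(tibble::tibble(patient_id = "p", visit_id = "v", ordinal = 1:2,
                                   concepts = list("a", "b")))
  expect_error(split_cohort(one, 0.5), "at least 2 visits")
})

test_that("micro-pooled F differs from macro mean-of-F where it should", {
  co <- mini_eval_cohort()
  params <- prediction_params(0.5, 0.6, measure_config("boc"))
  micro <- evaluate_cohort(co, co, params, mode = "all", strata = "all",
                           query_mode = "first_k_only")
  macro <- evaluate_cohort(co, co, params, mode = "all", strata = "all",
                           query_mode = "first_k_only", aggregate = "macro")
  # hand-checked: per-case F = 1, 0.4, 1 -> macro 0.8; pooled counts
  # tp=3 fp=0 fn=3 -> micro F = 2/3
  expect_equal(micro$f_measure, 2 / 3)
  expect_equal(macro$f_measure, 0.8)
  expect_equal(micro$tp, 3L)
  expect_equal(micro$fn, 3L)
})

test_that("grid_tune's argmax matches independent exhaustive re-evaluation", {
  fix <- planted_fixture(n_visits = 24L, seed = 61L)
  co <- fix$sim$cohort
  taus <- c(0.15, 0.5, 1.2)
  lams <- c(0.25, 0.5, 0.75)
  tuning <- grid_tune(co, measure_config("apl_sym"), taus, lams,
                      mode = "fresh", context = fix$index)
  grid <- tidy(tuning)
  # independent route: evaluate each cell with the evaluation entry point
  for (r in seq_len(nrow(grid))) {
    ev <- evaluate_cohort(co, co, prediction_params(grid$tau[r], grid$lambda[r],
                                                    measure_config("apl_sym")),
                          mode = "fresh", strata = "all", context = fix$index)
    expect_equal(grid$f_measure[r], ev$f_measure, info = sprintf("cell %d", r))
  }
  best_by_enum <- grid |>
    dplyr::arrange(dplyr::desc(f_measure), tau, lambda) |>
    dplyr::slice(1)
  expect_equal(tuning$best_tau, best_by_enum$tau)
  expect_equal(tuning$best_lambda, best_by_enum$lambda)
  expect_gt(max(grid$f_measure), 0)

  # single-cell grid returns that cell
  single <- grid_tune(co, measure_config("boc"), 0.9, 0.5, context = fix$index)
  expect_equal(c(single$best_tau, single$best_lambda), c(0.9, 0.5))

  # all-zero grid: tie rule picks the smallest pair
  zero <- grid_tune(co, measure_config("boc"), c(1e-9, 2e-9), c(0.98, 0.99),
                    context = fix$index)
  expect_equal(c(zero$best_tau, zero$best_lambda), c(1e-9, 0.98))
  expect_true(all(zero$grid$f_measure == 0))

  expect_error(grid_tune(co, measure_config("boc"), numeric(0), 0.5), "nonempty")
})

test_that("stratified evaluation restricts every set to the stratum", {
  meta <- tibble::tibble(id = c("q", "d1", "p1"),
                         label = c("query", "disorder", "procedure"),
                         semantic_group = c("other", "disorders", "procedures"))
  edges <- tibble::tibble(child = c("q", "d1", "p1"), parent = "root")
  ont <- ehr_ontology(edges, meta)
  idx <- build_ehr_index(ont)
  co <- ehr_cohort(dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(patient_id = sprintf("p%d", i), visit_id = sprintf("v%d", i),
                   ordinal = 1:2, concepts = list("q", "d1"))
  })))
  params <- prediction_params(0.5, 0.6, measure_config("boc"))
  ev <- evaluate_cohort(co, co, params, strata = c("all", "disorders", "procedures"),
                        context = idx)
  dis <- ev[ev$stratum == "disorders", ]
  pro <- ev[ev$stratum == "procedures", ]
  expect_gt(dis$tp, 0L)
  expect_equal(pro$tp, 0L)
  expect_equal(pro$fp, 0L)
  # stratum universe is only that group's concepts
  expect_equal(dis$universe_size, 1L)
  # strata = "all" equals the unstratified evaluation
  only_all <- evaluate_cohort(co, co, params, strata = "all")
  expect_equal(ev[ev$stratum == "all", ], only_all)
  expect_error(evaluate_cohort(co, co, params, strata = "bogus", context = idx),
               "Unknown stratum")
  expect_error(evaluate_cohort(co, co, params, strata = "disorders"),
               "need an")
})

test_that("fresh mode with prefix covering the truth flags undefined metrics", {
  cc <- confusion_counts(predicted = character(0), truth = c("a"),
                         universe = c("a", "b"), mode = "fresh",
                         prefix = c("a", "b"))
  expect_equal(cc$universe_size, 0L)
  m <- compute_metrics(cc)
  expect_setequal(m$undefined[[1]],
                  c("sensitivity", "specificity", "precision", "f_measure"))
})

test_that("metrics tables serialise as TSV", {
  co <- mini_eval_cohort()
  ev <- evaluate_cohort(co, co, prediction_params(0.5, 0.6, measure_config("boc")),
                        strata = "all", query_mode = "first_k_only")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_tsv(ev, path)
  back <- utils::read.delim(path)
  expect_equal(back$f_measure, ev$f_measure)
  expect_true(all(c("stratum", "mode", "tau", "lambda", "tp", "fp", "fn", "tn",
                    "sensitivity", "specificity", "precision", "f_measure")
                  %in% names(back)))
})
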