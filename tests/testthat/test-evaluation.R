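test_that("per-entity precision and recall follow the set definitions", {
  scores <- c(A = 0.9, B = 0.4, C = 0.8)
  pr <- per_entity_pr(scores, c("A", "B"), 0.5)
  expect_equal(unname(pr), c(1 / 2, 1 / 2))

  # perfect prediction at a threshold below all true scores
  pr2 <- per_entity_pr(c(A = 0.9, B = 0.8), c("A", "B"), 0.5)
  expect_equal(unname(pr2), c(1, 1))

  # nothing predicted: precision undefined
  pr3 <- per_entity_pr(c(A = 0.1), c("A"), 0.5)
  expect_true(is.na(pr3["precision"]))
  expect_equal(unname(pr3["recall"]), 0)

  expect_error(per_entity_pr(scores, character(0), 0.5), "empty truth")

  # random instances vs exhaustive set arithmetic
  for (seed in c(21, 22)) {
    inst <- rand_eval_instance(seed, max_entities = 5, max_terms = 10,
                               allow_empty_truth = FALSE)
    for (t in c(0.2, 0.5, 0.8)) {
      for (e in rownames(inst$pred$scores)) {
        got <- per_entity_pr(inst$pred$scores[e, ], inst$truth_sets[[e]], t)
        P <- colnames(inst$pred$scores)[inst$pred$scores[e, ] >= t]
        R <- inst$truth_sets[[e]]
        tp <- length(intersect(P, R))
        expect_equal(unname(got["recall"]), tp / length(R))
        if (length(P) > 0) expect_equal(unname(got["precision"]), tp / length(P))
      }
    }
  }
})

test_that("a perfect single-entity prediction attains Fmax 1", {
  scores <- matrix(c(1, 1, 0), 1, 3,
                   dimnames = list("e1", c("g1", "g2", "g3")))
  truth <- as_propagated(tibble::tibble(entity = "e1", term = c("g1", "g2")))
  ev <- evaluate_predictions(go_prediction(scores, merged = TRUE), truth)
  expect_equal(ev$fmax, 1)
  expect_equal(ev$n, 1)
  expect_equal(ev$coverage, 1)
})

test_that("all-zero scores only evaluate at the zero threshold", {
  scores <- matrix(0, 2, 3, dimnames = list(c("e1", "e2"), c("g1", "g2", "g3")))
  truth <- as_propagated(tibble::tibble(entity = c("e1", "e2"),
                                        term = c("g1", "g2")))
  ev <- evaluate_predictions(go_prediction(scores, merged = TRUE), truth)
  tb <- tidy(ev)
  expect_true(all(tb$recall[tb$t > 0] == 0))
  expect_true(all(tb$m[tb$t > 0] == 0))
  # at t = 0 everything is predicted: recall 1, precision = |R|/|universe|
  expect_equal(tb$recall[tb$t == 0], 1)
  expect_equal(tb$precision[tb$t == 0], 1 / 3)
  expect_equal(ev$t_max, 0)
})

test_that("evaluation matches the brute-force oracle on random instances", {
  for (seed in c(31, 32, 33)) {
    inst <- rand_eval_instance(seed)
    grid <- seq(0, 1, by = 0.01)
    got <- suppressWarnings(
      evaluate_predictions(inst$pred, inst$truth, config = eval_config(grid))
    )
    want <- oracle_evaluate(inst$pred$scores, inst$truth_sets, grid)
    expect_equal(tidy(got)$precision, want$sweep$precision, tolerance = 1e-12)
    expect_equal(tidy(got)$recall, want$sweep$recall, tolerance = 1e-12)
    expect_equal(got$fmax, want$fmax, tolerance = 1e-12)
  }
})

test_that("evaluation guards its contracts", {
  scores <- matrix(0.5, 1, 2, dimnames = list("e1", c("g1", "g2")))
  truth <- as_propagated(tibble::tibble(entity = "zz", term = "g1"))
  expect_error(
    evaluate_predictions(go_prediction(scores, merged = TRUE), truth),
    "disjoint"
  )
  expect_error(
    evaluate_predictions(go_prediction(scores, merged = FALSE),
                         as_propagated(tibble::tibble(entity = "e1", term = "g1"))),
    "merged"
  )
  unprop <- tibble::tibble(entity = "e1", term = "g1")
  expect_error(
    evaluate_predictions(go_prediction(scores, merged = TRUE), unprop),
    "propagated"
  )
})

test_that("recall and m(t) never increase with the threshold", {
  for (seed in c(41, 42)) {
    inst <- rand_eval_instance(seed)
    ev <- suppressWarnings(evaluate_predictions(inst$pred, inst$truth))
    tb <- tidy(ev)
    expect_true(all(diff(tb$recall) <= 1e-12))
    expect_true(all(diff(tb$m) <= 0))
  }
})

test_that("self-evaluation of binary truth scores is perfect", {
  dag <- rand_test_dag(15, 55)
  set.seed(56)
  annots <- propagate_annotations(dag, tibble::tibble(
    entity = rep(sprintf("e%d", 1:6), 2),
    term = sample(dag$terms, 12, replace = TRUE)
  ))
  lab <- build_label_matrix(annots, select_terms(dag, annots, min_count = 1))
  pred <- go_prediction(max_merge(lab, dag), merged = TRUE)
  ev <- suppressWarnings(evaluate_predictions(pred, annots, dag,
                                              eval_config(thresholds = 0.5)))
  expect_equal(ev$fmax, 1)
})

test_that("coverage counts entities with a scoring term", {
  scores <- matrix(c(0.9, 0, 0, 0, 0.2, 0), 3, 2,
                   dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  pred <- go_prediction(scores, merged = TRUE)
  expect_equal(prediction_coverage(pred, 0.5), 1)
  expect_equal(prediction_coverage(pred, 0.1), 2)
  expect_equal(prediction_coverage(go_prediction(scores * 0, merged = TRUE), 0.5), 0)
  # every entity above threshold -> N
  expect_equal(prediction_coverage(go_prediction(scores * 0 + 1, merged = TRUE), 0.5), 3)

  # counting oracle on a random instance
  inst <- rand_eval_instance(61, allow_empty_truth = FALSE)
  for (t in c(0.3, 0.7)) {
    manual <- sum(apply(inst$pred$scores, 1, function(r) any(r >= t)))
    expect_equal(prediction_coverage(inst$pred, t), manual)
  }
})

test_that("the PR curve exports (recall, precision) pairs in threshold order", {
  inst <- rand_eval_instance(71, allow_empty_truth = FALSE)
  ev <- suppressWarnings(evaluate_predictions(inst$pred, inst$truth))
  curve <- pr_curve(ev)
  expect_equal(names(curve), c("t", "recall", "precision"))
  expect_equal(curve$t, sort(curve$t))
  want <- oracle_evaluate(inst$pred$scores, inst$truth_sets, curve$t)
  expect_equal(curve$precision, want$sweep$precision, tolerance = 1e-12)
  expect_equal(curve$recall, want$sweep$recall, tolerance = 1e-12)
  expect_s3_class(autoplot(ev), "ggplot")

  # a perfect predictor sits on the precision = 1 line
  scores <- matrix(c(1, 1), 1, 2, dimnames = list("e", c("g1", "g2")))
  truth <- as_propagated(tibble::tibble(entity = "e", term = c("g1", "g2")))
  evp <- evaluate_predictions(go_prediction(scores, merged = TRUE), truth)
  expect_true(all(pr_curve(evp)$precision == 1, na.rm = TRUE))
})
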