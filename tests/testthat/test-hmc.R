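# shared toy setup: two well-separated Gaussian clusters labeled by the two
# branches of a 7-term DAG
make_cluster_data <- function(n = 200, dim = 16, sep = 3, seed = 1) {
  set.seed(seed)
  dag <- toy7_dag()
  ids <- sprintf("e%03d", seq_len(n))
  cl <- rep(1:2, length.out = n)
  X <- matrix(rnorm(n * dim), n, dim, dimnames = list(ids, NULL))
  X[cl == 1, 1] <- X[cl == 1, 1] + sep
  X[cl == 2, 1] <- X[cl == 2, 1] - sep
  leaf_sets <- list(c("c1", "c2"), c("c3", "c4"))
  annots <- propagate_annotations(dag, tibble::tibble(
    entity = rep(ids, each = 2),
    term = unlist(lapply(cl, function(k) leaf_sets[[k]]))
  ))
  terms <- select_terms(dag, annots, min_count = 1)
  labels <- build_label_matrix(annots, terms)[ids, , drop = FALSE]
  list(dag = dag, ids = ids, cluster = cl, X = X, labels = labels,
       annots = annots, terms = terms)
}

test_that("featurize looks rows up and falls back to zero vectors", {
  emb <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), NULL))
  f <- featurize(c("a", "zz", "b"), emb)
  expect_equal(f["a", ], emb["a", ], ignore_attr = TRUE)
  expect_equal(unname(f["zz", ]), c(0, 0, 0))
  expect_equal(f["b", ], emb["b", ], ignore_attr = TRUE)
  for (i in seq_len(nrow(f))) {
    id <- rownames(f)[i]
    want <- if (id %in% rownames(emb)) emb[id, ] else rep(0, 3)
    expect_equal(unname(f[i, ]), unname(want))
  }
})

test_that("maximum merge propagates scores upward and is idempotent", {
  dag <- go_dag(list(p = character(0), c = "p"), "BP")
  raw <- matrix(c(0.9, 0.2), 1, 2, dimnames = list("e", c("c", "p")))
  merged <- max_merge(raw, dag)
  expect_equal(unname(merged[, "p"]), 0.9)  # max(0.2 raw parent, 0.9 child)
  expect_equal(unname(merged[, "c"]), 0.9)  # leaf keeps its raw score
  expect_identical(max_merge(merged, dag), merged)

  # 5-term chain, scores given bottom-up, vs an independent bottom-up scan
  chain <- go_dag(list(t5 = character(0), t4 = "t5", t3 = "t4",
                       t2 = "t3", t1 = "t2"), "BP")
  raw5 <- matrix(c(0.1, 0.8, 0.3, 0.6, 0.2), 1, 5,
                 dimnames = list("e", c("t1", "t2", "t3", "t4", "t5")))
  expect_equal(max_merge(raw5, chain), oracle_max_merge(raw5, chain))
  expect_equal(unname(max_merge(raw5, chain)[1, ]),
               c(0.1, 0.8, 0.8, 0.8, 0.8))

  # random scores on random DAGs vs the descendant-max oracle
  for (seed in c(2, 8)) {
    d <- rand_test_dag(20, seed)
    set.seed(seed)
    r <- matrix(runif(5 * 20), 5, 20,
                dimnames = list(sprintf("e%d", 1:5), d$terms))
    m <- max_merge(r, d)
    expect_equal(m, oracle_max_merge(r, d))
    expect_identical(max_merge(m, d), m)
  }
})

test_that("an untrained model still yields valid, consistent scores", {
  dat <- make_cluster_data(n = 20, seed = 3)
  cfg <- hmc_config(hidden_units = 16, max_epochs = 0, seed = 5)
  model <- train_hmc(dat$X, dat$labels, dat$dag, cfg)
  expect_equal(model$best_epoch, 0)
  pred <- predict(model, dat$X)
  expect_true(pred$merged)
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
  merged_again <- max_merge(pred, dat$dag)
  expect_equal(merged_again$scores, pred$scores)
})

test_that("training recovers a planted cluster-to-term signal", {
  wins <- 0
  for (seed in 1:5) {
    dat <- make_cluster_data(n = 200, seed = seed)
    tr <- dat$ids[1:160]
    te <- dat$ids[161:200]
    cfg <- hmc_config(hidden_units = 64, max_epochs = 30, patience = 5,
                      seed = seed)
    model <- train_hmc(dat$X[tr, ], dat$labels[tr, ], dat$dag, cfg)
    pred <- predict(model, dat$X[te, , drop = FALSE])
    truth <- dat$annots[dat$annots$entity %in% te, ]
    attr(truth, "propagated") <- TRUE
    ev <- suppressWarnings(
      evaluate_predictions(pred, truth, dat$dag, eval_config())
    )
    if (ev$fmax >= 0.9) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("label-permuted training collapses to the frequency baseline", {
  dat <- make_cluster_data(n = 200, seed = 7)
  tr <- dat$ids[1:160]
  te <- dat$ids[161:200]
  truth <- dat$annots[dat$annots$entity %in% te, ]
  attr(truth, "propagated") <- TRUE

  perm_annots <- permute_labels(
    as_propagated(dat$annots[dat$annots$entity %in% tr, ]), seed = 1
  )
  perm_labels <- build_label_matrix(perm_annots, dat$terms)[tr, ]
  cfg <- hmc_config(hidden_units = 64, max_epochs = 30, patience = 5, seed = 7)
  perm_model <- train_hmc(dat$X[tr, ], perm_labels, dat$dag, cfg)
  perm_ev <- suppressWarnings(evaluate_predictions(
    predict(perm_model, dat$X[te, , drop = FALSE]), truth, dat$dag
  ))

  # prior baseline: every entity scored with the training label frequencies
  prior <- colMeans(dat$labels[tr, ])
  prior_scores <- matrix(prior, length(te), length(prior), byrow = TRUE,
                         dimnames = list(te, names(prior)))
  prior_ev <- suppressWarnings(evaluate_predictions(
    go_prediction(max_merge(prior_scores, dat$dag), merged = TRUE),
    truth, dat$dag
  ))
  expect_lt(abs(perm_ev$fmax - prior_ev$fmax), 0.15)

  # and the real model clearly beats the permuted one
  real_model <- train_hmc(dat$X[tr, ], dat$labels[tr, ], dat$dag, cfg)
  real_ev <- suppressWarnings(evaluate_predictions(
    predict(real_model, dat$X[te, , drop = FALSE]), truth, dat$dag
  ))
  expect_gt(real_ev$fmax, perm_ev$fmax + 0.2)
})

test_that("prediction is deterministic and validates input dimensions", {
  dat <- make_cluster_data(n = 30, seed = 9)
  cfg <- hmc_config(hidden_units = 16, max_epochs = 3, seed = 2)
  model <- train_hmc(dat$X, dat$labels, dat$dag, cfg)
  p1 <- predict(model, dat$X)
  p2 <- predict(model, dat$X)
  expect_identical(p1, p2)
  expect_error(predict(model, dat$X[, 1:5]), "dimension")

  # a zero-vector entity gets a well-defined merged score row
  z <- matrix(0, 1, ncol(dat$X), dimnames = list("ghost", NULL))
  pz <- predict(model, z)
  expect_true(all(is.finite(pz$scores)))
  expect_true(pz$merged)

  # training rejects degenerate inputs
  expect_error(train_hmc(dat$X, dat$labels * 0, dat$dag, cfg), "no positive labels")
  expect_error(train_hmc(dat$X[1, , drop = FALSE],
                         dat$labels[1, , drop = FALSE], dat$dag, cfg),
               "at least two")
})

test_that("training runs are reproducible and tidiers expose the fit", {
  dat <- make_cluster_data(n = 40, seed = 11)
  cfg <- hmc_config(hidden_units = 16, max_epochs = 5, seed = 13)
  m1 <- train_hmc(dat$X, dat$labels, dat$dag, cfg)
  m2 <- train_hmc(dat$X, dat$labels, dat$dag, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(predict(m1, dat$X)$scores, predict(m2, dat$X)$scores)

  td <- tidy(m1)
  expect_setequal(td$term, dat$terms)
  gl <- glance(m1)
  expect_equal(gl$n_terms, length(dat$terms))
  expect_s3_class(autoplot(m1), "ggplot")

  long <- tidy(predict(m1, dat$X))
  expect_setequal(names(long), c("entity", "term", "score"))
  expect_equal(nrow(long), nrow(dat$X) * length(dat$terms))
})
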