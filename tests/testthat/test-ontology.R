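test_that("OBO parsing handles chains, alt_ids, obsolete terms and cycles", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: mid", "namespace: biological_process",
    "is_a: GO:1 ! root", "alt_id: GO:22", "",
    "[Term]", "id: GO:3", "name: leaf", "namespace: biological_process",
    "is_a: GO:2", "",
    "[Term]", "id: GO:9", "name: gone", "namespace: biological_process",
    "is_a: GO:1", "is_obsolete: true", ""
  ), f)
  dag <- read_obo(f)
  expect_setequal(dag$terms, c("GO:1", "GO:2", "GO:3"))
  expect_equal(dag$parents, list(`GO:1` = character(0), `GO:2` = "GO:1",
                                 `GO:3` = "GO:2"))
  expect_equal(unname(dag$roots["BP"]), "GO:1")
  expect_equal(unname(resolve_terms(dag, "GO:22")), "GO:2")

  fc <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: A", "namespace: biological_process", "is_a: B", "",
    "[Term]", "id: B", "namespace: biological_process", "is_a: A", "",
    "[Term]", "id: R", "namespace: biological_process", ""
  ), fc)
  expect_error(read_obo(fc), "cycle")
})

test_that("written DAGs round-trip and reachability matches the closure oracle", {
  for (seed in c(3, 17)) {
    dag <- rand_test_dag(50, seed)
    f <- withr::local_tempfile(fileext = ".obo")
    write_obo(dag, f)
    back <- read_obo(f)
    expect_setequal(back$terms, dag$terms)
    expect_equal(lapply(back$parents[dag$terms], sort),
                 lapply(dag$parents, sort))
    # reachability of the parsed DAG equals the matrix-power closure
    anc <- term_ancestors(back)
    clo <- oracle_closure(dag)
    for (t in dag$terms) {
      expect_setequal(anc[[t]], colnames(clo)[clo[t, ]])
    }
  }
})

test_that("propagation closes annotation sets under the ancestor relation", {
  dag <- chain_dag()
  out <- propagate_annotations(dag, tibble::tibble(entity = "e1", term = "leaf"))
  expect_setequal(out$term, c("leaf", "mid", "root"))
  expect_true(isTRUE(attr(out, "propagated")))

  empty <- propagate_annotations(dag, tibble::tibble(entity = character(),
                                                     term = character()))
  expect_equal(nrow(empty), 0)

  dia <- diamond_dag()
  out2 <- propagate_annotations(dia, tibble::tibble(entity = "x", term = "bottom"))
  clo <- oracle_closure(dia)
  expect_setequal(out2$term, c("bottom", colnames(clo)[clo["bottom", ]]))
  expect_equal(nrow(out2), 4)

  expect_error(
    propagate_annotations(dag, tibble::tibble(entity = "e9", term = "nope")),
    "e9.*nope"
  )
})

test_that("propagation equals the transitive-closure oracle on random DAGs", {
  for (seed in 1:20) {
    dag <- rand_test_dag(sample(10:60, 1), seed)
    set.seed(seed + 500)
    ents <- sprintf("e%d", 1:5)
    annots <- tibble::tibble(
      entity = rep(ents, each = 2),
      term = sample(dag$terms, 10, replace = TRUE)
    )
    got <- propagate_annotations(dag, annots)
    clo <- oracle_closure(dag)
    for (e in ents) {
      direct <- unique(annots$term[annots$entity == e])
      want <- unique(c(direct, unlist(lapply(direct, function(t) {
        colnames(clo)[clo[t, ]]
      }))))
      expect_setequal(got$term[got$entity == e], want)
    }
    # idempotent and monotone
    again <- propagate_annotations(dag, got)
    expect_equal(dplyr::arrange(again, entity, term),
                 dplyr::arrange(got, entity, term), ignore_attr = TRUE)
    extra <- propagate_annotations(
      dag, dplyr::bind_rows(annots, tibble::tibble(entity = "e1",
                                                   term = dag$terms[1]))
    )
    expect_true(all(paste(got$term[got$entity == "e1"]) %in%
                      extra$term[extra$entity == "e1"]))
  }
})

test_that("term selection filters by count and orders children before parents", {
  dag <- toy7_dag()
  annots <- propagate_annotations(dag, tibble::tibble(
    entity = c("a", "b", "c", "d"),
    term = c("c1", "c1", "c3", "c2")
  ))
  all_used <- select_terms(dag, annots, min_count = 1)
  expect_setequal(all_used, c("b1", "b2", "c1", "c2", "c3"))  # root excluded
  expect_true(which(all_used == "c1") < which(all_used == "b1"))
  expect_equal(select_terms(dag, annots, min_count = 99), character(0))
  expect_error(select_terms(dag, annots, min_count = 0), "min_count")
  expect_error(select_terms(dag, tibble::tibble(entity = "a", term = "c1"),
                            min_count = 1), "propagated")

  # counting oracle on a seeded fixture
  dag2 <- rand_test_dag(30, 99)
  set.seed(100)
  annots2 <- propagate_annotations(dag2, tibble::tibble(
    entity = rep(sprintf("e%d", 1:20), each = 2),
    term = sample(dag2$terms, 40, replace = TRUE)
  ))
  sel <- select_terms(dag2, annots2, min_count = 5)
  counts <- table(unique(annots2)$term)
  manual <- names(counts)[counts >= 5]
  manual <- setdiff(manual, dag2$roots)
  expect_setequal(sel, manual)
})

test_that("label matrices encode set membership and respect the hierarchy", {
  dag <- toy7_dag()
  annots <- propagate_annotations(dag, tibble::tibble(
    entity = c("a", "b"), term = c("c1", "c3")
  ))
  terms <- select_terms(dag, annots, min_count = 1)
  lab <- build_label_matrix(annots, terms)
  expect_equal(sort(rownames(lab)), c("a", "b"))
  expect_equal(lab["a", "c1"], 1)
  expect_equal(lab["a", "b1"], 1)
  expect_equal(lab["a", "c3"], 0)
  # child = 1 implies selected ancestors = 1, columnwise
  expect_true(all(lab[, "b1"] >= lab[, "c1"]))
  expect_true(all(lab[, "b2"] >= lab[, "c3"]))

  # an entity with no selected terms keeps an all-zero row
  annots2 <- as_propagated(tibble::tibble(
    entity = c("a", "zz"), term = c("c1", "root")
  ))
  lab2 <- build_label_matrix(annots2, terms)
  expect_true("zz" %in% rownames(lab2))
  expect_equal(sum(lab2["zz", ]), 0)

  # set-membership oracle on a random fixture
  dag3 <- rand_test_dag(25, 5)
  set.seed(6)
  annots3 <- propagate_annotations(dag3, tibble::tibble(
    entity = rep(sprintf("e%d", 1:8), 3),
    term = sample(dag3$terms, 24, replace = TRUE)
  ))
  terms3 <- select_terms(dag3, annots3, min_count = 2)
  lab3 <- build_label_matrix(annots3, terms3)
  for (e in rownames(lab3)) {
    for (t in terms3) {
      expect_equal(unname(lab3[e, t]),
                   as.numeric(t %in% annots3$term[annots3$entity == e]))
    }
  }
})

test_that("annotation tables load with IEA filtering", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("e1\tGO:1\tEXP", "e1\tGO:2\tIEA", "e2\tGO:1\tIDA"), f)
  a <- read_annotations(f)
  expect_equal(nrow(a), 2)
  expect_false("GO:2" %in% a$term)
  a2 <- read_annotations(f, keep_iea = TRUE)
  expect_equal(nrow(a2), 3)
})
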