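# Small fixtures built in code at test time.

# chain root -> mid -> leaf
chain_dag <- function() {
  go_dag(list(root = character(0), mid = "root", leaf = "mid"), "BP")
}

# diamond: bottom has two parents sharing one grandparent
diamond_dag <- function() {
  go_dag(list(
    top = character(0), left = "top", right = "top",
    bottom = c("left", "right")
  ), "BP")
}

# seven terms, two branches of two leaves each — used for recovery tests
toy7_dag <- function() {
  go_dag(list(
    root = character(0),
    b1 = "root", b2 = "root",
    c1 = "b1", c2 = "b1", c3 = "b2", c4 = "b2"
  ), "BP")
}

# random rooted DAG built directly in the test (1-2 parents per term)
rand_test_dag <- function(n_terms, seed) {
  set.seed(seed)
  ids <- sprintf("X%03d", seq_len(n_terms))
  parents <- setNames(vector("list", n_terms), ids)
  parents[[1]] <- character(0)
  for (i in 2:n_terms) {
    k <- sample(seq_len(min(2L, i - 1L)), 1)
    parents[[i]] <- sample(ids[seq_len(i - 1)], k)
  }
  go_dag(parents, "BP")
}

# a small two-block heterogeneous network: miRNAs in two planted blocks
two_block_network <- function(n_per_block = 25, p_in = 0.5, p_out = 0.02,
                              seed = 1) {
  set.seed(seed)
  ids <- sprintf("mir%03d", seq_len(2 * n_per_block))
  block <- rep(1:2, each = n_per_block)
  edges <- list()
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      p <- if (block[i] == block[j]) p_in else p_out
      if (runif(1) < p) {
        edges[[length(edges) + 1]] <- data.frame(
          u = ids[i], v = ids[j], weight = 1, layer = "coexpr"
        )
      }
    }
  }
  net <- build_global_network(list(do.call(rbind, edges)), quiet = TRUE)
  list(net = net, ids = ids, block = block)
}

# annotations tibble with the propagated flag set (for direct construction)
as_propagated <- function(df) {
  attr(df, "propagated") <- TRUE
  df
}

# random prediction/truth instance over a shared term universe
rand_eval_instance <- function(seed, max_entities = 20, max_terms = 15,
                               allow_empty_truth = TRUE) {
  set.seed(seed)
  n_e <- sample(2:max_entities, 1)
  n_t <- sample(3:max_terms, 1)
  entities <- sprintf("e%02d", seq_len(n_e))
  terms <- sprintf("g%02d", seq_len(n_t))
  scores <- matrix(runif(n_e * n_t), n_e, n_t, dimnames = list(entities, terms))
  truth_sets <- lapply(setNames(entities, entities), function(e) {
    k <- sample(0:n_t, 1)
    if (!allow_empty_truth) k <- max(1L, k)
    sort(sample(terms, k))
  })
  # at least one entity must have truth, else evaluation is undefined
  if (all(lengths(truth_sets) == 0)) {
    truth_sets[[1]] <- sort(sample(terms, 2))
  }
  truth_tbl <- do.call(rbind, lapply(names(truth_sets), function(e) {
    if (length(truth_sets[[e]]) == 0) return(NULL)
    data.frame(entity = e, term = truth_sets[[e]])
  }))
  list(
    pred = go_prediction(scores, merged = TRUE),
    truth_sets = truth_sets,
    truth = as_propagated(tibble::as_tibble(truth_tbl))
  )
}
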