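#' Embedding hyper-parameters
#'
#' Defaults follow the LINE conventions used throughout this package:
#' initial learning rate 0.025 with linear decay, 10 negative samples per
#' positive draw, 64 total dimensions split equally between the first- and
#' second-order halves. `total_samples` is the number of SGD edge draws per
#' half; the desk-scale default is 1e6 (production-scale runs use far more).
#'
#' @param dim Total embedding dimension (positive even integer; half per
#'   proximity order).
#' @param n_negative Negative samples per positive edge draw (>= 1).
#' @param total_samples SGD edge draws per order.
#' @param rho0 Initial learning rate.
#' @param seed Integer seed; fixed seed => bit-identical embeddings.
#' @return A `line_config` list.
#' @export
line_config <- function(dim = 64, n_negative = 10, total_samples = 1e6,
                        rho0 = 0.025, seed = 1L) {
  if (dim < 2 || dim %% 2 != 0) {
    stop("dim must be a positive even integer (split between the two orders)",
         call. = FALSE)
  }
  if (n_negative < 1) stop("n_negative must be >= 1", call. = FALSE)
  if (total_samples < 0) stop("total_samples must be >= 0", call. = FALSE)
  if (rho0 <= 0) stop("rho0 must be > 0", call. = FALSE)
  structure(
    list(dim = as.integer(dim), n_negative = as.integer(n_negative),
         total_samples = as.double(total_samples), rho0 = rho0,
         seed = as.integer(seed)),
    class = "line_config"
  )
}

# directed edge list (both directions per undirected edge) with a 0-based
# node index over nodes that touch at least one edge
directed_edges <- function(net) {
  stopifnot(inherits(net, "het_network"))
  e <- net$edges
  if (nrow(e) == 0) stop("cannot embed an edgeless graph", call. = FALSE)
  nodes <- sort(unique(c(e$u, e$v)))
  idx <- setNames(seq_along(nodes) - 1L, nodes)
  list(
    nodes = nodes,
    src = c(idx[e$u], idx[e$v]),
    dst = c(idx[e$v], idx[e$u]),
    weight = c(e$weight, e$weight)
  )
}

#' O(1) weighted sampling (alias method)
#'
#' Builds the alias table used for edge and noise-node sampling inside the
#' LINE trainer; exposed so the sampling distribution can be inspected and
#' tested directly.
#'
#' @param weights Positive finite weights.
#' @return An `alias_table` (list with `prob`, `alias`, `n`).
#' @export
alias_table <- function(weights) {
  t <- alias_build_cpp(as.double(weights))
  structure(list(prob = t$prob, alias = t$alias, n = length(weights)),
            class = "alias_table")
}

#' @rdname alias_table
#' @param table An `alias_table`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Integer vector of 1-based indices drawn proportionally to
#'   `weights`.
#' @export
alias_sample <- function(table, n, seed = 1L) {
  stopifnot(inherits(table, "alias_table"))
  alias_sample_cpp(table$prob, table$alias, as.integer(n), as.integer(seed))
}

#' Train a single LINE proximity order
#'
#' Runs stochastic gradient descent with negative sampling over
#' `config$total_samples` weighted edge draws, optimizing either first-order
#' proximity (direct edge weight; both endpoint vectors updated) or
#' second-order proximity (shared neighbourhoods; a separate context-vector
#' table is maintained during training and discarded). Noise nodes are drawn
#' proportionally to weighted degree^0.75; the learning rate decays linearly
#' from `rho0`.
#'
#' @param net A `het_network`.
#' @param config A [line_config()]; `config$dim` here is the dimension of
#'   this half.
#' @param order `"first"` or `"second"`.
#' @param dim Dimension of this half (defaults to `config$dim %/% 2`).
#' @return Numeric matrix (nodes x dim, rownames = node ids) with attribute
#'   `loss`: the mean negative-sampling loss per training window.
#' @export
line_train <- function(net, config = line_config(), order = c("first", "second"),
                       dim = config$dim %/% 2L) {
  order <- match.arg(order)
  d <- directed_edges(net)
  fit <- line_train_cpp(
    src = as.integer(d$src), dst = as.integer(d$dst),
    weight = d$weight, n_nodes = length(d$nodes), dim = as.integer(dim),
    order = if (order == "first") 1L else 2L,
    n_negative = config$n_negative, total_samples = config$total_samples,
    rho0 = config$rho0, seed = config$seed
  )
  m <- fit$embedding
  rownames(m) <- d$nodes
  stopifnot(all(is.finite(m)))
  attr(m, "loss") <- fit$loss
  m
}

#' Embed a heterogeneous network with LINE
#'
#' Trains the first- and second-order halves independently (dim/2 each),
#' L2-normalizes every node vector within each half so neither half
#' dominates, and concatenates them. Nodes that touch no edge receive no
#' row; downstream code assigns such entities the zero vector (see
#' [featurize()]).
#'
#' @param net A `het_network`.
#' @param config A [line_config()].
#' @return Numeric matrix (nodes x dim) with rownames = node ids and
#'   attribute `halves`: factor tagging columns `"first"`/`"second"`.
#' @export
line_embedding <- function(net, config = line_config()) {
  half <- config$dim %/% 2L
  cfg1 <- config
  cfg2 <- config
  # distinct deterministic streams per half, derived from the one seed
  cfg1$seed <- as.integer(config$seed %% .Machine$integer.max)
  cfg2$seed <- as.integer((config$seed + 1000003L) %% .Machine$integer.max)
  e1 <- line_train(net, cfg1, order = "first", dim = half)
  e2 <- line_train(net, cfg2, order = "second", dim = half)
  out <- cbind(l2_normalize_rows(e1), l2_normalize_rows(e2))
  colnames(out) <- c(paste0("first_", seq_len(half)), paste0("second_", seq_len(half)))
  attr(out, "halves") <- rep(c("first", "second"), each = half)
  out
}

# rows scaled to unit L2 norm (zero rows left as zero)
l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Write / read embeddings in word2vec text format
#'
#' Header line `n_nodes dim`, then one row per node:
#' `id v1 v2 ... vd`, space-separated.
#'
#' @param emb Embedding matrix with rownames.
#' @param path Output path.
#' @export
write_embedding <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  writeLines(paste(rownames(emb), apply(emb, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  })), con)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- lapply(strsplit(lines[-1], " ", fixed = TRUE),
                  function(p) p[nzchar(p)])
  ids <- vapply(parts, `[`, character(1), 1)
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  if (nrow(m) != hdr[1] || ncol(m) != hdr[2]) {
    stop("embedding file header disagrees with its contents", call. = FALSE)
  }
  rownames(m) <- ids
  m
}
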