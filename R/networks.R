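#' Edge layers of the heterogeneous network
#'
#' The global graph is assembled from six undirected layers: three
#' entity-similarity layers (miRNA co-expression, protein-protein interaction,
#' disease phenotype similarity) and three bipartite association layers
#' linking them. For bipartite layers the `u` column holds the first-named
#' entity type (`mirna_target`: u = miRNA, v = protein; `mirna_disease`:
#' u = miRNA, v = disease; `protein_disease`: u = protein, v = disease).
#'
#' @format A character vector of the six layer names.
#' @export
EDGE_LAYERS <- c(
  "coexpr", "ppi", "disease_sim",
  "mirna_target", "mirna_disease", "protein_disease"
)

# endpoint types implied by each layer (u-type, v-type)
layer_endpoint_types <- function(layer) {
  switch(layer,
    coexpr          = c("miRNA", "miRNA"),
    ppi             = c("protein", "protein"),
    disease_sim     = c("disease", "disease"),
    mirna_target    = c("miRNA", "protein"),
    mirna_disease   = c("miRNA", "disease"),
    protein_disease = c("protein", "disease"),
    stop("unknown edge layer: ", layer, call. = FALSE)
  )
}

validate_edge_table <- function(edges) {
  stopifnot(is.data.frame(edges))
  needed <- c("u", "v", "weight", "layer")
  missing <- setdiff(needed, names(edges))
  if (length(missing) > 0) {
    stop("edge table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    stop("edge weights must be finite and strictly positive", call. = FALSE)
  }
  if (any(edges$u == edges$v)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  bad <- setdiff(unique(edges$layer), EDGE_LAYERS)
  if (length(bad) > 0) {
    stop("unknown edge layer(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(edges)
}

#' Average precursor expression profiles into mature miRNA profiles
#'
#' Two or more homologous precursor miRNAs can produce the same mature
#' miRNA; their expression profiles are combined by the arithmetic mean so
#' that each mature miRNA carries a single profile. Precursors without an
#' entry in `homolog_map` are dropped.
#'
#' @param expr Data frame: first column is the precursor id, remaining
#'   columns are numeric expression values per condition.
#' @param homolog_map Data frame with columns `precursor` and `mature`.
#' @return A tibble with one row per mature miRNA and the same condition
#'   columns as `expr`.
#' @export
average_homolog_profiles <- function(expr, homolog_map) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 3)
  stopifnot(all(c("precursor", "mature") %in% names(homolog_map)))
  id_col <- names(expr)[1]
  absent <- setdiff(homolog_map$precursor, expr[[id_col]])
  if (length(absent) > 0) {
    stop("homolog map references precursor(s) absent from the expression ",
         "matrix: ", paste(head(absent, 5), collapse = ", "), call. = FALSE)
  }
  expr |>
    dplyr::rename(precursor = 1) |>
    dplyr::inner_join(
      dplyr::distinct(tibble::as_tibble(homolog_map), .data$precursor, .data$mature),
      by = "precursor"
    ) |>
    dplyr::select(-"precursor") |>
    dplyr::summarise(
      dplyr::across(dplyr::where(is.numeric), mean),
      .by = "mature"
    ) |>
    dplyr::rename(mirna = "mature") |>
    dplyr::arrange(.data$mirna)
}

#' Co-expression edges from an expression matrix
#'
#' Computes the Pearson correlation coefficient (PCC) between the expression
#' profiles of every pair of miRNAs and keeps the strictly positive
#' correlations as edge weights; pairs with PCC <= 0 produce no edge
#' (negative correlations are screened out). Rows with zero variance have
#' an undefined PCC: their pairs are skipped with a warning.
#'
#' @param expr Data frame: first column is the miRNA id, remaining columns
#'   are numeric expression values (at least two conditions).
#' @return A tibble of edges (`u`, `v`, `weight`, `layer = "coexpr"`), with
#'   `u < v` lexicographically.
#' @export
coexpression_edges <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 3)
  ids <- as.character(expr[[1]])
  if (anyDuplicated(ids)) stop("duplicate miRNA ids in expression matrix", call. = FALSE)
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  sds <- apply(m, 1, stats::sd)
  flat <- ids[sds == 0 | is.na(sds)]
  if (length(flat) > 0) {
    warning("zero-variance expression profile(s), pairs skipped: ",
            paste(head(flat, 5), collapse = ", "), call. = FALSE)
    m <- m[!(ids %in% flat), , drop = FALSE]
    ids <- rownames(m)
  }
  if (nrow(m) < 2) {
    return(tibble::tibble(u = character(), v = character(),
                          weight = double(), layer = character()))
  }
  pcc <- stats::cor(t(m))
  keep <- which(upper.tri(pcc) & pcc > 0, arr.ind = TRUE)
  tibble::tibble(
    u = pmin(ids[keep[, 1]], ids[keep[, 2]]),
    v = pmax(ids[keep[, 1]], ids[keep[, 2]]),
    weight = pcc[keep],
    layer = "coexpr"
  ) |>
    dplyr::arrange(.data$u, .data$v)
}

#' Read a weighted edge list from a TSV file
#'
#' Expects tab-separated columns `u`, `v` and (optionally) `weight`; the
#' weight column may be absent for pure association lists, in which case
#' every edge gets weight 1. Duplicate pairs are collapsed to the maximum
#' weight; edges with non-positive transformed weight are dropped (a zero
#' score means no interaction, i.e. no edge).
#'
#' @param path TSV file. A header row is detected and skipped if the third
#'   column is non-numeric.
#' @param layer One of [EDGE_LAYERS].
#' @param weight_transform `"identity"` (similarities already in (0,1]),
#'   `"divide_by_1000"` (STRING-style 0-999 confidence scores), or `"unit"`
#'   (force all weights to 1, for association layers).
#' @return A tibble of edges (`u`, `v`, `weight`, `layer`).
#' @export
read_edge_list <- function(path, layer,
                           weight_transform = c("identity", "divide_by_1000", "unit")) {
  weight_transform <- match.arg(weight_transform)
  layer <- match.arg(layer, EDGE_LAYERS)
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(u = character(), v = character(),
                          weight = double(), layer = character()))
  }
  if (ncol(raw) < 2) stop("edge list must have at least two columns: ", path, call. = FALSE)
  # drop a header row if present
  if (ncol(raw) >= 3 && is.na(suppressWarnings(as.numeric(raw[[3]][1]))) &&
      nrow(raw) > 1) {
    raw <- raw[-1, , drop = FALSE]
  }
  w <- if (ncol(raw) >= 3) suppressWarnings(as.numeric(raw[[3]])) else rep(1, nrow(raw))
  bad <- which(is.na(w) | is.na(raw[[1]]) | is.na(raw[[2]]) | raw[[1]] == "" | raw[[2]] == "")
  if (length(bad) > 0) {
    stop("malformed edge list row(s) in ", path, " at line(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  w <- switch(weight_transform,
    identity = w,
    divide_by_1000 = w / 1000,
    unit = rep(1, length(w))
  )
  edges <- tibble::tibble(u = raw[[1]], v = raw[[2]], weight = w, layer = layer)
  edges <- edges[edges$u != edges$v, , drop = FALSE]
  if (any(edges$weight < 0)) {
    warning("dropping ", sum(edges$weight < 0), " edge(s) with negative weight",
            call. = FALSE)
  }
  edges <- edges[edges$weight > 0, , drop = FALSE]
  collapse_duplicate_edges(edges, layer)
}

# collapse duplicate pairs (in either orientation) to the maximum weight,
# keeping the first-seen orientation so bipartite column conventions survive
collapse_duplicate_edges <- function(edges, layer) {
  types <- layer_endpoint_types(layer)
  if (types[1] == types[2]) {
    edges <- dplyr::mutate(edges,
      u0 = pmin(.data$u, .data$v), v0 = pmax(.data$u, .data$v),
      u = .data$u0, v = .data$v0
    ) |> dplyr::select(-"u0", -"v0")
  }
  edges |>
    dplyr::summarise(weight = max(.data$weight), .by = c("u", "v", "layer")) |>
    dplyr::select("u", "v", "weight", "layer") |>
    dplyr::arrange(.data$u, .data$v)
}

#' Assemble the global heterogeneous network
#'
#' Takes the per-layer edge tables and merges them into one weighted,
#' undirected, typed graph. Vertex types (miRNA / protein / disease) are
#' inferred from the layers each id appears in; an id implying two different
#' types is a hard error naming the id. Edges are stored once in canonical
#' form (lexicographic endpoint ordering within the unipartite layers; the
#' u-column type convention in bipartite layers); duplicates within a layer
#' collapse to the maximum weight. Connected-component sizes are reported via `message()`.
#'
#' @param layers A list of edge tibbles (as produced by
#'   [coexpression_edges()], [read_edge_list()], ...), or a single stacked
#'   edge tibble.
#' @param vertex_types Optional data frame (`id`, `type`) asserting types for
#'   ids, checked against the inferred types.
#' @param quiet Suppress the component-size message.
#' @return A `het_network` object: a list with a `vertices` tibble
#'   (`id`, `type`) and an `edges` tibble (`u`, `v`, `weight`, `layer`).
#' @export
build_global_network <- function(layers, vertex_types = NULL, quiet = FALSE) {
  if (is.data.frame(layers)) layers <- list(layers)
  if (length(layers) == 0) stop("no layers", call. = FALSE)
  layers <- layers[vapply(layers, nrow, 1L) > 0]
  if (length(layers) == 0) stop("no layers with edges", call. = FALSE)
  for (l in layers) validate_edge_table(l)
  all_edges <- dplyr::bind_rows(layers)

  # infer vertex types from layer membership
  utypes <- t(vapply(all_edges$layer, layer_endpoint_types, character(2)))
  typed <- tibble::tibble(
    id = c(all_edges$u, all_edges$v),
    type = unname(c(utypes[, 1], utypes[, 2]))
  )
  if (!is.null(vertex_types)) {
    stopifnot(all(c("id", "type") %in% names(vertex_types)))
    typed <- dplyr::bind_rows(typed, vertex_types[, c("id", "type")])
  }
  typed <- dplyr::distinct(typed)
  conflict <- typed$id[duplicated(typed$id)]
  if (length(conflict) > 0) {
    stop("vertex id(s) with conflicting types: ",
         paste(unique(head(conflict, 5)), collapse = ", "), call. = FALSE)
  }

  # canonical storage: lexicographic u < v within unipartite layers; in
  # bipartite layers the type convention (u = first-named type) is already
  # the canonical orientation and must be preserved
  edges <- split(all_edges, all_edges$layer) |>
    lapply(function(e) collapse_duplicate_edges(e, e$layer[1])) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$layer, .data$u, .data$v)

  net <- structure(
    list(
      vertices = dplyr::arrange(typed, .data$id),
      edges = edges
    ),
    class = "het_network"
  )
  if (!quiet) {
    g <- igraph::graph_from_data_frame(edges[, c("u", "v")], directed = FALSE,
                                       vertices = net$vertices$id)
    comp <- igraph::components(g)
    message("global network: ", nrow(net$vertices), " vertices, ",
            nrow(edges), " edges, ", comp$no, " component(s) of size(s) ",
            paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))
  }
  net
}

#' @export
print.het_network <- function(x, ...) {
  cat("<het_network> ", nrow(x$vertices), " vertices, ",
      nrow(x$edges), " edges\n", sep = "")
  print(dplyr::count(x$vertices, .data$type))
  print(dplyr::count(x$edges, .data$layer, wt = NULL))
  invisible(x)
}

#' Write / read a heterogeneous network as a TSV edge list
#'
#' The merged network round-trips through a four-column TSV
#' (`u`, `v`, `weight`, `layer`); vertex types are re-inferred on read.
#'
#' @param net A `het_network`.
#' @param path Output TSV path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "het_network"))
  readr::write_tsv(net$edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  edges <- readr::read_tsv(
    path,
    col_types = readr::cols(u = "c", v = "c", weight = "d", layer = "c"),
    progress = FALSE
  )
  build_global_network(split(edges, edges$layer), quiet = TRUE)
}
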