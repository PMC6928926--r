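OBO_NAMESPACES <- c(
  biological_process = "BP",
  molecular_function = "MF",
  cellular_component = "CC"
)

#' Construct a GO-style rooted DAG
#'
#' A `go_dag` holds the is_a/part_of parent structure of an ontology:
#' a named list of parent vectors, a namespace label per term (BP/MF/CC),
#' and one root per namespace. The constructor verifies acyclicity (a cycle
#' is a hard error listing its members) and that parents stay within the
#' term's namespace.
#'
#' @param parents Named list: term id -> character vector of parent term ids
#'   (empty for roots). Every referenced parent must itself be a name.
#' @param namespace Named character vector term id -> "BP"/"MF"/"CC", or a
#'   single value recycled to all terms.
#' @return A `go_dag` object.
#' @export
go_dag <- function(parents, namespace = "BP") {
  terms <- names(parents)
  if (is.null(terms) || anyDuplicated(terms)) {
    stop("`parents` must be a uniquely named list", call. = FALSE)
  }
  parents <- lapply(parents, as.character)
  unknown <- setdiff(unlist(parents), terms)
  if (length(unknown) > 0) {
    stop("parent term(s) not defined in the DAG: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (length(namespace) == 1) namespace <- setNames(rep(namespace, length(terms)), terms)
  namespace <- namespace[terms]
  if (anyNA(namespace) || !all(namespace %in% c("BP", "MF", "CC"))) {
    stop("every term needs a namespace in {BP, MF, CC}", call. = FALSE)
  }
  for (t in terms) {
    bad <- parents[[t]][namespace[parents[[t]]] != namespace[[t]]]
    if (length(bad) > 0) {
      stop("term ", t, " has parent(s) in a different namespace: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  children <- lapply(setNames(terms, terms), function(t) character(0))
  for (t in terms) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }

  order <- reverse_topo_order(parents, terms)  # errors on a cycle

  rootless <- terms[vapply(parents, length, 1L) == 0]
  roots <- character(0)
  for (ns in unique(namespace)) {
    r <- rootless[namespace[rootless] == ns]
    if (length(r) != 1) {
      stop("namespace ", ns, " must have exactly one root, found: ",
           paste(r, collapse = ", "), call. = FALSE)
    }
    roots[ns] <- r
  }

  structure(
    list(terms = terms, parents = parents, children = children,
         namespace = namespace, roots = roots, order = order,
         alt = character(0)),
    class = "go_dag"
  )
}

# children-before-parents (reverse-topological) order; deterministic
# (lexicographic tie-break); errors listing cycle members if not a DAG
reverse_topo_order <- function(parents, terms) {
  n_children <- setNames(integer(length(terms)), terms)
  for (t in terms) {
    for (p in parents[[t]]) n_children[p] <- n_children[p] + 1L
  }
  out <- character(0)
  ready <- sort(names(n_children)[n_children == 0L])
  remaining <- n_children
  while (length(ready) > 0) {
    t <- ready[1]
    ready <- ready[-1]
    out <- c(out, t)
    ps <- parents[[t]]
    for (p in ps) {
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) ready <- sort(c(ready, p))
    }
  }
  if (length(out) < length(terms)) {
    stop("ontology contains a cycle involving: ",
         paste(setdiff(terms, out), collapse = ", "), call. = FALSE)
  }
  out
}

#' @export
print.go_dag <- function(x, ...) {
  cat("<go_dag> ", length(x$terms), " terms; roots: ",
      paste(names(x$roots), x$roots, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas keeping `is_a` and (optionally) `part_of`
#' relationships as parent edges. Obsolete terms are dropped; `alt_id`s are
#' recorded so lookups by an alternative id resolve to the primary term.
#'
#' @param path Path to an OBO file.
#' @param use_part_of Treat `relationship: part_of` like `is_a` (default).
#' @return A [go_dag()].
#' @export
read_obo <- function(path, use_part_of = TRUE) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) stop("no [Term] stanzas in ", path, call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  stanza_field <- function(block, key) {
    hits <- block[startsWith(block, paste0(key, ": "))]
    sub("\\s*!.*$", "", substring(hits, nchar(key) + 3L))
  }
  terms <- list()
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[!grepl("^\\[", block)]
    id <- stanza_field(block, "id")[1]
    if (is.na(id)) next
    rel <- stanza_field(block, "relationship")
    part_of <- sub("^part_of\\s+", "", rel[startsWith(rel, "part_of ")])
    terms[[id]] <- list(
      id = trimws(id),
      namespace = trimws(stanza_field(block, "namespace")[1]),
      is_a = trimws(stanza_field(block, "is_a")),
      part_of = trimws(part_of),
      alt_id = trimws(stanza_field(block, "alt_id")),
      obsolete = any(stanza_field(block, "is_obsolete") == "true")
    )
  }
  obsolete <- names(terms)[vapply(terms, function(t) t$obsolete, TRUE)]
  terms <- terms[setdiff(names(terms), obsolete)]
  if (length(terms) == 0) stop("no non-obsolete terms in ", path, call. = FALSE)

  ns <- vapply(terms, function(t) t$namespace, character(1))
  ns <- ifelse(ns %in% names(OBO_NAMESPACES), OBO_NAMESPACES[ns], ns)
  ns[is.na(ns)] <- "BP"
  parents <- lapply(terms, function(t) {
    p <- c(t$is_a, if (use_part_of) t$part_of)
    setdiff(p, obsolete)
  })
  ns_by_term <- setNames(ns, names(terms))
  # drop the rare cross-namespace parent links (part_of can cross in real GO)
  for (t in names(parents)) {
    keep <- ns_by_term[parents[[t]]] == ns_by_term[[t]]
    keep[is.na(keep)] <- FALSE
    if (!all(keep)) {
      warning("dropping cross-namespace/unknown parent(s) of ", t, call. = FALSE)
      parents[[t]] <- parents[[t]][keep]
    }
  }
  dag <- go_dag(parents, ns_by_term)
  alts <- unlist(unname(lapply(terms, function(t) {
    setNames(rep(t$id, length(t$alt_id)), t$alt_id)
  })))
  dag$alt <- if (is.null(alts)) character(0) else alts
  dag
}

#' Write a `go_dag` as an OBO 1.2 file
#'
#' @param dag A [go_dag()].
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  long_ns <- setNames(names(OBO_NAMESPACES), OBO_NAMESPACES)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in sort(dag$terms)) {
    ps <- sort(dag$parents[[t]])
    writeLines(c(
      "[Term]",
      paste0("id: ", t),
      paste0("name: ", t),
      paste0("namespace: ", long_ns[[dag$namespace[[t]]]]),
      if (length(ps) > 0) paste0("is_a: ", ps),
      ""
    ), con)
  }
  invisible(path)
}

#' Resolve term ids against a DAG (mapping alt_ids to primary ids)
#'
#' @param dag A [go_dag()].
#' @param terms Character vector of term ids.
#' @return Character vector of primary ids (`NA` where unknown).
#' @export
resolve_terms <- function(dag, terms) {
  out <- as.character(terms)
  is_alt <- out %in% names(dag$alt)
  out[is_alt] <- dag$alt[out[is_alt]]
  out[!(out %in% dag$terms)] <- NA_character_
  out
}

#' All ancestors of every term
#'
#' @param dag A [go_dag()].
#' @return Named list term -> character vector of ancestors (self excluded).
#' @export
term_ancestors <- function(dag) {
  anc <- list()
  # parents-before-children scan: reverse of the children-first order
  for (t in rev(dag$order)) {
    ps <- dag$parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc[dag$terms]
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Annotation to a term implies annotation to all of its ancestors: each
#' entity's term set is closed under the ancestor relation. The operation is
#' idempotent and monotone.
#'
#' @param dag A [go_dag()].
#' @param annots Data frame with columns `entity` and `term`.
#' @return A tibble (`entity`, `term`), distinct rows, with attribute
#'   `propagated = TRUE`.
#' @export
propagate_annotations <- function(dag, annots) {
  stopifnot(all(c("entity", "term") %in% names(annots)))
  annots <- tibble::as_tibble(annots)[, c("entity", "term")]
  resolved <- resolve_terms(dag, annots$term)
  if (anyNA(resolved)) {
    i <- which(is.na(resolved))[1]
    stop("entity ", annots$entity[i], " is annotated with unknown term ",
         annots$term[i], call. = FALSE)
  }
  annots$term <- resolved
  if (nrow(annots) == 0) {
    out <- dplyr::distinct(annots)
  } else {
    anc <- term_ancestors(dag)
    extra <- tidyr::unnest(
      dplyr::mutate(annots, anc = unname(anc[.data$term])),
      "anc"
    ) |>
      dplyr::transmute(entity = .data$entity, term = .data$anc)
    out <- dplyr::distinct(dplyr::bind_rows(annots, extra)) |>
      dplyr::arrange(.data$entity, .data$term)
  }
  attr(out, "propagated") <- TRUE
  out
}

is_propagated <- function(annots) isTRUE(attr(annots, "propagated"))

#' Select the trainable term set
#'
#' Keeps terms of the requested namespace annotated (after propagation) to at
#' least `min_count` entities, excluding the namespace root, ordered
#' children-before-parents (reverse-topologically). This count threshold is
#' the standard construction for hierarchy-aware function prediction.
#'
#' @param dag A [go_dag()].
#' @param annots Propagated annotations (see [propagate_annotations()]).
#' @param min_count Minimum number of annotated entities per term (>= 1).
#' @param namespace Optional filter: "BP", "MF" or "CC".
#' @return Character vector of term ids in reverse-topological order.
#' @export
select_terms <- function(dag, annots, min_count = 5, namespace = NULL) {
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  if (!is_propagated(annots)) {
    stop("annotations must be propagated first (see propagate_annotations)",
         call. = FALSE)
  }
  counts <- dplyr::count(dplyr::distinct(annots), .data$term)
  keep <- counts$term[counts$n >= min_count]
  keep <- setdiff(keep, dag$roots)
  if (!is.null(namespace)) keep <- keep[dag$namespace[keep] == namespace]
  dag$order[dag$order %in% keep]
}

#' Build a binary label matrix from propagated annotations
#'
#' @param annots Propagated annotations.
#' @param terms Term ids defining the columns (use [select_terms()] so the
#'   order is reverse-topological).
#' @return Binary matrix, entities x terms; entities with none of the
#'   selected terms keep an all-zero row.
#' @export
build_label_matrix <- function(annots, terms) {
  if (!is_propagated(annots)) {
    stop("annotations must be propagated first", call. = FALSE)
  }
  entities <- sort(unique(annots$entity))
  m <- matrix(0, nrow = length(entities), ncol = length(terms),
              dimnames = list(entities, terms))
  hit <- annots[annots$term %in% terms, ]
  if (nrow(hit) > 0) m[cbind(hit$entity, hit$term)] <- 1
  m
}

#' Read an annotation table
#'
#' Tab-separated `entity<TAB>term[<TAB>evidence]`, no header. When the
#' evidence column is present, IEA (inferred from electronic annotation)
#' rows are dropped unless `keep_iea = TRUE`.
#'
#' @param path TSV path.
#' @param keep_iea Keep IEA-evidence rows.
#' @return Tibble (`entity`, `term`), unpropagated.
#' @export
read_annotations <- function(path, keep_iea = FALSE) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) stop("annotation table needs >= 2 columns: ", path, call. = FALSE)
  out <- tibble::tibble(entity = raw[[1]], term = raw[[2]])
  if (ncol(raw) >= 3 && !keep_iea) out <- out[raw[[3]] != "IEA", ]
  attr(out, "propagated") <- FALSE
  dplyr::distinct(out)
}

#' @rdname read_annotations
#' @param annots Annotation tibble to write.
#' @export
write_annotations <- function(annots, path) {
  readr::write_tsv(annots[, c("entity", "term")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
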