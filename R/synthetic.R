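#' Synthetic benchmark settings
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' functional modules planted jointly in (a) miRNA expression profiles
#' (module archetype + Gaussian noise, so co-expression PCC recovers the
#' modules), (b) planted-partition PPI and disease-similarity graphs
#' (within-module edge probability `p_in`, across `p_out`), (c) bipartite
#' association layers preferentially linking same-module entities, and
#' (d) annotations that give each entity its module's characteristic GO
#' terms with probability `annotation_signal` plus uniform noise terms.
#'
#' @param n_mirna,n_protein,n_disease Entity counts.
#' @param n_modules Number of planted functional modules.
#' @param p_in,p_out Within/across-module edge probabilities (`p_in > p_out`)
#'   for the PPI and disease-similarity layers.
#' @param assoc_in,assoc_out Same/cross-module probabilities for the three
#'   bipartite association layers.
#' @param mirna_target_in,mirna_disease_in,protein_disease_in Optional
#'   per-layer overrides of `assoc_in`, so an individual association layer
#'   can be made sparser or denser than the others (e.g. to build a fixture
#'   in which the disease layers carry signal the other layers do not).
#' @param n_conditions Expression conditions.
#' @param expression_noise SD of per-miRNA Gaussian noise around the module
#'   archetype profile (archetypes have SD 1).
#' @param two_precursor_fraction Fraction of miRNAs given two homologous
#'   precursors in the expression file.
#' @param n_terms Ontology size (one BP-like namespace, rooted).
#' @param terms_per_module Characteristic (leaf) terms per module.
#' @param annotation_signal Probability that each characteristic term of the
#'   entity's module annotates the entity.
#' @param noise_term_rate Probability that any other non-root term annotates
#'   the entity.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_mirna = 120, n_protein = 120, n_disease = 60,
                         n_modules = 4, p_in = 0.30, p_out = 0.02,
                         assoc_in = 0.15, assoc_out = 0.01,
                         mirna_target_in = assoc_in,
                         mirna_disease_in = assoc_in,
                         protein_disease_in = assoc_in,
                         n_conditions = 20, expression_noise = 1.0,
                         two_precursor_fraction = 0.2,
                         n_terms = 60, terms_per_module = 4,
                         annotation_signal = 0.9, noise_term_rate = 0.02,
                         seed = 1L) {
  stopifnot(n_mirna >= 1, n_protein >= 1, n_disease >= 1, n_modules >= 1,
            p_in > p_out, p_in <= 1, p_out >= 0,
            assoc_in > assoc_out, assoc_out >= 0,
            mirna_target_in >= 0, mirna_target_in <= 1,
            mirna_disease_in >= 0, mirna_disease_in <= 1,
            protein_disease_in >= 0, protein_disease_in <= 1,
            n_conditions >= 2, expression_noise >= 0,
            two_precursor_fraction >= 0, two_precursor_fraction <= 1,
            n_terms >= 3, terms_per_module >= 1,
            annotation_signal > 0, annotation_signal <= 1, noise_term_rate >= 0)
  if (n_modules > min(n_mirna, n_protein, n_disease)) {
    stop("n_modules exceeds the smallest entity count", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

pad_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

# random rooted single-namespace DAG: term i >= 2 picks 1-2 parents among
# earlier terms, so T001 is the root and the id order is topological
random_go_dag <- function(n_terms) {
  ids <- pad_ids("T", n_terms)
  parents <- setNames(vector("list", n_terms), ids)
  parents[[1]] <- character(0)
  for (i in 2:n_terms) {
    k <- if (i > 2 && runif(1) < 0.3) 2L else 1L
    parents[[i]] <- sample(ids[seq_len(i - 1)], min(k, i - 1))
  }
  go_dag(parents, "BP")
}

# edges of a planted-partition graph over `ids` with module labels `mod`;
# present edges get weights ~ Uniform(0.5, 1)
planted_partition_edges <- function(ids, mod, p_in, p_out, layer) {
  n <- length(ids)
  if (n < 2) {
    return(tibble::tibble(u = character(), v = character(),
                          weight = double(), layer = character()))
  }
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(mod[pair[, 1]] == mod[pair[, 2]], p_in, p_out)
  hit <- runif(nrow(pair)) < p
  tibble::tibble(
    u = pmin(ids[pair[hit, 1]], ids[pair[hit, 2]]),
    v = pmax(ids[pair[hit, 1]], ids[pair[hit, 2]]),
    weight = round(runif(sum(hit), 0.5, 1), 4),
    layer = layer
  ) |> dplyr::arrange(.data$u, .data$v)
}

# unit-weight bipartite association edges, preferential within modules
bipartite_edges <- function(ids_u, mod_u, ids_v, mod_v, assoc_in, assoc_out, layer) {
  grid <- expand.grid(i = seq_along(ids_u), j = seq_along(ids_v))
  p <- ifelse(mod_u[grid$i] == mod_v[grid$j], assoc_in, assoc_out)
  hit <- runif(nrow(grid)) < p
  tibble::tibble(
    u = ids_u[grid$i[hit]], v = ids_v[grid$j[hit]],
    weight = 1, layer = layer
  ) |> dplyr::arrange(.data$u, .data$v)
}

#' Generate the synthetic benchmark
#'
#' Writes every input the pipeline consumes to `out_dir`: a precursor-level
#' expression matrix plus homolog map, PPI and disease-similarity edge
#' lists, the three bipartite association lists, an OBO ontology, an
#' unpropagated annotation table covering proteins and miRNAs, and a
#' `truth.json` manifest with the planted module assignments. Byte-identical
#' across runs with the same config.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return (Invisibly) a `synth_truth` list: module assignment per entity,
#'   characteristic terms per module, the DAG, the file manifest and the
#'   config.
#' @export
generate_benchmark <- function(config = synth_config(), out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  mirnas <- pad_ids("mir", config$n_mirna)
  proteins <- pad_ids("prot", config$n_protein)
  diseases <- pad_ids("dis", config$n_disease)
  assign_modules <- function(ids) {
    setNames(sample(rep_len(seq_len(config$n_modules), length(ids))), ids)
  }
  mod_mirna <- assign_modules(mirnas)
  mod_protein <- assign_modules(proteins)
  mod_disease <- assign_modules(diseases)

  # --- expression: archetype per module + noise, at precursor level -------
  archetypes <- matrix(rnorm(config$n_modules * config$n_conditions),
                       config$n_modules, config$n_conditions)
  mature_expr <- archetypes[mod_mirna, , drop = FALSE] +
    matrix(rnorm(config$n_mirna * config$n_conditions, sd = config$expression_noise),
           config$n_mirna)
  rownames(mature_expr) <- mirnas
  two_pre <- runif(config$n_mirna) < config$two_precursor_fraction
  homolog_map <- tibble::tibble(
    precursor = c(paste0("pre-", mirnas, "-1"),
                  paste0("pre-", mirnas[two_pre], "-2")),
    mature = c(mirnas, mirnas[two_pre])
  ) |> dplyr::arrange(.data$precursor)
  pre_expr <- mature_expr[homolog_map$mature, , drop = FALSE] +
    matrix(rnorm(nrow(homolog_map) * config$n_conditions, sd = 0.1),
           nrow(homolog_map))
  expr_tbl <- as.data.frame(round(pre_expr, 6)) |>
    setNames(paste0("cond", seq_len(config$n_conditions))) |>
    tibble::as_tibble()
  expr_tbl <- dplyr::bind_cols(tibble::tibble(precursor = homolog_map$precursor),
                               expr_tbl)

  # --- entity and association layers --------------------------------------
  ppi <- planted_partition_edges(proteins, mod_protein,
                                 config$p_in, config$p_out, "ppi")
  dis_sim <- planted_partition_edges(diseases, mod_disease,
                                     config$p_in, config$p_out, "disease_sim")
  mt <- bipartite_edges(mirnas, mod_mirna, proteins, mod_protein,
                        config$mirna_target_in, config$assoc_out, "mirna_target")
  md <- bipartite_edges(mirnas, mod_mirna, diseases, mod_disease,
                        config$mirna_disease_in, config$assoc_out, "mirna_disease")
  pd <- bipartite_edges(proteins, mod_protein, diseases, mod_disease,
                        config$protein_disease_in, config$assoc_out, "protein_disease")

  # --- ontology and annotations -------------------------------------------
  dag <- random_go_dag(config$n_terms)
  leaves <- dag$terms[lengths(dag$children) == 0]
  needed <- config$n_modules * config$terms_per_module
  if (length(leaves) < needed) {
    stop("DAG has only ", length(leaves), " leaves; need ", needed,
         " characteristic terms — increase n_terms", call. = FALSE)
  }
  char_terms <- split(sample(leaves, needed),
                      rep(seq_len(config$n_modules), each = config$terms_per_module))
  other_terms <- setdiff(dag$terms, unname(dag$roots))

  annotate <- function(ids, mod) {
    purrr::map_dfr(ids, function(id) {
      own <- char_terms[[mod[[id]]]]
      hits <- own[runif(length(own)) < config$annotation_signal]
      noise <- setdiff(other_terms, own)
      hits <- c(hits, noise[runif(length(noise)) < config$noise_term_rate])
      if (length(hits) == 0) return(NULL)
      tibble::tibble(entity = id, term = sort(unique(hits)))
    })
  }
  annots <- dplyr::bind_rows(annotate(proteins, mod_protein),
                             annotate(mirnas, mod_mirna))
  attr(annots, "propagated") <- FALSE

  # --- write everything ----------------------------------------------------
  files <- list(
    expression = "expression.tsv", homolog_map = "homolog_map.tsv",
    ppi = "ppi.tsv", disease_sim = "disease_sim.tsv",
    mirna_target = "mirna_target.tsv", mirna_disease = "mirna_disease.tsv",
    protein_disease = "protein_disease.tsv",
    ontology = "ontology.obo", annotations = "annotations.tsv",
    truth = "truth.json"
  )
  fp <- function(nm) file.path(out_dir, files[[nm]])
  readr::write_tsv(expr_tbl, fp("expression"), progress = FALSE)
  readr::write_tsv(homolog_map, fp("homolog_map"), col_names = FALSE, progress = FALSE)
  for (nm in c("ppi", "disease_sim", "mirna_target", "mirna_disease", "protein_disease")) {
    e <- switch(nm, ppi = ppi, disease_sim = dis_sim, mirna_target = mt,
                mirna_disease = md, protein_disease = pd)
    readr::write_tsv(e[, c("u", "v", "weight")], fp(nm), col_names = FALSE,
                     progress = FALSE)
  }
  write_obo(dag, fp("ontology"))
  write_annotations(annots, fp("annotations"))

  truth <- structure(
    list(
      modules = list(mirna = mod_mirna, protein = mod_protein,
                     disease = mod_disease),
      module_terms = char_terms,
      dag = dag,
      annotations = annots,
      files = lapply(files, function(f) file.path(out_dir, f)),
      config = config
    ),
    class = "synth_truth"
  )
  manifest <- list(
    config = unclass(config),
    modules = lapply(truth$modules, as.list),
    module_terms = char_terms,
    files = files,
    counts = list(
      ppi_edges = nrow(ppi), disease_sim_edges = nrow(dis_sim),
      mirna_target_edges = nrow(mt), mirna_disease_edges = nrow(md),
      protein_disease_edges = nrow(pd), annotations = nrow(annots)
    )
  )
  jsonlite::write_json(manifest, fp("truth"), auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(truth)
}

#' Permute annotation sets across entities (null control)
#'
#' Randomly reassigns each entity's whole term set to another entity, so
#' the multiset of term sets (and hence every term's frequency) is exactly
#' conserved while any entity-to-term signal is destroyed.
#'
#' @param annots Annotation tibble (`entity`, `term`).
#' @param seed Integer seed.
#' @return Annotation tibble of the same shape, same `propagated` flag.
#' @export
permute_labels <- function(annots, seed = 1L) {
  sets <- split(annots$term, annots$entity)
  entities <- names(sets)
  set.seed(seed)
  perm <- sample.int(length(entities))
  out <- purrr::map2_dfr(entities, sets[perm], function(e, ts) {
    tibble::tibble(entity = e, term = ts)
  }) |> dplyr::arrange(.data$entity, .data$term)
  attr(out, "propagated") <- attr(annots, "propagated")
  out
}
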