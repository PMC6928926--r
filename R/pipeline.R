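#' Assemble a pipeline configuration
#'
#' One object drives the whole run: where the inputs live (or a
#' [synth_config()] to generate them), the embedding and classifier
#' settings, the evaluated namespace, and the ablation switch. A single
#' global seed fans out deterministically to the per-stage seeds.
#'
#' @param inputs Named list of file paths (`expression`, `homolog_map`,
#'   `ppi`, `disease_sim`, `mirna_target`, `mirna_disease`,
#'   `protein_disease`, `ontology`, `annotations`), or `NULL` when `synth`
#'   is given.
#' @param synth Optional [synth_config()]; when present the benchmark is
#'   generated into the run directory and its files become the inputs.
#' @param line A [line_config()] (its seed is overridden by `seed`).
#' @param model An [hmc_config()] (its seed is overridden by `seed`).
#' @param eval An [eval_config()].
#' @param namespace Evaluated GO namespace.
#' @param min_count Minimum annotated-entity count for trainable terms.
#' @param ablate_disease Drop the disease similarity, miRNA-disease and
#'   protein-disease layers before embedding.
#' @param permute_training_labels Permute the training annotation sets
#'   across training entities (null control).
#' @param ppi_transform,similarity_transform Weight transforms for the PPI
#'   and disease-similarity edge lists (see [read_edge_list()]).
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = NULL, synth = NULL,
                            line = line_config(), model = hmc_config(),
                            eval = eval_config(), namespace = "BP",
                            min_count = 5, ablate_disease = FALSE,
                            permute_training_labels = FALSE,
                            ppi_transform = "identity",
                            similarity_transform = "identity",
                            seed = 1L) {
  if (is.null(inputs) && is.null(synth)) {
    stop("either `inputs` paths or a `synth` config is required", call. = FALSE)
  }
  structure(
    list(inputs = inputs, synth = synth, line = line, model = model,
         eval = eval, namespace = namespace, min_count = min_count,
         ablate_disease = isTRUE(ablate_disease),
         permute_training_labels = isTRUE(permute_training_labels),
         ppi_transform = ppi_transform,
         similarity_transform = similarity_transform,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# deterministic per-stage seeds derived from the one global seed
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 0L, embed = 10007L, train = 20011L, permute = 30013L)
  as.integer((as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max)
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> build-net -> embed -> train -> predict ->
#' evaluate, logging per-stage timings and counts, and writes every artifact
#' into `out_dir`: the merged network (`network.tsv`), the embedding
#' (`embedding.txt`), the fitted model (`model.rds`), miRNA predictions
#' (`predictions.tsv`), the threshold sweep (`evaluation.tsv`) and a
#' `summary.json` with Fmax, the argmax threshold, averaged precision and
#' recall, coverage and N, plus the exact configuration used
#' (`config.json`). Training entities are the annotated proteins; the model
#' is then transferred to the miRNAs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a `pipeline_run` list: `summary`, `eval`, `model`,
#'   `prediction`, `network`, `embedding`, `dag`, `truth` (when simulated).
#' @export
run_pipeline <- function(config, out_dir = tempfile("hetgo_run_"), quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  say <- function(...) if (!quiet) message(...)
  clock <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }

  # -- stage: simulate ------------------------------------------------------
  truth <- NULL
  inputs <- config$inputs
  if (!is.null(config$synth)) {
    synth <- config$synth
    synth$seed <- stage_seed(config$seed, "simulate")
    truth <- generate_benchmark(synth, file.path(out_dir, "data"))
    inputs <- truth$files
    say("simulated benchmark in ", file.path(out_dir, "data"))
  }
  clock("simulate")

  # -- stage: build-net -----------------------------------------------------
  expr <- readr::read_tsv(inputs$expression, col_types = readr::cols(),
                          progress = FALSE)
  homolog_map <- readr::read_tsv(inputs$homolog_map, col_names = c("precursor", "mature"),
                                 col_types = "cc", progress = FALSE)
  mature <- average_homolog_profiles(expr, homolog_map)
  layers <- list(
    coexpr = coexpression_edges(mature),
    ppi = read_edge_list(inputs$ppi, "ppi", config$ppi_transform),
    mirna_target = read_edge_list(inputs$mirna_target, "mirna_target", "unit")
  )
  if (!config$ablate_disease) {
    layers$disease_sim <- read_edge_list(inputs$disease_sim, "disease_sim",
                                         config$similarity_transform)
    layers$mirna_disease <- read_edge_list(inputs$mirna_disease, "mirna_disease", "unit")
    layers$protein_disease <- read_edge_list(inputs$protein_disease, "protein_disease", "unit")
  }
  net <- build_global_network(layers, quiet = quiet)
  write_network(net, file.path(out_dir, "network.tsv"))
  clock("build_net")

  # -- stage: embed ---------------------------------------------------------
  line_cfg <- config$line
  line_cfg$seed <- stage_seed(config$seed, "embed")
  emb <- line_embedding(net, line_cfg)
  write_embedding(emb, file.path(out_dir, "embedding.txt"))
  say("embedded ", nrow(emb), " nodes in ", ncol(emb), " dimensions")
  clock("embed")

  # -- stage: ontology + labels --------------------------------------------
  dag <- read_obo(inputs$ontology)
  annots <- propagate_annotations(dag, read_annotations(inputs$annotations))
  types <- setNames(net$vertices$type, net$vertices$id)
  entity_type <- function(ids) types[ids]
  annotated <- unique(annots$entity)
  train_entities <- sort(annotated[!is.na(entity_type(annotated)) &
                                     entity_type(annotated) == "protein"])
  if (length(train_entities) < 2) {
    stop("pipeline stage `train` failed: fewer than two annotated proteins",
         call. = FALSE)
  }
  train_annots <- annots[annots$entity %in% train_entities, ]
  attr(train_annots, "propagated") <- TRUE
  if (config$permute_training_labels) {
    train_annots <- permute_labels(train_annots, stage_seed(config$seed, "permute"))
  }
  terms <- select_terms(dag, train_annots, min_count = config$min_count,
                        namespace = config$namespace)
  if (length(terms) == 0) {
    stop("pipeline stage `train` failed: no trainable terms at min_count = ",
         config$min_count, call. = FALSE)
  }
  labels <- build_label_matrix(train_annots, terms)
  say("training on ", nrow(labels), " proteins x ", length(terms), " terms")

  # -- stage: train ---------------------------------------------------------
  model_cfg <- config$model
  model_cfg$seed <- stage_seed(config$seed, "train")
  features <- featurize(rownames(labels), emb)
  model <- train_hmc(features, labels, dag, model_cfg)
  saveRDS(model, file.path(out_dir, "model.rds"))
  clock("train")

  # -- stage: predict -------------------------------------------------------
  mirnas <- sort(net$vertices$id[net$vertices$type == "miRNA"])
  pred <- predict(model, featurize(mirnas, emb))
  write_predictions(pred, file.path(out_dir, "predictions.tsv"))
  clock("predict")

  # -- stage: evaluate ------------------------------------------------------
  truth_annots <- annots[annots$entity %in% mirnas, ]
  attr(truth_annots, "propagated") <- TRUE
  eval_cfg <- config$eval
  eval_cfg$namespace <- config$namespace
  ev <- withCallingHandlers(
    evaluate_predictions(pred, truth_annots, dag, eval_cfg),
    warning = function(w) {
      if (quiet) invokeRestart("muffleWarning")
    }
  )
  readr::write_tsv(tidy(ev), file.path(out_dir, "evaluation.tsv"), progress = FALSE)
  clock("evaluate")

  summary <- list(
    fmax = ev$fmax, t_max = ev$t_max,
    precision = ev$precision, recall = ev$recall,
    n = ev$n, coverage = ev$coverage,
    n_vertices = nrow(net$vertices), n_edges = nrow(net$edges),
    n_train_proteins = nrow(labels), n_terms = length(terms),
    n_mirnas_scored = length(mirnas),
    ablate_disease = config$ablate_disease,
    permute_training_labels = config$permute_training_labels,
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(timings, file.path(out_dir, "timings.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  strip_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  }
  cfg_out <- strip_classes(config)
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("Fmax = ", signif(ev$fmax, 4), " at t = ", ev$t_max)

  summary$timings_sec <- timings
  invisible(structure(
    list(summary = summary, eval = ev, model = model, prediction = pred,
         network = net, embedding = emb, dag = dag, truth = truth,
         out_dir = out_dir),
    class = "pipeline_run"
  ))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> ", x$out_dir, "\n", sep = "")
  print(x$eval)
  invisible(x)
}
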