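#' Evaluation settings
#'
#' @param thresholds Sorted score thresholds in `[0, 1]` (default: step 0.01).
#' @param namespace Optional namespace filter ("BP", "MF", "CC"); requires a
#'   DAG at evaluation time.
#' @param exclude_roots Drop namespace roots from both the predicted and the
#'   true term sets (predicting a root is vacuous); requires a DAG.
#' @return An `eval_config` list.
#' @export
eval_config <- function(thresholds = seq(0, 1, by = 0.01), namespace = NULL,
                        exclude_roots = TRUE) {
  thresholds <- sort(unique(as.double(thresholds)))
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(thresholds = thresholds, namespace = namespace,
         exclude_roots = isTRUE(exclude_roots)),
    class = "eval_config"
  )
}

#' Precision and recall for one entity at one threshold
#'
#' The predicted set P(t) holds every term scoring at least `t`; precision
#' is |P(t) n R| / |P(t)| (undefined when P(t) is empty) and recall is
#' |P(t) n R| / |R| against the true term set R.
#'
#' @param scores Named numeric vector of term scores for one entity.
#' @param truth Character vector: the entity's true (propagated) terms.
#' @param t Threshold.
#' @return Named vector `c(precision =, recall =)`; precision is `NA` when
#'   no term reaches the threshold.
#' @export
per_entity_pr <- function(scores, truth, t) {
  if (length(truth) == 0) stop("empty truth set", call. = FALSE)
  pred <- names(scores)[scores >= t]
  tp <- length(intersect(pred, truth))
  c(precision = if (length(pred) > 0) tp / length(pred) else NA_real_,
    recall = tp / length(truth))
}

# scores and truth as aligned matrices over the evaluation term universe
eval_matrices <- function(pred, truth, dag, config) {
  stopifnot(inherits(pred, "go_prediction"))
  if (!pred$merged) {
    stop("predictions must be hierarchically merged before evaluation",
         call. = FALSE)
  }
  if (!is_propagated(truth)) {
    stop("truth annotations must be propagated before evaluation", call. = FALSE)
  }
  drop_terms <- character(0)
  if (!is.null(dag)) {
    if (config$exclude_roots) drop_terms <- unname(dag$roots)
    if (!is.null(config$namespace)) {
      keep_ns <- names(dag$namespace)[dag$namespace == config$namespace]
      truth <- truth[truth$term %in% keep_ns, ]
    }
  } else if (!is.null(config$namespace) || isTRUE(config$exclude_roots)) {
    if (!is.null(config$namespace)) {
      stop("namespace filtering needs a DAG", call. = FALSE)
    }
  }
  truth <- truth[!(truth$term %in% drop_terms), ]

  truth_entities <- unique(truth$entity)
  common <- intersect(pred$entity_ids, truth_entities)
  if (length(common) == 0) {
    stop("prediction and truth entity sets are disjoint", call. = FALSE)
  }
  skipped <- setdiff(pred$entity_ids, truth_entities)
  if (length(skipped) > 0) {
    warning(length(skipped), " entity(ies) without truth annotations ",
            "excluded from evaluation", call. = FALSE)
  }

  universe <- sort(union(setdiff(pred$term_ids, drop_terms), unique(truth$term)))
  if (!is.null(dag) && !is.null(config$namespace)) {
    universe <- universe[universe %in% names(dag$namespace)[dag$namespace == config$namespace]]
  }
  entities <- sort(common)
  S <- matrix(0, length(entities), length(universe),
              dimnames = list(entities, universe))
  keep_cols <- intersect(pred$term_ids, universe)
  S[, keep_cols] <- pred$scores[entities, keep_cols, drop = FALSE]
  TR <- matrix(0, length(entities), length(universe),
               dimnames = list(entities, universe))
  hit <- truth[truth$entity %in% entities & truth$term %in% universe, ]
  TR[cbind(hit$entity, hit$term)] <- 1
  # entities whose truth became empty after filtering
  nonempty <- rowSums(TR) > 0
  if (any(!nonempty)) {
    warning(sum(!nonempty), " entity(ies) with empty truth in the evaluated ",
            "namespace excluded", call. = FALSE)
    S <- S[nonempty, , drop = FALSE]
    TR <- TR[nonempty, , drop = FALSE]
  }
  if (nrow(S) == 0) stop("no entities left to evaluate", call. = FALSE)
  list(scores = S, truth = TR)
}

#' Protein-centric evaluation over a threshold sweep
#'
#' For every threshold t: the average precision Pre(t) is taken over the
#' m(t) entities with at least one prediction scoring >= t, while the
#' average recall Rec(t) is taken over all N evaluated entities. Fmax is the
#' maximum harmonic mean 2*Pre*Rec/(Pre+Rec) across the sweep (thresholds
#' where m(t)=0 or Pre+Rec=0 are skipped). Entities with no truth
#' annotations in the evaluated namespace are excluded from N with a
#' warning.
#'
#' @param pred A merged [go_prediction()].
#' @param truth Propagated annotations tibble (`entity`, `term`).
#' @param dag Optional [go_dag()], required for namespace filtering and root
#'   exclusion.
#' @param config An [eval_config()].
#' @return A `go_eval` object: per-threshold tibble plus `fmax`, the argmax
#'   threshold, `n`, and coverage at the argmax threshold.
#' @export
evaluate_predictions <- function(pred, truth, dag = NULL, config = eval_config()) {
  if (is.null(dag) && isTRUE(config$exclude_roots)) {
    config$exclude_roots <- FALSE  # nothing to exclude without a DAG
  }
  m <- eval_matrices(pred, truth, dag, config)
  S <- m$scores
  TR <- m$truth
  n <- nrow(S)
  truth_sizes <- rowSums(TR)

  rows <- lapply(config$thresholds, function(t) {
    B <- S >= t
    npred <- rowSums(B)
    tp <- rowSums(B & (TR > 0))
    has_pred <- npred > 0
    m_t <- sum(has_pred)
    pre <- if (m_t > 0) mean(tp[has_pred] / npred[has_pred]) else NA_real_
    rec <- mean(tp / truth_sizes)
    tibble::tibble(t = t, precision = pre, recall = rec, m = m_t)
  })
  sweep_tbl <- dplyr::bind_rows(rows) |>
    dplyr::mutate(f = dplyr::if_else(
      !is.na(.data$precision) & (.data$precision + .data$recall) > 0,
      2 * .data$precision * .data$recall / (.data$precision + .data$recall),
      NA_real_
    ))

  if (all(is.na(sweep_tbl$f))) {
    fmax <- NA_real_
    t_max <- NA_real_
  } else {
    i <- which.max(sweep_tbl$f)
    fmax <- sweep_tbl$f[i]
    t_max <- sweep_tbl$t[i]
  }
  cov <- if (is.na(t_max)) 0L else sum(rowSums(S >= t_max) > 0)

  structure(
    list(thresholds = sweep_tbl, fmax = fmax, t_max = t_max, n = n,
         coverage = cov,
         precision = if (is.na(t_max)) NA_real_ else sweep_tbl$precision[sweep_tbl$t == t_max],
         recall = if (is.na(t_max)) NA_real_ else sweep_tbl$recall[sweep_tbl$t == t_max]),
    class = "go_eval"
  )
}

#' @export
print.go_eval <- function(x, ...) {
  cat("<go_eval> Fmax = ", signif(x$fmax, 4), " at t = ", x$t_max,
      " (Pre ", signif(x$precision, 4), ", Rec ", signif(x$recall, 4),
      "); N = ", x$n, ", coverage = ", x$coverage, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.go_eval <- function(x, ...) x$thresholds

#' @export
glance.go_eval <- function(x, ...) {
  tibble::tibble(fmax = x$fmax, t_max = x$t_max, precision = x$precision,
                 recall = x$recall, n = x$n, coverage = x$coverage)
}

#' Coverage: entities with at least one predicted term at a threshold
#'
#' @param pred A merged [go_prediction()].
#' @param t Score threshold.
#' @param dag,namespace Optional: restrict to terms of one namespace.
#' @return Integer count.
#' @export
prediction_coverage <- function(pred, t, dag = NULL, namespace = NULL) {
  stopifnot(inherits(pred, "go_prediction"))
  terms <- pred$term_ids
  if (!is.null(namespace)) {
    if (is.null(dag)) stop("namespace filtering needs a DAG", call. = FALSE)
    terms <- terms[dag$namespace[terms] == namespace]
  }
  if (length(terms) == 0) return(0L)
  sum(rowSums(pred$scores[, terms, drop = FALSE] >= t) > 0)
}

#' Precision-recall curve of an evaluation
#'
#' @param result A `go_eval`.
#' @return Tibble of `(t, recall, precision)` in threshold order.
#' @export
pr_curve <- function(result) {
  stopifnot(inherits(result, "go_eval"))
  result$thresholds[, c("t", "recall", "precision")]
}

#' @export
autoplot.go_eval <- function(object, ...) {
  pr_curve(object) |>
    dplyr::filter(!is.na(.data$precision)) |>
    ggplot2::ggplot(ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "average recall", y = "average precision")
}
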