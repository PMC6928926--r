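#' Classifier hyper-parameters
#'
#' One shared fully connected layer feeds one sigmoid output unit per GO
#' term; maximum-merge layers then enforce parent >= child consistency.
#' Defaults: 1024 hidden units, RMSprop at learning rate 0.01, minibatch 64,
#' dropout 0.2 after the shared layer, 80/20 train/validation hold-out with
#' checkpoint selection on validation loss.
#'
#' @param hidden_units Width of the shared fully connected layer.
#' @param minibatch Minibatch size.
#' @param learning_rate RMSprop learning rate.
#' @param dropout_rate Dropout after the shared layer, in `[0, 1)`.
#' @param max_epochs Maximum training epochs (0 = return the initialization).
#' @param patience Epochs without validation improvement before stopping.
#' @param holdout_fraction Fraction held out for validation, in (0, 1).
#' @param loss_on_merged Compute the binary cross-entropy on the merged
#'   outputs (default) rather than the raw per-term heads.
#' @param seed Integer seed controlling initialization, the hold-out split,
#'   shuffling and dropout.
#' @return An `hmc_config` list.
#' @export
hmc_config <- function(hidden_units = 1024, minibatch = 64, learning_rate = 0.01,
                       dropout_rate = 0.2, max_epochs = 100, patience = 10,
                       holdout_fraction = 0.2, loss_on_merged = TRUE, seed = 1L) {
  stopifnot(hidden_units >= 1, minibatch >= 1, learning_rate > 0,
            dropout_rate >= 0, dropout_rate < 1, max_epochs >= 0,
            patience >= 1, holdout_fraction > 0, holdout_fraction < 1)
  structure(
    list(hidden_units = as.integer(hidden_units), minibatch = as.integer(minibatch),
         learning_rate = learning_rate, dropout_rate = dropout_rate,
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         holdout_fraction = holdout_fraction,
         loss_on_merged = isTRUE(loss_on_merged), seed = as.integer(seed)),
    class = "hmc_config"
  )
}

#' Look up feature vectors, with the zero-vector fallback
#'
#' Entities present in the embedding get their row; entities absent from the
#' network (hence from the embedding) get a zero vector of the same
#' dimension, so they can still be scored.
#'
#' @param entities Character vector of entity ids.
#' @param emb Embedding matrix with rownames.
#' @return Numeric matrix, `length(entities)` x `ncol(emb)`.
#' @export
featurize <- function(entities, emb) {
  entities <- as.character(entities)
  out <- matrix(0, nrow = length(entities), ncol = ncol(emb),
                dimnames = list(entities, colnames(emb)))
  present <- entities[entities %in% rownames(emb)]
  out[present, ] <- emb[present, , drop = FALSE]
  out
}

# For each selected term, the indices (into `terms`) of the selected terms
# directly below it in the DAG, bridging over unselected intermediates.
# `terms` must be in reverse-topological order, so every child index is
# smaller than its parent's.
selected_children <- function(dag, terms) {
  sel <- setNames(seq_along(terms), terms)
  out <- lapply(terms, function(t) {
    found <- integer(0)
    stack <- dag$children[[t]]
    seen <- character(0)
    while (length(stack) > 0) {
      c1 <- stack[[1]]
      stack <- stack[-1]
      if (c1 %in% seen) next
      seen <- c(seen, c1)
      if (!is.na(sel[c1])) {
        found <- c(found, sel[[c1]])
      } else {
        stack <- c(stack, dag$children[[c1]])
      }
    }
    sort(unique(found))
  })
  for (j in seq_along(out)) {
    if (any(out[[j]] >= j)) {
      stop("terms are not in reverse-topological order", call. = FALSE)
    }
  }
  out
}

# bottom-up max scan; optionally tracks which input won each max so the
# gradient can be routed back to it (0 = the term's own raw score)
merge_scores <- function(raw, children, track = FALSE) {
  M <- raw
  S <- if (track) matrix(0L, nrow(raw), ncol(raw)) else NULL
  rows <- seq_len(nrow(raw))
  for (j in seq_along(children)) {
    ch <- children[[j]]
    if (length(ch) > 0) {
      cand <- cbind(raw[, j], M[, ch, drop = FALSE])
      win <- max.col(cand, ties.method = "first")
      M[, j] <- cand[cbind(rows, win)]
      if (track) S[, j] <- c(0L, ch)[win]
    }
  }
  list(M = M, S = S)
}

#' Enforce hierarchical consistency by maximum merge
#'
#' Each term with children takes the maximum of its own score and its
#' children's merged scores, scanned bottom-up (children first), so that
#' score(parent) >= score(child) for every parent-child pair among the
#' scored terms. Idempotent.
#'
#' @param scores Numeric matrix (entities x terms) in `[0, 1]`, or a
#'   `go_prediction`.
#' @param dag A [go_dag()].
#' @return The merged object of the same kind, marked `merged = TRUE`.
#' @export
max_merge <- function(scores, dag) {
  if (inherits(scores, "go_prediction")) {
    m <- max_merge(scores$scores, dag)
    return(go_prediction(m, merged = TRUE))
  }
  terms <- colnames(scores)
  ord <- dag$order[dag$order %in% terms]
  if (length(ord) != length(terms)) {
    stop("score columns contain terms absent from the DAG", call. = FALSE)
  }
  children <- selected_children(dag, ord)
  merged <- merge_scores(scores[, ord, drop = FALSE], children)$M
  merged[, terms, drop = FALSE]
}

#' Prediction scores for entities over GO terms
#'
#' @param scores Numeric matrix (entities x terms) with scores in `[0, 1]`.
#' @param merged Whether the scores are hierarchically consistent
#'   (parent >= child), i.e. have been through the maximum-merge layers.
#' @return A `go_prediction` object.
#' @export
go_prediction <- function(scores, merged = FALSE) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)), !is.null(colnames(scores)))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]", call. = FALSE)
  structure(
    list(entity_ids = rownames(scores), term_ids = colnames(scores),
         scores = scores, merged = isTRUE(merged)),
    class = "go_prediction"
  )
}

#' @export
print.go_prediction <- function(x, ...) {
  cat("<go_prediction> ", length(x$entity_ids), " entities x ",
      length(x$term_ids), " terms; merged = ", x$merged, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.go_prediction <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "entity") |>
    tidyr::pivot_longer(-"entity", names_to = "term", values_to = "score")
}

hmc_init <- function(feature_dim, hidden, n_terms) {
  lim1 <- sqrt(6 / (feature_dim + hidden))
  lim2 <- sqrt(6 / (hidden + 1))
  list(
    W1 = matrix(runif(feature_dim * hidden, -lim1, lim1), feature_dim, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(runif(hidden * n_terms, -lim2, lim2), hidden, n_terms),
    b2 = rep(0, n_terms)
  )
}

hmc_forward_pass <- function(params, X, children, dropout_rate = 0,
                             stochastic = FALSE, track = FALSE) {
  Z1 <- sweep(X %*% params$W1, 2, params$b1, "+")
  H <- pmax(Z1, 0)
  mask <- NULL
  if (stochastic && dropout_rate > 0) {
    mask <- matrix(
      (runif(length(H)) >= dropout_rate) / (1 - dropout_rate),
      nrow(H), ncol(H)
    )
    Hd <- H * mask
  } else {
    Hd <- H
  }
  A <- sweep(Hd %*% params$W2, 2, params$b2, "+")
  R <- 1 / (1 + exp(-A))
  mg <- merge_scores(R, children, track = track)
  list(Z1 = Z1, Hd = Hd, mask = mask, R = R, M = mg$M, S = mg$S)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# gradient of mean BCE w.r.t. the pre-sigmoid activations, routed through
# the max-merge argmax pointers: each output's (score - label) lands on the
# head whose raw score won the nested max
route_gradient <- function(D, S) {
  for (j in rev(seq_len(ncol(D)))) {
    src <- S[, j]
    nz <- which(src != 0L)
    if (length(nz) > 0) {
      for (c1 in unique(src[nz])) {
        rows <- nz[src[nz] == c1]
        D[rows, c1] <- D[rows, c1] + D[rows, j]
      }
      D[nz, j] <- 0
    }
  }
  D
}

hmc_gradients <- function(params, X, Y, fw, loss_on_merged = TRUE) {
  scale <- nrow(Y) * ncol(Y)
  if (loss_on_merged) {
    D <- route_gradient((fw$M - Y) / scale, fw$S)
  } else {
    D <- (fw$R - Y) / scale
  }
  dHd <- D %*% t(params$W2)
  dH <- if (!is.null(fw$mask)) dHd * fw$mask else dHd
  dZ1 <- dH * (fw$Z1 > 0)
  list(
    W1 = crossprod(X, dZ1), b1 = colSums(dZ1),
    W2 = crossprod(fw$Hd, D), b2 = colSums(D)
  )
}

rmsprop_step <- function(params, grads, cache, lr, decay = 0.9, eps = 1e-8) {
  for (nm in names(params)) {
    cache[[nm]] <- decay * cache[[nm]] + (1 - decay) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - lr * grads[[nm]] / (sqrt(cache[[nm]]) + eps)
  }
  list(params = params, cache = cache)
}

#' Train the hierarchical multi-label classifier
#'
#' Fits the shared-layer / per-term-sigmoid / maximum-merge network by
#' RMSprop on multi-output binary cross-entropy computed (by default) on the
#' merged outputs. A random `holdout_fraction` of the entities forms a
#' validation set; after every epoch the validation loss is monitored and
#' the checkpoint with the lowest validation loss is returned, with early
#' stopping after `patience` epochs without improvement. Entirely
#' reproducible given `config$seed`.
#'
#' @param features Numeric matrix (entities x feature dim), e.g. from
#'   [featurize()].
#' @param labels Binary matrix from [build_label_matrix()]; columns must be
#'   in reverse-topological order and rows aligned with `features`.
#' @param dag The [go_dag()] the label columns come from.
#' @param config An [hmc_config()].
#' @return An `hmc_model`.
#' @export
train_hmc <- function(features, labels, dag, config = hmc_config()) {
  stopifnot(is.matrix(features), is.matrix(labels))
  if (nrow(features) < 2) stop("need at least two training entities", call. = FALSE)
  if (nrow(features) != nrow(labels) ||
      !identical(rownames(features), rownames(labels))) {
    stop("features and labels must cover the same entities in the same order",
         call. = FALSE)
  }
  if (sum(labels) == 0) stop("no positive labels", call. = FALSE)
  terms <- colnames(labels)
  children <- selected_children(dag, terms)

  set.seed(config$seed)
  params <- hmc_init(ncol(features), config$hidden_units, length(terms))
  cache <- lapply(params, function(p) p * 0)

  n <- nrow(features)
  n_val <- max(1L, round(config$holdout_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- features[tr_idx, , drop = FALSE]
  Ytr <- labels[tr_idx, , drop = FALSE]
  Xval <- features[val_idx, , drop = FALSE]
  Yval <- labels[val_idx, , drop = FALSE]

  val_loss_of <- function(p) {
    fw <- hmc_forward_pass(p, Xval, children)
    bce_loss(if (config$loss_on_merged) fw$M else fw$R, Yval)
  }

  best <- params
  best_loss <- val_loss_of(params)
  best_epoch <- 0L
  history <- list()
  stall <- 0L

  if (config$max_epochs > 0) {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nrow(Xtr))
      batch_losses <- c()
      for (start in seq(1, length(ord), by = config$minibatch)) {
        idx <- ord[start:min(start + config$minibatch - 1L, length(ord))]
        X <- Xtr[idx, , drop = FALSE]
        Y <- Ytr[idx, , drop = FALSE]
        fw <- hmc_forward_pass(params, X, children,
                               dropout_rate = config$dropout_rate,
                               stochastic = TRUE, track = config$loss_on_merged)
        batch_losses <- c(batch_losses,
                          bce_loss(if (config$loss_on_merged) fw$M else fw$R, Y))
        grads <- hmc_gradients(params, X, Y, fw, config$loss_on_merged)
        upd <- rmsprop_step(params, grads, cache, config$learning_rate)
        params <- upd$params
        cache <- upd$cache
      }
      vl <- val_loss_of(params)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(batch_losses), val_loss = vl
      )
      if (vl < best_loss - 1e-9) {
        best <- params
        best_loss <- vl
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  }

  structure(
    list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
         term_ids = terms, children = children,
         feature_dim = ncol(features), config = config,
         best_epoch = best_epoch, val_loss = best_loss,
         history = dplyr::bind_rows(history)),
    class = "hmc_model"
  )
}

#' @export
print.hmc_model <- function(x, ...) {
  cat("<hmc_model> ", x$feature_dim, " features -> ", ncol(x$W1),
      " hidden -> ", length(x$term_ids), " terms (max-merged); best epoch ",
      x$best_epoch, ", val loss ", signif(x$val_loss, 4), "\n", sep = "")
  invisible(x)
}

#' Predict GO term scores
#'
#' Forward pass in inference mode (dropout off) followed by the
#' maximum-merge layers, so the returned scores are hierarchically
#' consistent. Deterministic.
#'
#' @param object An `hmc_model`.
#' @param features Numeric matrix (entities x feature dim); entities without
#'   network features should carry zero vectors (see [featurize()]).
#' @param ... Unused.
#' @return A [go_prediction()] with `merged = TRUE`.
#' @export
predict.hmc_model <- function(object, features, ...) {
  stopifnot(is.matrix(features))
  if (ncol(features) != object$feature_dim) {
    stop("feature dimension mismatch: model expects ", object$feature_dim,
         ", got ", ncol(features), call. = FALSE)
  }
  params <- object[c("W1", "b1", "W2", "b2")]
  fw <- hmc_forward_pass(params, features, object$children)
  scores <- fw$M
  dimnames(scores) <- list(rownames(features), object$term_ids)
  go_prediction(scores, merged = TRUE)
}

#' @export
tidy.hmc_model <- function(x, ...) {
  tibble::tibble(
    term = x$term_ids,
    bias = x$b2,
    weight_norm = sqrt(colSums(x$W2^2)),
    n_children = lengths(x$children)
  )
}

#' @export
glance.hmc_model <- function(x, ...) {
  tibble::tibble(
    n_terms = length(x$term_ids),
    hidden_units = ncol(x$W1),
    feature_dim = x$feature_dim,
    best_epoch = x$best_epoch,
    val_loss = x$val_loss
  )
}

#' @export
autoplot.hmc_model <- function(object, ...) {
  if (nrow(object$history) == 0) {
    stop("model has no training history to plot", call. = FALSE)
  }
  object$history |>
    tidyr::pivot_longer(-"epoch", names_to = "set", values_to = "loss") |>
    ggplot2::ggplot(ggplot2::aes(.data$epoch, .data$loss, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy", colour = NULL)
}

#' Write / read predictions as TSV (`entity<TAB>term<TAB>score`)
#'
#' @param pred A [go_prediction()].
#' @param path TSV path.
#' @export
write_predictions <- function(pred, path) {
  readr::write_tsv(tidy(pred), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @param merged Whether the stored scores were hierarchically merged.
#' @export
read_predictions <- function(path, merged = TRUE) {
  long <- readr::read_tsv(path, col_types = readr::cols(
    entity = "c", term = "c", score = "d"
  ), progress = FALSE)
  wide <- tidyr::pivot_wider(long, names_from = "term", values_from = "score",
                             values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$entity
  go_prediction(m, merged = merged)
}
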