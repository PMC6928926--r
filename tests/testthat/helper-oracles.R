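# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (set arithmetic, covariance formula,
# matrix-power closure) and share no code path with the package.

# Pearson correlation straight from the covariance definition
oracle_pcc <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# all positive-PCC pairs of the rows of m (ids = rownames), by double loop
oracle_pcc_edges <- function(m) {
  ids <- rownames(m)
  out <- list()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      r <- oracle_pcc(m[i, ], m[j, ])
      if (is.finite(r) && r > 0) {
        a <- min(ids[i], ids[j])
        b <- max(ids[i], ids[j])
        out[[length(out) + 1]] <- data.frame(u = a, v = b, weight = r)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(u = character(), v = character(), weight = double()))
  }
  o <- do.call(rbind, out)
  o[order(o$u, o$v), , drop = FALSE]
}

# reachability (strict ancestor) matrix by boolean matrix powers
oracle_closure <- function(dag) {
  terms <- dag$terms
  A <- matrix(FALSE, length(terms), length(terms), dimnames = list(terms, terms))
  for (t in terms) A[t, dag$parents[[t]]] <- TRUE
  repeat {
    A2 <- A | ((A %*% A) > 0)
    if (identical(A2, A)) break
    A <- A2
  }
  A
}

# max-merge by collapsing nested maxima: merged(t) = max raw over {t} and
# every scored strict descendant of t
oracle_max_merge <- function(raw, dag) {
  anc <- oracle_closure(dag)  # anc[x, y]: y is an ancestor of x
  terms <- colnames(raw)
  out <- raw
  for (t in terms) {
    desc <- rownames(anc)[anc[, t]]
    group <- intersect(c(t, desc), terms)
    out[, t] <- apply(raw[, group, drop = FALSE], 1, max)
  }
  out
}

# Eqs-style protein-centric evaluation by explicit set arithmetic
oracle_evaluate <- function(scores, truth_sets, thresholds) {
  entities <- rownames(scores)
  entities <- entities[vapply(
    entities, function(e) length(truth_sets[[e]]) > 0, TRUE
  )]
  terms <- colnames(scores)
  rows <- data.frame()
  for (t in thresholds) {
    pre_i <- c()
    rec_i <- c()
    m <- 0L
    for (e in entities) {
      P <- terms[scores[e, ] >= t]
      R <- truth_sets[[e]]
      tp <- length(intersect(P, R))
      if (length(P) > 0) {
        m <- m + 1L
        pre_i <- c(pre_i, tp / length(P))
      }
      rec_i <- c(rec_i, tp / length(R))
    }
    pre <- if (m > 0) sum(pre_i) / m else NA_real_
    rec <- sum(rec_i) / length(entities)
    f <- if (!is.na(pre) && (pre + rec) > 0) 2 * pre * rec / (pre + rec) else NA_real_
    rows <- rbind(rows, data.frame(t = t, precision = pre, recall = rec,
                                   m = m, f = f))
  }
  fmax <- if (all(is.na(rows$f))) NA_real_ else max(rows$f, na.rm = TRUE)
  list(sweep = rows, fmax = fmax,
       t_max = if (is.na(fmax)) NA_real_ else rows$t[which.max(rows$f)])
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
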