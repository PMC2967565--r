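# Independent reference implementations used as oracles. These deliberately
# take the slow/brute-force route and never call the code paths they check.

# enumerate all contiguous c-partitions of the sorted values; return the
# minimal within-cluster sum of squares
oracle_kmeans1d_wcss <- function(values, c) {
  x <- sort(values)
  n <- length(x)
  stopifnot(c <= n)
  wcss_of <- function(bounds) {
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    sum(vapply(seq_along(starts), function(i) {
      seg <- x[starts[i]:ends[i]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
  }
  if (c == 1L) return(wcss_of(integer(0)))
  cuts <- utils::combn(n - 1L, c - 1L)
  min(apply(cuts, 2L, wcss_of))
}

# assign EWD levels value by value from explicit cut points,
# cut-point-equal values going to the lower interval
oracle_ewd_row <- function(v, k) {
  lo <- min(v); hi <- max(v)
  cuts <- lo + (hi - lo) / k * seq_len(k - 1L)
  vapply(v, function(val) {
    lv <- 1L
    for (cp in cuts) if (val > cp) lv <- lv + 1L
    lv
  }, integer(1))
}

# quantile-style EFD oracle: count how many sorted positions precede each
# value's stable-sorted slot
oracle_efd_sizes <- function(M, k) {
  sizes <- rep(M %/% k, k)
  if (M %% k > 0) sizes[seq_len(M %% k)] <- sizes[seq_len(M %% k)] + 1L
  sizes
}

# plug-in mutual information from an explicitly built contingency table
oracle_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij > 0)
      mi <- mi + nij / n * log((nij * n) / (sum(tab[i, ]) * sum(tab[, j])))
  }
  mi
}

# confusion counts by looping over every ordered gene pair
oracle_confusion <- function(inferred, truth) {
  genes <- truth$genes
  in_set <- function(net, a, b)
    any(net$edges[, 1L] == a & net$edges[, 2L] == b)
  tp <- tn <- fp <- fn <- 0L
  for (a in genes) for (b in genes) {
    if (a == b) next
    t_ <- in_set(truth, a, b)
    i_ <- in_set(inferred, a, b)
    if (t_ && i_) tp <- tp + 1L
    else if (t_ && !i_) fn <- fn + 1L
    else if (!t_ && i_) fp <- fp + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Cooper-Herskovits family log-score computed straight from the closed form
oracle_ch_score <- function(x, parent_levels, r) {
  if (is.null(parent_levels) || length(parent_levels) == 0L) {
    pj <- rep(1L, length(x))
  } else {
    pm <- do.call(cbind, parent_levels)
    pj <- as.integer(factor(apply(pm, 1L, paste, collapse = "-")))
  }
  score <- 0
  for (j in unique(pj)) {
    xs <- x[pj == j]
    nj <- length(xs)
    score <- score + lgamma(r) - lgamma(nj + r)
    for (k in seq_len(r)) score <- score + lgamma(sum(xs == k) + 1)
  }
  score
}

# exhaustive K2 oracle: per node, best-scoring subset of its predecessors
# (up to max_parents) under the CH score
oracle_k2 <- function(lv, order_idx, max_parents, r) {
  N <- nrow(lv)
  edges <- NULL
  for (pos in seq_along(order_idx)) {
    node <- order_idx[pos]
    cands <- order_idx[seq_len(pos - 1L)]
    best <- oracle_ch_score(lv[node, ], NULL, r)
    best_set <- integer(0)
    for (sz in seq_len(min(max_parents, length(cands)))) {
      if (length(cands) == 0L) break
      sets <- if (length(cands) == 1L) matrix(cands, 1L, 1L)
              else utils::combn(cands, sz)
      for (ci in seq_len(ncol(sets))) {
        pa <- sets[, ci]
        sc <- oracle_ch_score(lv[node, ], lapply(pa, function(p) lv[p, ]), r)
        if (sc > best + 1e-9) { best <- sc; best_set <- pa }
      }
    }
    for (p in best_set) edges <- rbind(edges, c(p, node))
  }
  edges
}

# independent stepwise replay of greedy K2 parent selection (pure R, scores
# from oracle_ch_score): at each step score every remaining candidate and
# take the first strict maximizer, stop when nothing improves
oracle_k2_greedy <- function(lv, order_idx, max_parents, r) {
  edges <- NULL
  for (pos in seq_along(order_idx)) {
    node <- order_idx[pos]
    cands <- order_idx[seq_len(pos - 1L)]
    pa <- integer(0)
    cur <- oracle_ch_score(lv[node, ], NULL, r)
    while (length(pa) < max_parents && length(cands) > 0L) {
      scores <- vapply(cands, function(p)
        oracle_ch_score(lv[node, ], lapply(c(pa, p),
                                           function(q) lv[q, ]), r),
        numeric(1))
      best <- which.max(scores)
      if (scores[best] <= cur + 1e-9) break
      cur <- scores[best]
      pa <- c(pa, cands[best])
      cands <- cands[-best]
    }
    for (p in pa) edges <- rbind(edges, c(p, node))
  }
  edges
}

# DAG test by repeated sink elimination
is_dag <- function(net) {
  genes <- net$genes
  e <- net$edges
  repeat {
    if (nrow(e) == 0L) return(TRUE)
    has_out <- genes %in% e[, 1L]
    has_in <- genes %in% e[, 2L]
    sinks <- genes[has_in & !has_out]
    sources <- genes[has_out & !has_in]
    iso <- genes[!has_in & !has_out]
    if (length(sinks) == 0L && length(sources) == 0L) return(FALSE)
    drop <- c(sinks, sources, iso)
    genes <- setdiff(genes, drop)
    e <- e[!(e[, 1L] %in% drop) & !(e[, 2L] %in% drop), , drop = FALSE]
  }
}

# small random fixtures
rand_expression <- function(n = 6L, m = 10L, seed = 1L) {
  set.seed(seed)
  expression_matrix(matrix(stats::runif(n * m, 10, 500), n, m),
                    sprintf("G%02d", seq_len(n)),
                    paste0("T", seq_len(m)))
}

rand_discrete <- function(n = 4L, m = 25L, k = 3L, seed = 1L) {
  set.seed(seed)
  discrete_matrix(matrix(sample.int(k, n * m, replace = TRUE), n, m,
                         dimnames = list(sprintf("G%02d", seq_len(n)),
                                         paste0("T", seq_len(m)))),
                  k, "manual")
}
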