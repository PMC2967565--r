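#' Node ordering by time of initial expression change
#'
#' For each gene the fold change of every time point relative to the first
#' (baseline) time point is computed; the initial-change time is the earliest
#' `t >= 2` with fold change `>= up_cut` (up-regulation) or `<= down_cut`
#' (down-regulation). Genes are ordered by ascending initial-change time —
#' earlier changers are eligible regulators of later ones — with genes that
#' never cross either cutoff placed last and ties broken by input row order.
#'
#' @param m An [expression_matrix()] with strictly non-zero baseline values.
#' @param up_cut Up-regulation fold-change cutoff (default 1.2).
#' @param down_cut Down-regulation fold-change cutoff (default 0.7).
#' @return A list of class `NodeOrder` with `genes` (ordered ids) and
#'   `change_time` (named integer vector, `NA` for never-changing genes).
#' @export
node_order <- function(m, up_cut = 1.2, down_cut = 0.7) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  base <- m[, 1L]
  if (any(base == 0))
    stop("zero baseline expression for gene(s): ",
         paste(rownames(m)[base == 0], collapse = ", "))
  fc <- sweep(unclass(m), 1L, base, `/`)
  change_time <- apply(fc[, -1L, drop = FALSE], 1L, function(r) {
    hit <- which(r >= up_cut | r <= down_cut)
    if (length(hit) == 0L) NA_integer_ else hit[1L] + 1L
  })
  ord <- order(ifelse(is.na(change_time), .Machine$integer.max, change_time),
               seq_len(nrow(m)))
  structure(list(genes = rownames(m)[ord],
                 change_time = stats::setNames(as.integer(change_time),
                                               rownames(m))),
            class = "NodeOrder")
}

#' @export
print.NodeOrder <- function(x, ...) {
  cat("NodeOrder over", length(x$genes), "genes (earliest changers first)\n")
  invisible(x)
}

.check_discrete <- function(d) {
  stopifnot(inherits(d, "DiscreteMatrix"))
  if (is.null(rownames(d))) rownames(d) <- paste0("G", seq_len(nrow(d)))
  d
}

#' K2 structure learning with a fixed node ordering
#'
#' Classic K2: visiting genes in the given order, each gene greedily acquires
#' the predecessor parent that most increases the Cooper-Herskovits marginal
#' likelihood (computed in log space, uniform Dirichlet prior), stopping when
#' no single addition improves the score or `max_parents` is reached. Time
#' points are treated as i.i.d. samples of a static Bayesian network.
#'
#' @param d A [discrete_matrix()] (genes x time points).
#' @param order A [node_order()] (or a character vector of gene ids) covering
#'   exactly the genes of `d`.
#' @param max_parents Maximum parents per gene (default 3).
#' @return A [regulatory_network()]; every edge points from an earlier to a
#'   later gene in the order, so the result is a DAG.
#' @export
k2 <- function(d, order, max_parents = 3L) {
  d <- .check_discrete(d)
  ord_genes <- if (inherits(order, "NodeOrder")) order$genes
               else as.character(order)
  genes <- rownames(d)
  if (!setequal(ord_genes, genes) || length(ord_genes) != length(genes))
    stop("node order must be a permutation of the matrix genes; missing: ",
         paste(setdiff(genes, ord_genes), collapse = ", "))
  D <- t(unclass(d))  # samples x variables
  nlev <- rep(attr(d, "k"), ncol(D))
  e <- .k2_cpp(D, match(ord_genes, genes), as.integer(max_parents),
               as.integer(nlev))
  edges <- cbind(genes[e[, 1L]], genes[e[, 2L]])
  regulatory_network(genes, edges)
}

#' Greedy hill-climbing DAG search
#'
#' Score-based structure learning from the empty graph with add, delete and
#' reverse moves, acyclicity enforced, first-ascent over a deterministic
#' lexicographic move enumeration, stopping at a local optimum. The default
#' score is BIC; the K2-style Cooper-Herskovits marginal likelihood is also
#' available.
#'
#' @param d A [discrete_matrix()].
#' @param score `"bic"` (default) or `"k2_marginal"`.
#' @param max_parents Maximum parents per gene (default 3).
#' @param seed Ignored (the search is deterministic); kept for interface
#'   stability.
#' @return A [regulatory_network()] that is a DAG and whose total score is at
#'   least the empty-graph score.
#' @export
greedy_search <- function(d, score = c("bic", "k2_marginal"),
                          max_parents = 3L, seed = NULL) {
  d <- .check_discrete(d)
  score <- match.arg(score)
  D <- t(unclass(d))
  genes <- rownames(d)
  nlev <- rep(attr(d, "k"), ncol(D))
  e <- .greedy_cpp(D, as.integer(max_parents), as.integer(nlev),
                   if (score == "bic") 1L else 0L)
  regulatory_network(genes, cbind(genes[e[, 1L]], genes[e[, 2L]]))
}

#' Total network score of a DAG on discrete data
#'
#' Sum of per-family scores under the same scoring functions used by [k2()]
#' and [greedy_search()]; exposed for diagnostics and testing.
#'
#' @inheritParams greedy_search
#' @param net A [regulatory_network()] over the genes of `d`.
#' @export
network_score <- function(d, net, score = c("bic", "k2_marginal")) {
  d <- .check_discrete(d)
  score <- match.arg(score)
  genes <- rownames(d)
  e <- net$edges
  em <- if (nrow(e) == 0L) matrix(integer(0), 0L, 2L)
        else cbind(match(e[, 1L], genes), match(e[, 2L], genes))
  storage.mode(em) <- "integer"
  .dag_score_cpp(t(unclass(d)), em, rep(as.integer(attr(d, "k")), nrow(d)),
                 if (score == "bic") 1L else 0L)
}

#' Pairwise mutual information of discretized genes
#'
#' Plug-in mutual information (natural log) from the joint contingency table
#' of each gene pair across time points, with large-sample p-values from
#' `2 M MI ~ chi-square` on `(r - 1)(c - 1)` degrees of freedom, where `r`
#' and `c` are the numbers of levels actually observed for the two genes. A
#' gene with a single observed level has MI 0 and p-value 1 against every
#' partner.
#'
#' @param d A [discrete_matrix()].
#' @return A list of class `MIMatrix` with symmetric matrices `mi` (nats) and
#'   `p_value`; diagonals are `NA`.
#' @export
mutual_information <- function(d) {
  d <- .check_discrete(d)
  N <- nrow(d); M <- ncol(d)
  genes <- rownames(d)
  mi <- matrix(0, N, N, dimnames = list(genes, genes))
  pv <- matrix(1, N, N, dimnames = list(genes, genes))
  lv <- unclass(d)
  obs_levels <- apply(lv, 1L, function(x) length(unique(x)))
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      if (obs_levels[i] < 2L || obs_levels[j] < 2L) next
      tab <- table(lv[i, ], lv[j, ])
      p <- tab / M
      pi_ <- rowSums(p); pj <- colSums(p)
      nz <- p > 0
      m_ij <- sum(p[nz] * log(p[nz] / outer(pi_, pj)[nz]))
      m_ij <- max(m_ij, 0)
      df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
      mi[i, j] <- mi[j, i] <- m_ij
      pv[i, j] <- pv[j, i] <- stats::pchisq(2 * M * m_ij, df,
                                            lower.tail = FALSE)
    }
  }
  diag(mi) <- NA_real_; diag(pv) <- NA_real_
  structure(list(mi = mi, p_value = pv), class = "MIMatrix")
}

#' ARACNE-style network inference
#'
#' Gene pairs whose mutual-information p-value is at most `p_threshold` form
#' the candidate undirected graph. The data-processing inequality then prunes
#' putative indirect interactions: triangles (unordered gene triples whose
#' three pairs are all present) are scanned in lexicographic order and the
#' edge `(a, c)` is marked for removal when
#' `MI(a, c) < min(MI(a, b), MI(b, c)) * (1 - dpi_tolerance)`; all removals
#' are applied after the full scan. The surviving undirected edges are
#' expanded to both ordered pairs so the result shares the directed pair
#' universe of the other algorithms.
#'
#' @param d A [discrete_matrix()].
#' @param p_threshold MI significance cutoff (default `1e-7`).
#' @param dpi_tolerance DPI tolerance `t` in `[0, 1]` (default 0.15); `t = 1`
#'   disables pruning.
#' @return A [regulatory_network()] with symmetric (both-direction) edges.
#' @export
aracne <- function(d, p_threshold = 1e-7, dpi_tolerance = 0.15) {
  d <- .check_discrete(d)
  mim <- mutual_information(d)
  genes <- rownames(d)
  N <- length(genes)
  keep <- !is.na(mim$p_value) & mim$p_value <= p_threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  keep <- dpi_prune(mim$mi, keep, dpi_tolerance)
  pairs <- which(keep, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(regulatory_network(genes))
  edges <- rbind(cbind(genes[pairs[, 1L]], genes[pairs[, 2L]]),
                 cbind(genes[pairs[, 2L]], genes[pairs[, 1L]]))
  regulatory_network(genes, edges)
}

#' Data-processing-inequality pruning of an MI graph
#'
#' For every triangle (unordered triple of genes with all three pairs kept),
#' scanned in lexicographic order, the edge whose mutual information falls
#' below `min` of the other two times `(1 - tolerance)` is marked; all marks
#' are applied after the full scan. Exposed for direct testing of the DPI
#' rule on crafted MI matrices.
#'
#' @param mi Symmetric MI matrix.
#' @param keep Logical upper-triangular matrix of currently kept pairs.
#' @param tolerance DPI tolerance in `[0, 1]`; 1 disables pruning.
#' @return Pruned logical upper-triangular matrix.
#' @export
dpi_prune <- function(mi, keep, tolerance) {
  N <- nrow(mi)
  if (tolerance >= 1 || sum(keep) == 0L) return(keep)
  adj <- keep | t(keep)
  drop <- matrix(FALSE, N, N)
  slack <- 1 - tolerance
  for (a in seq_len(max(N - 2L, 0L))) {
    for (b in seq(a + 1L, N - 1L)) {
      if (!adj[a, b]) next
      for (cc in seq(b + 1L, N)) {
        if (!adj[a, cc] || !adj[b, cc]) next
        m_ab <- mi[a, b]; m_bc <- mi[b, cc]; m_ac <- mi[a, cc]
        if (m_ac < min(m_ab, m_bc) * slack) drop[a, cc] <- TRUE
        if (m_ab < min(m_ac, m_bc) * slack) drop[a, b] <- TRUE
        if (m_bc < min(m_ab, m_ac) * slack) drop[b, cc] <- TRUE
      }
    }
  }
  keep & !(drop | t(drop))
}

#' Infer a network by a named algorithm
#'
#' Dispatcher used by the benchmark driver and CLI. `"k2"` requires the
#' continuous matrix `expr` (for the fold-change node ordering) unless an
#' explicit `order` is given.
#'
#' @param d A [discrete_matrix()].
#' @param algorithm `"k2"`, `"greedy"` or `"aracne"`.
#' @param expr Optional [expression_matrix()] for the K2 node ordering.
#' @param order Optional precomputed [node_order()].
#' @param max_parents Parent bound for `"k2"` / `"greedy"`.
#' @param p_threshold,dpi_tolerance ARACNE parameters.
#' @param score Greedy-search score.
#' @return A [regulatory_network()].
#' @export
infer_network <- function(d, algorithm = c("k2", "greedy", "aracne"),
                          expr = NULL, order = NULL, max_parents = 3L,
                          p_threshold = 1e-7, dpi_tolerance = 0.15,
                          score = "bic") {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         k2 = {
           if (is.null(order)) {
             if (is.null(expr))
               stop("k2 needs `expr` (for the node ordering) or `order`")
             order <- node_order(expr)
           }
           k2(d, order, max_parents)
         },
         greedy = greedy_search(d, score = score, max_parents = max_parents),
         aracne = aracne(d, p_threshold, dpi_tolerance))
}
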