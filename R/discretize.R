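#' Equal-width discretization (EWD)
#'
#' Per gene (row), the range between the row minimum and maximum is split
#' into `k` intervals of equal width `w = (max - min) / k`, with cut points
#' at `min + w, min + 2w, ..., min + (k-1)w`. A value equal to an interior
#' cut point is assigned to the lower interval; the row maximum gets level
#' `k`. A constant row (zero width) is assigned level 1 throughout, with a
#' warning.
#'
#' @param m An [expression_matrix()].
#' @param k Number of intervals, `k >= 2`.
#' @return A [discrete_matrix()] with method tag `"ewd"`.
#' @export
ewd <- function(m, k) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  lv <- t(apply(m, 1L, .ewd_row, k = k))
  dimnames(lv) <- dimnames(m)
  discrete_matrix(lv, k, "ewd")
}

.ewd_row <- function(v, k) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    warning("constant gene row: all values assigned level 1", call. = FALSE)
    return(rep(1L, length(v)))
  }
  w <- (hi - lo) / k
  # ceiling sends values exactly on a cut point to the lower interval;
  # the row minimum (ratio 0) is lifted to level 1, the maximum lands on k.
  lv <- ceiling((v - lo) / w)
  lv[lv < 1L] <- 1L
  lv[lv > k] <- k
  as.integer(lv)
}

#' Equal-frequency discretization (EFD)
#'
#' Per gene (row), the `M` values are stably sorted and split into `k`
#' consecutive intervals containing approximately the same number of values:
#' the first `M %% k` intervals hold `ceiling(M/k)` values, the rest
#' `floor(M/k)`. Ties are kept in stable sort order, so equal values may
#' straddle an interval boundary.
#'
#' @inheritParams ewd
#' @return A [discrete_matrix()] with method tag `"efd"`.
#' @export
efd <- function(m, k) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > ncol(m))
    stop("k (", k, ") exceeds the number of time points (", ncol(m), ")")
  M <- ncol(m)
  sizes <- rep(M %/% k, k)
  sizes[seq_len(M %% k)] <- sizes[seq_len(M %% k)] + 1L
  sorted_levels <- rep.int(seq_len(k), sizes)
  lv <- t(apply(m, 1L, function(v) {
    out <- integer(M)
    out[order(v)] <- sorted_levels  # order() is stable: ties keep position order
    out
  }))
  dimnames(lv) <- dimnames(m)
  discrete_matrix(lv, k, "efd")
}

#' Exact one-dimensional k-means clustering
#'
#' Clusters a numeric vector into `c` contiguous groups minimizing the
#' within-cluster sum of squares. Because optimal 1-D clusters are contiguous
#' intervals of the sorted values, the global optimum is found by dynamic
#' programming over sorted positions; the result is deterministic and the
#' `seed` argument (kept for API uniformity with the matrix-level
#' discretizers) is ignored. Labels are numbered `1..c` by ascending cluster
#' center. If the number of distinct values `d` is smaller than `c`, `d`
#' singleton-value clusters are returned and the solution is flagged
#' degenerate.
#'
#' @param values Numeric vector (at least one value).
#' @param c Number of clusters, `c >= 2`.
#' @param seed Ignored; see Details.
#' @return A list of class `KmeansSolution1D` with elements `labels`
#'   (integer, parallel to `values`), `centers` (strictly increasing cluster
#'   means), `c` (clusters requested), `wcss`, and `degenerate`.
#' @export
kmeans_1d <- function(values, c, seed = NULL) {
  if (length(values) == 0L) stop("empty input to kmeans_1d")
  if (anyNA(values)) stop("missing values in kmeans_1d input")
  c <- as.integer(c)
  if (c < 2L) stop("c must be at least 2")
  ux <- sort(unique(values))
  d <- length(ux)
  degenerate <- d < c
  cc <- min(c, d)
  if (cc == 1L) {
    sol <- list(labels = rep(1L, length(values)), centers = ux[1L],
                c = c, wcss = 0, degenerate = TRUE)
    class(sol) <- "KmeansSolution1D"
    return(sol)
  }
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  # prefix sums for O(1) interval cost: cost(i..j) = sum (x - mean)^2
  cs <- cumsum(x)
  cs2 <- cumsum(x * x)
  segcost <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s * s / (j - i + 1L)
  }
  # D[q, j]: minimal WCSS for first j points in q clusters; B records splits
  D <- matrix(Inf, cc, n)
  B <- matrix(0L, cc, n)
  for (j in seq_len(n)) D[1L, j] <- segcost(1L, j)
  if (cc > 1L) {
    for (q in 2L:cc) {
      for (j in q:n) {
        best <- Inf; bi <- q
        for (i in q:j) {
          v <- D[q - 1L, i - 1L] + segcost(i, j)
          if (v < best) { best <- v; bi <- i }
        }
        D[q, j] <- best
        B[q, j] <- bi
      }
    }
  }
  lab_sorted <- integer(n)
  j <- n
  for (q in cc:1L) {
    i <- if (q == 1L) 1L else B[q, j]
    lab_sorted[i:j] <- q
    j <- i - 1L
  }
  labels <- integer(n)
  labels[ord] <- lab_sorted
  centers <- vapply(seq_len(cc), function(q) mean(x[lab_sorted == q]),
                    numeric(1))
  sol <- list(labels = labels, centers = centers, c = c,
              wcss = D[cc, n], degenerate = degenerate)
  class(sol) <- "KmeansSolution1D"
  sol
}

.kmeans_levels <- function(v, k, what) {
  ux <- unique(v)
  if (length(ux) == 1L) {
    warning("constant ", what, ": all values assigned level 1", call. = FALSE)
    return(rep(1L, length(v)))
  }
  sol <- kmeans_1d(v, k)
  if (sol$degenerate)
    warning("degenerate ", what, ": only ", length(sol$centers),
            " distinct clusters for k = ", k, call. = FALSE)
  sol$labels
}

#' Row k-means discretization
#'
#' Each gene row is clustered into `k` contiguous intervals by exact 1-D
#' k-means ([kmeans_1d()]); level 1 is the lowest-expression cluster.
#' Constant rows get level 1 throughout with a warning; rows with fewer
#' distinct values than `k` use as many levels as there are distinct
#' clusters.
#'
#' @inheritParams ewd
#' @param seed Ignored (the exact 1-D solver is deterministic); kept so all
#'   discretizers share one signature.
#' @return A [discrete_matrix()] with method tag `"kmeans"`.
#' @export
row_kmeans <- function(m, k, seed = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  lv <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m)))
    lv[i, ] <- .kmeans_levels(as.numeric(m[i, ]), k,
                              paste0("gene row '", rownames(m)[i], "'"))
  discrete_matrix(lv, k, "kmeans")
}

#' Column k-means discretization (cokmeans)
#'
#' Each time-point column (one microarray) is clustered into `k` contiguous
#' intervals by exact 1-D k-means; level 1 is the lowest-expression cluster
#' within that column.
#'
#' @inheritParams row_kmeans
#' @return A [discrete_matrix()] with method tag `"cokmeans"`.
#' @export
col_kmeans <- function(m, k, seed = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  lv <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m)))
    lv[, j] <- .kmeans_levels(as.numeric(m[, j]), k,
                              paste0("time column '", colnames(m)[j], "'"))
  discrete_matrix(lv, k, "cokmeans")
}

#' Bidirectional k-means discretization (bikmeans)
#'
#' Row k-means and column k-means are each run with `k + 1` clusters, giving
#' every expression value a row label `r` and a column label `s`. The final
#' level is the integer `x` with `x^2 <= r * s < (x + 1)^2`, i.e.
#' `x = floor(sqrt(r * s))`. The one product outside every such window,
#' `(k + 1)^2` (both labels maximal), is clamped to `k` so levels always lie
#' in `1..k`.
#'
#' @inheritParams row_kmeans
#' @return A [discrete_matrix()] with method tag `"bikmeans"`.
#' @export
bikmeans <- function(m, k, seed = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  r <- row_kmeans(m, k + 1L)
  s <- col_kmeans(m, k + 1L)
  lv <- bikmeans_combine(unclass(r), unclass(s), k)
  dimnames(lv) <- dimnames(m)
  discrete_matrix(lv, k, "bikmeans")
}

#' Combine row and column labels by the bikmeans product rule
#'
#' Exposed separately so the product rule can be checked cell-wise: given row
#' labels and column labels in `1..(k+1)`, the combined level is
#' `floor(sqrt(rowlabel * collabel))`, clamped to `[1, k]`.
#'
#' @param row_labels,col_labels Integer matrices (or scalars) of equal shape.
#' @param k Target number of intervals.
#' @return Integer matrix of levels in `1..k`.
#' @export
bikmeans_combine <- function(row_labels, col_labels, k) {
  p <- as.numeric(row_labels) * as.numeric(col_labels)
  x <- floor(sqrt(p))
  x <- x - (x * x > p)  # guard against floating sqrt overshoot
  x[x < 1] <- 1
  x[x > k] <- k
  out <- as.integer(x)
  if (is.matrix(row_labels)) dim(out) <- dim(row_labels)
  out
}

#' Discretize an expression matrix by a named method
#'
#' Dispatcher over the five discretizers; used by the benchmark driver and
#' the command-line interface.
#'
#' @param m An [expression_matrix()].
#' @param method One of `"ewd"`, `"efd"`, `"kmeans"`, `"cokmeans"`,
#'   `"bikmeans"`.
#' @param k Number of intervals.
#' @param seed Ignored (all methods are deterministic); kept for interface
#'   stability.
#' @return A [discrete_matrix()].
#' @export
discretize <- function(m, method = c("ewd", "efd", "kmeans", "cokmeans",
                                     "bikmeans"), k, seed = NULL) {
  method <- match.arg(method)
  switch(method,
         ewd = ewd(m, k),
         efd = efd(m, k),
         kmeans = row_kmeans(m, k, seed),
         cokmeans = col_kmeans(m, k, seed),
         bikmeans = bikmeans(m, k, seed))
}
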