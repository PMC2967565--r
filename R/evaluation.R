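#' Confusion counts and Sn/Sp/TA for an inferred network
#'
#' Compares an inferred network with the ground truth over a fixed pair
#' universe: all `N(N-1)` ordered gene pairs in directed mode (the default),
#' or all `N(N-1)/2` unordered pairs in undirected mode (where an edge in
#' either direction counts as a prediction of the pair). Self-pairs are
#' excluded. Sensitivity is `Tp / (Tp + Fn)`, specificity `Tn / (Tn + Fp)`
#' and total accuracy `(Tn + Tp) / (Tn + Fn + Tp + Fp)`; a ratio with a zero
#' denominator (e.g. sensitivity when the truth has no edges) is reported as
#' `NA`.
#'
#' @param inferred,truth [regulatory_network()]s over identical gene
#'   universes.
#' @param mode `"directed"` (default) or `"undirected"`.
#' @return A list of class `ConfusionCounts` with integer `tp`, `tn`, `fp`,
#'   `fn` and real `sn`, `sp`, `ta`.
#' @export
confusion <- function(inferred, truth, mode = c("directed", "undirected")) {
  stopifnot(inherits(inferred, "RegulatoryNetwork"),
            inherits(truth, "RegulatoryNetwork"))
  mode <- match.arg(mode)
  if (!identical(inferred$genes, truth$genes))
    stop("gene universes differ between inferred and truth networks")
  N <- length(truth$genes)
  pair_universe <- if (mode == "directed") N * (N - 1L) else (N * (N - 1L)) %/% 2L
  key <- function(net) {
    e <- net$edges
    if (nrow(e) == 0L) return(character(0))
    if (mode == "undirected") {
      lo <- pmin(e[, 1L], e[, 2L]); hi <- pmax(e[, 1L], e[, 2L])
      unique(paste(lo, hi, sep = "\r"))
    } else paste(e[, 1L], e[, 2L], sep = "\r")
  }
  ki <- key(inferred); kt <- key(truth)
  tp <- length(intersect(ki, kt))
  fp <- length(setdiff(ki, kt))
  fn <- length(setdiff(kt, ki))
  tn <- pair_universe - tp - fp - fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sn = ratio(tp, tp + fn), sp = ratio(tn, tn + fp),
                 ta = ratio(tn + tp, pair_universe),
                 mode = mode, pair_universe = pair_universe),
            class = "ConfusionCounts")
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("ConfusionCounts (%s): Tp=%d Tn=%d Fp=%d Fn=%d\n",
              x$mode, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  Sn=%.4f Sp=%.4f TA=%.4f\n", x$sn, x$sp, x$ta))
  invisible(x)
}

#' File-level evaluation wrapper
#'
#' Reads an inferred and a true network, computes [confusion()] and
#' optionally writes a one-row TSV report.
#'
#' @param inferred_path,truth_path Network files readable by
#'   [read_network()].
#' @param mode Passed to [confusion()].
#' @param out Optional report path.
#' @param genes Optional shared gene universe (defaults to the union of both
#'   files' endpoints).
#' @return The [confusion()] result, invisibly if `out` is given.
#' @export
evaluate_run <- function(inferred_path, truth_path,
                         mode = c("directed", "undirected"), out = NULL,
                         genes = NULL) {
  mode <- match.arg(mode)
  if (is.null(genes)) {
    g1 <- tryCatch(read_network(inferred_path)$genes, error = function(e) character(0))
    g2 <- read_network(truth_path)$genes
    genes <- union(g1, g2)
  }
  inferred <- read_network(inferred_path, genes = genes)
  truth <- read_network(truth_path, genes = genes)
  cc <- confusion(inferred, truth, mode)
  if (!is.null(out)) {
    df <- data.frame(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
                     sn = cc$sn, sp = cc$sp, ta = cc$ta, mode = cc$mode)
    utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(cc))
  }
  cc
}
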