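#' Construct a directed regulatory network
#'
#' A `RegulatoryNetwork` is a set of directed regulator -> target edges over a
#' gene universe. Self-loops are rejected and duplicate edges collapsed; the
#' edge set is kept lexicographically sorted so that equal networks compare
#' and serialize identically.
#'
#' @param genes Character vector, the gene universe.
#' @param edges Two-column character matrix or data frame
#'   (regulator, target); may have zero rows.
#' @return An object of class `RegulatoryNetwork` with elements `genes`
#'   (sorted unique) and `edges` (two-column character matrix).
#' @examples
#' regulatory_network(c("A", "B", "C"), rbind(c("A", "B")))
#' @export
regulatory_network <- function(genes, edges = NULL) {
  genes <- sort(unique(as.character(genes)))
  if (length(genes) < 1L) stop("gene universe is empty")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    storage.mode(edges) <- "character"
  }
  if (nrow(edges) > 0L) {
    if (any(edges[, 1L] == edges[, 2L])) {
      i <- which(edges[, 1L] == edges[, 2L])[1L]
      stop("self-loop not allowed: ", edges[i, 1L], " -> ", edges[i, 2L])
    }
    missing <- setdiff(c(edges), genes)
    if (length(missing) > 0L)
      stop("edge endpoint(s) outside the gene universe: ",
           paste(missing, collapse = ", "))
    key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  colnames(edges) <- c("regulator", "target")
  structure(list(genes = genes, edges = edges), class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d genes, %d directed edges\n",
              length(x$genes), nrow(x$edges)))
  if (nrow(x$edges) > 0L)
    cat(paste0("  ", utils::head(x$edges[, 1L], 5L), " -> ",
               utils::head(x$edges[, 2L], 5L), collapse = "\n"), "\n")
  invisible(x)
}

#' Number of edges in a network
#' @param n A [regulatory_network()].
#' @export
n_edges <- function(n) nrow(n$edges)

edge_keys <- function(n) {
  if (nrow(n$edges) == 0L) character(0)
  else paste(n$edges[, 1L], n$edges[, 2L], sep = "\r")
}

#' Read a directed network from a TSV or SIF edge list
#'
#' Two dialects are accepted and auto-detected per line count of fields:
#' two-column TSV `regulator<TAB>target` (an optional `regulator target`
#' header line is skipped), and three-column SIF
#' `regulator<TAB>interaction<TAB>target`.
#'
#' @param path File path.
#' @param genes Optional gene universe; defaults to the union of edge
#'   endpoints. Supply it to keep isolated genes in the universe.
#' @return A [regulatory_network()].
#' @export
read_network <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L && identical(tolower(strsplit(lines[1L], "\t")[[1L]][1L]),
                                      "regulator"))
    lines <- lines[-1L]
  edges <- matrix(character(0), ncol = 2L)
  if (length(lines) > 0L) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(!(nf %in% c(2L, 3L)))
    if (length(bad) > 0L)
      stop(sprintf("malformed line %d: expected 2 (TSV) or 3 (SIF) fields, got %d",
                   bad[1L], nf[bad[1L]]))
    edges <- t(vapply(parts, function(p)
      if (length(p) == 2L) p else p[c(1L, 3L)], character(2L)))
    loops <- which(edges[, 1L] == edges[, 2L])
    if (length(loops) > 0L)
      stop(sprintf("self-loop at line %d: %s", loops[1L], lines[loops[1L]]))
  }
  if (is.null(genes)) genes <- unique(c(edges))
  if (length(genes) == 0L) stop("empty network file and no gene universe given")
  regulatory_network(genes, edges)
}

#' Write a directed network as a TSV or SIF edge list
#'
#' Edges are written in lexicographic (regulator, target) order. The SIF
#' interaction type is `regulates`. An empty network produces a header-only
#' TSV file (or an empty SIF file).
#'
#' @param n A [regulatory_network()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @export
write_network <- function(n, path, format = c("tsv", "sif")) {
  stopifnot(inherits(n, "RegulatoryNetwork"))
  format <- match.arg(format)
  e <- n$edges
  if (format == "tsv") {
    lines <- c("regulator\ttarget",
               if (nrow(e) > 0L) paste(e[, 1L], e[, 2L], sep = "\t"))
  } else {
    lines <- if (nrow(e) > 0L)
      paste(e[, 1L], "regulates", e[, 2L], sep = "\t") else character(0)
  }
  writeLines(lines, path)
  invisible(path)
}
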