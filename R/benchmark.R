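#' Run the discretizer x algorithm x interval-count benchmark
#'
#' For every combination of dataset, algorithm, discretizer and interval
#' count, the expression matrix is discretized, a network is inferred and
#' compared with the dataset's ground truth, and one long-format record
#' (dataset id, algorithm, k, discretizer, Tp/Tn/Fp/Fn, Sn, Sp, TA) is
#' emitted. Failures and degenerate-discretization warnings never abort the
#' sweep: they are recorded in the `warnings` column, and a failed cell gets
#' missing metrics. K2/greedy predictions are evaluated as directed edges;
#' ARACNE's undirected predictions are expanded to both directions and
#' evaluated over the same directed pair universe (the `eval_mode` column
#' records this).
#'
#' @param suite A `SimSuite` from [simulate_suite()] /
#'   [read_benchmark_suite()], or a list of `list(dataset_id, expression,
#'   network)` entries.
#' @param algorithms Character subset of `c("k2", "greedy", "aracne")`.
#' @param discretizers Character subset of
#'   `c("ewd", "efd", "kmeans", "cokmeans", "bikmeans")`.
#' @param ks Integer vector of interval counts (default `c(2, 3, 4)`).
#' @param max_parents,p_threshold,dpi_tolerance Inference parameters, see
#'   [infer_network()].
#' @return A `data.frame` of `BenchmarkRecord` rows, one per design cell per
#'   dataset.
#' @export
run_benchmark <- function(suite,
                          algorithms = c("k2", "greedy", "aracne"),
                          discretizers = c("ewd", "efd", "kmeans",
                                           "cokmeans", "bikmeans"),
                          ks = c(2L, 3L, 4L), max_parents = 3L,
                          p_threshold = 1e-7, dpi_tolerance = 0.15) {
  if (length(suite) == 0L) stop("empty dataset suite")
  if (length(algorithms) == 0L || length(discretizers) == 0L ||
      length(ks) == 0L)
    stop("empty design axis")
  algorithms <- match.arg(algorithms, c("k2", "greedy", "aracne"),
                          several.ok = TRUE)
  discretizers <- match.arg(discretizers,
                            c("ewd", "efd", "kmeans", "cokmeans", "bikmeans"),
                            several.ok = TRUE)
  rows <- list()
  for (ds in suite) {
    expr <- ds$expression
    truth <- ds$network
    ord <- if ("k2" %in% algorithms) node_order(expr) else NULL
    for (disc in discretizers) {
      for (k in ks) {
        warn <- character(0)
        dmat <- withCallingHandlers(
          tryCatch(discretize(expr, disc, k), error = function(e) e),
          warning = function(w) {
            warn <<- c(warn, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        for (alg in algorithms) {
          rec <- list(dataset_id = ds$dataset_id, algorithm = alg,
                      k = as.integer(k), discretizer = disc,
                      tp = NA_integer_, tn = NA_integer_, fp = NA_integer_,
                      fn = NA_integer_, sn = NA_real_, sp = NA_real_,
                      ta = NA_real_, eval_mode = "directed",
                      warnings = paste(unique(warn), collapse = "; "))
          if (!inherits(dmat, "error")) {
            res <- tryCatch({
              net <- infer_network(dmat, alg, expr = expr, order = ord,
                                   max_parents = max_parents,
                                   p_threshold = p_threshold,
                                   dpi_tolerance = dpi_tolerance)
              confusion(net, truth, mode = "directed")
            }, error = function(e) e)
            if (inherits(res, "error")) {
              rec$warnings <- paste(c(rec$warnings[nzchar(rec$warnings)],
                                      conditionMessage(res)), collapse = "; ")
            } else {
              rec[c("tp", "tn", "fp", "fn")] <- res[c("tp", "tn", "fp", "fn")]
              rec[c("sn", "sp", "ta")] <- res[c("sn", "sp", "ta")]
            }
          } else {
            rec$warnings <- paste(c(rec$warnings[nzchar(rec$warnings)],
                                    conditionMessage(dmat)), collapse = "; ")
          }
          rows[[length(rows) + 1L]] <- rec
        }
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

.balanced_check <- function(records, response) {
  need <- c("algorithm", "k", "discretizer", response)
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  y <- records[[response]]
  if (anyNA(y)) {
    keep_ds <- !(records$dataset_id %in%
                   unique(records$dataset_id[is.na(y)]))
    if (!any(keep_ds))
      stop("all datasets have missing responses")
    warning(sum(!keep_ds & !duplicated(records$dataset_id)),
            " dataset(s) dropped listwise for missing responses",
            call. = FALSE)
    records <- records[keep_ds, , drop = FALSE]
  }
  cells <- table(records$algorithm, records$k, records$discretizer)
  if (length(unique(as.vector(cells))) != 1L || any(cells == 0L))
    stop("unbalanced design: unequal cell counts; balanced ANOVA requires ",
         "a complete equally-replicated design")
  records
}

#' Balanced three-way ANOVA of a benchmark response
#'
#' Fixed-effects analysis of variance of `ta` (or `sn` / `sp`) with the model
#' `algorithm + k + discretizer` plus all two-way interactions and no
#' three-way term; the three-way interaction is pooled into error. Sums of
#' squares use the standard balanced-design decomposition over cell means, so
#' the design must be complete with equal replication (datasets with missing
#' responses are dropped listwise with a warning). F statistics are
#' `MS(term) / MS(Error)`; p-values come from the F distribution.
#'
#' @param records Benchmark table from [run_benchmark()].
#' @param response `"ta"` (default), `"sn"` or `"sp"`.
#' @param three_way Include the three-way interaction as a model term instead
#'   of pooling it into error (default FALSE, matching the reduced model).
#' @return A `data.frame` of class `AnovaTable` with columns `term`,
#'   `sum_sq`, `df`, `mean_sq`, `f`, `p`; terms are S1 = algorithm,
#'   S2 = interval count, S3 = discretizer, their two-way interactions,
#'   `Error` and `Total`.
#' @export
anova3 <- function(records, response = c("ta", "sn", "sp"),
                   three_way = FALSE) {
  response <- match.arg(response)
  records <- .balanced_check(records, response)
  y <- records[[response]]
  A <- factor(records$algorithm)
  B <- factor(records$k)
  C <- factor(records$discretizer)
  n <- length(y)
  gm <- mean(y)
  ss_total <- sum((y - gm)^2)
  mean_by <- function(...) tapply(y, list(...), mean)
  cnt_by <- function(...) tapply(y, list(...), length)
  ss_main <- function(f) sum(cnt_by(f) * (mean_by(f) - gm)^2)
  ss_two <- function(f, g) {
    mab <- mean_by(f, g)
    eff <- sweep(sweep(mab, 1L, mean_by(f) - gm, `-`), 2L, mean_by(g) - gm,
                 `-`) - gm
    sum(cnt_by(f, g) * eff^2)
  }
  ss <- c(S1 = ss_main(A), S2 = ss_main(B), S3 = ss_main(C),
          `S1*S2` = ss_two(A, B), `S1*S3` = ss_two(A, C),
          `S2*S3` = ss_two(B, C))
  df <- c(nlevels(A) - 1L, nlevels(B) - 1L, nlevels(C) - 1L,
          (nlevels(A) - 1L) * (nlevels(B) - 1L),
          (nlevels(A) - 1L) * (nlevels(C) - 1L),
          (nlevels(B) - 1L) * (nlevels(C) - 1L))
  if (three_way) {
    mabc <- mean_by(A, B, C)
    # three-way effect = cell mean minus the additive + two-way reconstruction
    abc_eff <- mabc
    ma <- mean_by(A); mb <- mean_by(B); mc <- mean_by(C)
    mab <- mean_by(A, B); mac <- mean_by(A, C); mbc <- mean_by(B, C)
    for (a in seq_len(nlevels(A)))
      for (b in seq_len(nlevels(B)))
        for (cc in seq_len(nlevels(C)))
          abc_eff[a, b, cc] <- mabc[a, b, cc] - mab[a, b] - mac[a, cc] -
            mbc[b, cc] + ma[a] + mb[b] + mc[cc] - gm
    ss <- c(ss, `S1*S2*S3` = sum(cnt_by(A, B, C) * abc_eff^2))
    df <- c(df, (nlevels(A) - 1L) * (nlevels(B) - 1L) * (nlevels(C) - 1L))
  }
  ss_err <- ss_total - sum(ss)
  df_err <- (n - 1L) - sum(df)
  ms <- ss / df
  ms_err <- ss_err / df_err
  fstat <- if (ms_err > 0) ms / ms_err else rep(NA_real_, length(ms))
  pval <- if (ms_err > 0) stats::pf(fstat, df, df_err, lower.tail = FALSE)
          else rep(NA_real_, length(ms))
  out <- data.frame(
    term = c(names(ss), "Error", "Total"),
    sum_sq = c(ss, ss_err, ss_total),
    df = c(df, df_err, n - 1L),
    mean_sq = c(ms, ms_err, NA_real_),
    f = c(fstat, NA_real_, NA_real_),
    p = c(pval, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "response") <- response
  class(out) <- c("AnovaTable", class(out))
  out
}

#' Tukey-Kramer comparison of design-cell marginal means
#'
#' Computes the mean response of every (algorithm, k, discretizer) cell with
#' simultaneous Tukey-Kramer confidence half-widths based on the error mean
#' square of [anova3()], flags the cells significantly different from a
#' reference cell, and ranks cells by mean response (the `top` column marks
#' the `n_top` best cells).
#'
#' @inheritParams anova3
#' @param alpha Simultaneous error rate (default 0.05).
#' @param reference_cell Length-3 character vector
#'   `c(algorithm, k, discretizer)`; default `c("greedy", "3", "bikmeans")`.
#' @param n_top Number of top-ranked cells to mark (default 12).
#' @return A `data.frame` with one row per cell: factors, `n`, `mean`,
#'   `halfwidth` (for a difference of two cell means), `diff_from_ref`,
#'   `significant`, `rank`, `top`.
#' @export
marginal_means_comparison <- function(records, response = c("ta", "sn", "sp"),
                                      alpha = 0.05,
                                      reference_cell = c("greedy", "3",
                                                         "bikmeans"),
                                      n_top = 12L) {
  response <- match.arg(response)
  records <- .balanced_check(records, response)
  an <- suppressWarnings(anova3(records, response))
  ms_err <- an$mean_sq[an$term == "Error"]
  df_err <- an$df[an$term == "Error"]
  y <- records[[response]]
  cell <- interaction(records$algorithm, records$k, records$discretizer,
                      sep = "|", drop = TRUE)
  means <- tapply(y, cell, mean)
  ns <- tapply(y, cell, length)
  labels <- do.call(rbind, strsplit(names(means), "|", fixed = TRUE))
  out <- data.frame(algorithm = labels[, 1L], k = labels[, 2L],
                    discretizer = labels[, 3L], n = as.integer(ns),
                    mean = as.numeric(means), stringsAsFactors = FALSE)
  ref_key <- paste(reference_cell, collapse = "|")
  ref_i <- match(ref_key, names(means))
  if (is.na(ref_i))
    stop("reference cell not present in the design: ", ref_key)
  q_crit <- stats::qtukey(1 - alpha, nmeans = length(means), df = df_err)
  out$halfwidth <- q_crit / sqrt(2) *
    sqrt(ms_err * (1 / out$n + 1 / out$n[ref_i]))
  out$diff_from_ref <- out$mean - out$mean[ref_i]
  out$significant <- abs(out$diff_from_ref) > out$halfwidth
  out$significant[ref_i] <- FALSE
  out$rank <- rank(-out$mean, ties.method = "min")
  out$top <- out$rank <= n_top
  out[order(-out$mean), ]
}

#' Per-cell summary of a benchmark table
#'
#' Group means and standard deviations of Sn, Sp and TA by
#' (algorithm, discretizer, k). Optionally writes scatter plots of
#' (Sn, TA) and (Sp, TA) coloured by discretizer.
#'
#' @param records Benchmark table from [run_benchmark()].
#' @param plot_file Optional PDF path for the two scatter plots.
#' @return A `data.frame` with one row per design cell.
#' @export
summarize_benchmark <- function(records, plot_file = NULL) {
  cell <- interaction(records$algorithm, records$discretizer, records$k,
                      sep = "|", drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, cell, f, simplify = TRUE))
  labels <- do.call(rbind, strsplit(levels(cell), "|", fixed = TRUE))
  out <- data.frame(
    algorithm = labels[, 1L], discretizer = labels[, 2L],
    k = as.integer(labels[, 3L]),
    n = as.integer(table(cell)),
    sn_mean = agg(records$sn, function(x) mean(x, na.rm = TRUE)),
    sn_sd = agg(records$sn, function(x) stats::sd(x[!is.na(x)])),
    sp_mean = agg(records$sp, function(x) mean(x, na.rm = TRUE)),
    sp_sd = agg(records$sp, function(x) stats::sd(x[!is.na(x)])),
    ta_mean = agg(records$ta, function(x) mean(x, na.rm = TRUE)),
    ta_sd = agg(records$ta, function(x) stats::sd(x[!is.na(x)])),
    stringsAsFactors = FALSE)
  if (!is.null(plot_file)) {
    grDevices::pdf(plot_file, width = 10, height = 5)
    on.exit(grDevices::dev.off())
    disc <- factor(records$discretizer)
    graphics::par(mfrow = c(1, 2))
    graphics::plot(records$sn, records$ta, col = as.integer(disc), pch = 16,
                   xlab = "Sensitivity", ylab = "Total accuracy",
                   main = "Sn vs TA")
    graphics::legend("bottomright", legend = levels(disc), pch = 16,
                     col = seq_len(nlevels(disc)), cex = 0.7)
    graphics::plot(records$sp, records$ta, col = as.integer(disc), pch = 16,
                   xlab = "Specificity", ylab = "Total accuracy",
                   main = "Sp vs TA")
  }
  out
}
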