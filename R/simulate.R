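#' Configuration for the synthetic time-course simulator
#'
#' The simulator is a parametric stand-in for benchmark suites built by
#' resampling real yeast time-course microarray data: it draws a ground-truth
#' directed acyclic regulatory network and generates a positive expression
#' matrix in which each target gene follows a lagged, saturating function of
#' its regulators plus Gaussian noise. Defaults match the benchmark shape of
#' 100 datasets of 50 genes x 25 time points.
#'
#' @param n_genes Number of genes (>= 2). Default 50.
#' @param n_timepoints Number of time points (>= 3). Default 25.
#' @param n_datasets Number of datasets in a suite. Default 100.
#' @param n_edges Number of directed edges in the ground-truth network.
#'   Default 60 (sparse, roughly one regulation per gene, typical of curated
#'   yeast subnetworks).
#' @param regulator_fraction Fraction of genes eligible as regulators
#'   (sources of edges). Default 0.2.
#' @param lag Regulatory time lag in time steps. Default 1.
#' @param effect_size Scale of the regulator effect on the log-expression of
#'   its targets. Default 1.
#' @param noise_sd Standard deviation of Gaussian noise on log-expression.
#'   Default 0.2.
#' @param baseline Multiplicative baseline expression level (arbitrary
#'   units, positive). Default 100.
#' @param acyclic Keep the ground truth a DAG (default TRUE); set FALSE to
#'   allow feedback cycles for mutual-information-only studies.
#' @param seed Master seed; all randomness in a suite derives from it.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 50L, n_timepoints = 25L, n_datasets = 100L,
                       n_edges = 60L, regulator_fraction = 0.2, lag = 1L,
                       effect_size = 1, noise_sd = 0.2, baseline = 100,
                       acyclic = TRUE, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_timepoints = as.integer(n_timepoints),
              n_datasets = as.integer(n_datasets),
              n_edges = as.integer(n_edges),
              regulator_fraction = regulator_fraction,
              lag = as.integer(lag), effect_size = effect_size,
              noise_sd = noise_sd, baseline = baseline,
              acyclic = isTRUE(acyclic), seed = as.integer(seed))
  if (cfg$n_genes < 2L) stop("n_genes must be at least 2")
  if (cfg$n_timepoints < 3L) stop("n_timepoints must be at least 3")
  if (cfg$n_edges < 1L) stop("n_edges must be at least 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$baseline <= 0) stop("baseline must be positive")
  if (cfg$regulator_fraction <= 0 || cfg$regulator_fraction > 1)
    stop("regulator_fraction must be in (0, 1]")
  if (cfg$lag < 0L || cfg$lag >= cfg$n_timepoints)
    stop("lag must be in [0, n_timepoints)")
  class(cfg) <- "SimConfig"
  cfg
}

.sim_gene_ids <- function(n) sprintf("G%03d", seq_len(n))

#' Simulate a ground-truth regulatory network
#'
#' Genes are placed in a random topological order; the first
#' `ceiling(regulator_fraction * n_genes)` genes in that order are eligible
#' regulators. Each regulator receives a heavy-tailed (Pareto-like) weight
#' and `n_edges` regulator -> downstream-gene pairs are sampled without
#' replacement with probability proportional to the regulator weight, so
#' out-degrees are heavy-tailed while the network stays acyclic (every edge
#' points forward in the hidden order). With `acyclic = FALSE` edges are
#' sampled from all ordered pairs instead.
#'
#' @param cfg A [sim_config()].
#' @return A [regulatory_network()] with exactly `cfg$n_edges` edges.
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  n <- cfg$n_genes
  genes <- .sim_gene_ids(n)
  topo <- sample(genes)
  n_reg <- max(1L, ceiling(cfg$regulator_fraction * n))
  regulators <- topo[seq_len(min(n_reg, n - 1L))]
  # eligible pairs: regulator -> any gene later in the topological order
  reg_pos <- match(regulators, topo)
  if (cfg$acyclic) {
    pairs <- do.call(rbind, lapply(seq_along(regulators), function(i) {
      after <- topo[seq_len(n) > reg_pos[i]]
      if (length(after) == 0L) NULL else cbind(regulators[i], after)
    }))
  } else {
    pairs <- as.matrix(expand.grid(regulators, genes,
                                   stringsAsFactors = FALSE))
    pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  }
  if (cfg$n_edges > nrow(pairs))
    stop("n_edges (", cfg$n_edges, ") exceeds the ", nrow(pairs),
         " eligible regulator-target pairs")
  w_reg <- (1 - stats::runif(length(regulators)))^(-1 / 2.5)  # Pareto(2.5)
  prob <- w_reg[match(pairs[, 1L], regulators)]
  take <- sample.int(nrow(pairs), cfg$n_edges, prob = prob)
  regulatory_network(genes, pairs[take, , drop = FALSE])
}

#' Simulate a time-course expression matrix for a known network
#'
#' Regulator-free genes follow smooth positive trajectories: a Gaussian
#' random walk on the log scale, smoothed with a short moving average and
#' scaled by a lognormal per-gene amplitude (genes differ widely in dynamic
#' range, as in real time-course data).
#' Each target gene's log-expression at time `t` is
#' `effect_size * tanh(mean of its regulators' centered log-expression at
#' t - lag)` plus Gaussian noise of sd `noise_sd`; before the lag has
#' elapsed targets sit at their baseline plus noise. Expression is
#' `baseline * exp(log-signal)`, hence strictly positive, and fold changes
#' relative to the first time point are well defined.
#'
#' @param net A [regulatory_network()] over the config's gene universe.
#' @param cfg A [sim_config()].
#' @return An [expression_matrix()] of dimension `n_genes x n_timepoints`.
#' @export
simulate_expression <- function(net, cfg) {
  stopifnot(inherits(net, "RegulatoryNetwork"), inherits(cfg, "SimConfig"))
  genes <- net$genes
  n <- length(genes)
  M <- cfg$n_timepoints
  if (n != cfg$n_genes)
    stop("network gene universe does not match cfg$n_genes")
  parents <- split(net$edges[, 1L], factor(net$edges[, 2L], levels = genes))
  z <- matrix(0, n, M, dimnames = list(genes, NULL))
  # smooth source trajectories: moving-average-smoothed random walk with a
  # heterogeneous per-gene amplitude (real profiles differ widely in range)
  smooth_curve <- function() {
    amp <- stats::rlnorm(1L, meanlog = 0, sdlog = 0.5)
    steps <- stats::rnorm(M + 4L, sd = 0.6)
    walk <- cumsum(steps)
    sm <- stats::filter(walk, rep(1 / 5, 5L), sides = 2L)
    sm <- sm[!is.na(sm)][seq_len(M)]
    amp * as.numeric(sm - mean(sm))
  }
  # evaluation order: sources first, then targets whose parents are done;
  # with a cyclic truth, unresolved genes fall back to source behaviour.
  done <- logical(n); names(done) <- genes
  force_source <- FALSE
  while (any(!done)) {
    progressed <- FALSE
    for (g in genes[!done]) {
      pa <- parents[[g]]
      if (length(pa) == 0L || force_source) {
        z[g, ] <- smooth_curve() + stats::rnorm(M, sd = cfg$noise_sd)
      } else if (all(done[pa])) {
        drive <- colMeans(z[pa, , drop = FALSE])
        zt <- numeric(M)
        lagged <- seq_len(M) - cfg$lag
        zt[lagged >= 1L] <- cfg$effect_size * tanh(drive[lagged[lagged >= 1L]])
        z[g, ] <- zt + stats::rnorm(M, sd = cfg$noise_sd)
      } else {
        next
      }
      done[g] <- TRUE
      progressed <- TRUE
    }
    # a pass with no progress means a feedback cycle: break it by treating
    # the remaining genes as autonomous sources
    if (!progressed) force_source <- TRUE
  }
  expression_matrix(cfg$baseline * exp(z), genes,
                    paste0("T", seq_len(M)))
}

#' Simulate a suite of (expression matrix, true network) dataset pairs
#'
#' Per-dataset seeds are drawn once from the master seed (`sample.int` on the
#' full integer range), so any single dataset can be regenerated bit-exactly
#' from its recorded seed without replaying the whole suite.
#'
#' @param cfg A [sim_config()].
#' @param n_datasets Number of pairs; defaults to `cfg$n_datasets`.
#' @return A list of class `SimSuite`: elements are lists with `expression`,
#'   `network`, `seed`, `dataset_id`.
#' @export
simulate_suite <- function(cfg, n_datasets = cfg$n_datasets) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, n_datasets)
  suite <- lapply(seq_len(n_datasets), function(i) {
    set.seed(seeds[i])
    net <- simulate_network(cfg)
    expr <- simulate_expression(net, cfg)
    list(dataset_id = sprintf("D%03d", i), seed = seeds[i],
         expression = expr, network = net)
  })
  class(suite) <- "SimSuite"
  suite
}

#' Write a simulated benchmark suite to disk
#'
#' Writes one expression TSV and one network TSV per dataset plus a
#' `manifest.tsv` (dataset id, per-dataset seed, file names) that allows
#' bit-exact regeneration.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest data frame.
#' @export
generate_benchmark_suite <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "SimConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  suite <- simulate_suite(cfg)
  manifest <- data.frame(
    dataset_id = vapply(suite, `[[`, character(1), "dataset_id"),
    seed = vapply(suite, `[[`, integer(1), "seed"),
    expression_file = paste0(vapply(suite, `[[`, character(1), "dataset_id"),
                             "_expr.tsv"),
    network_file = paste0(vapply(suite, `[[`, character(1), "dataset_id"),
                          "_net.tsv"),
    stringsAsFactors = FALSE)
  for (i in seq_along(suite)) {
    write_expression(suite[[i]]$expression,
                     file.path(out_dir, manifest$expression_file[i]))
    write_network(suite[[i]]$network,
                  file.path(out_dir, manifest$network_file[i]))
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Load a benchmark suite written by [generate_benchmark_suite()]
#'
#' @param dir Directory containing `manifest.tsv`.
#' @return A `SimSuite` list as from [simulate_suite()].
#' @export
read_benchmark_suite <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  suite <- lapply(seq_len(nrow(manifest)), function(i) {
    expr <- read_expression(file.path(dir, manifest$expression_file[i]))
    net <- read_network(file.path(dir, manifest$network_file[i]),
                        genes = rownames(expr))
    list(dataset_id = manifest$dataset_id[i], seed = manifest$seed[i],
         expression = expr, network = net)
  })
  class(suite) <- "SimSuite"
  suite
}
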