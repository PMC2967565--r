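# small suite shared by the benchmark tests (tiny for speed)
local_mini_suite <- function(n_datasets = 2L, seed = 42L) {
  cfg <- sim_config(n_genes = 10L, n_timepoints = 12L,
                    n_datasets = n_datasets, n_edges = 8L,
                    regulator_fraction = 0.4, seed = seed)
  simulate_suite(cfg)
}

test_that("run_benchmark emits one record per design cell per dataset", {
  suite <- local_mini_suite(2L)
  rec <- run_benchmark(suite, ks = c(2L, 3L, 4L))
  expect_equal(nrow(rec), 2L * 3L * 5L * 3L)
  expect_setequal(unique(rec$algorithm), c("k2", "greedy", "aracne"))
  expect_setequal(unique(rec$discretizer),
                  c("ewd", "efd", "kmeans", "cokmeans", "bikmeans"))
  expect_true(all(rec$ta[!is.na(rec$ta)] >= 0 & rec$ta[!is.na(rec$ta)] <= 1))
  expect_true(all(rec$tp + rec$tn + rec$fp + rec$fn == 10L * 9L,
                  na.rm = TRUE))
  # determinism: same suite, same table
  rec2 <- run_benchmark(local_mini_suite(2L), ks = c(2L, 3L, 4L))
  expect_identical(rec, rec2)
  expect_error(run_benchmark(suite, ks = integer(0)), "empty design axis")
})

test_that("anova3 reproduces textbook sums of squares on a known model", {
  set.seed(1)
  levsA <- c("k2", "greedy", "aracne")
  levsB <- c("2", "3", "4")
  levsC <- c("ewd", "efd", "kmeans", "cokmeans", "bikmeans")
  r <- 6L
  grid <- expand.grid(algorithm = levsA, k = levsB, discretizer = levsC,
                      rep = seq_len(r), stringsAsFactors = FALSE)
  effA <- c(k2 = 0.02, greedy = -0.01, aracne = -0.01)
  effC <- c(ewd = 0, efd = 0.01, kmeans = -0.01, cokmeans = 0, bikmeans = 0.03)
  grid$ta <- 0.9 + effA[grid$algorithm] + effC[grid$discretizer] +
    rnorm(nrow(grid), sd = 0.01)
  grid$dataset_id <- paste0("D", grid$rep)
  an <- anova3(grid)

  # cross-check every term against stats::aov on the same reduced model
  fit <- stats::aov(ta ~ (factor(algorithm) + factor(k) +
                            factor(discretizer))^2, data = grid)
  ref <- summary(fit)[[1]]
  ref_ss <- ref[["Sum Sq"]]
  ord <- c("S1", "S2", "S3", "S1*S2", "S1*S3", "S2*S3", "Error")
  got <- an$sum_sq[match(ord, an$term)]
  expect_equal(got, ref_ss, tolerance = 1e-8)
  expect_equal(an$df[match(ord, an$term)], ref[["Df"]])
  expect_equal(an$p[match(ord[1:6], an$term)],
               ref[["Pr(>F)"]][1:6], tolerance = 1e-8)
  # decomposition sums to the total
  expect_equal(sum(an$sum_sq[an$term != "Total"]),
               an$sum_sq[an$term == "Total"], tolerance = 1e-10)
})

test_that("anova3 degrees of freedom follow the balanced-design identity", {
  for (dims in list(c(3L, 3L, 5L, 4L), c(2L, 4L, 3L, 5L))) {
    a <- dims[1]; b <- dims[2]; cc <- dims[3]; r <- dims[4]
    grid <- expand.grid(algorithm = paste0("A", 1:a), k = paste0("B", 1:b),
                        discretizer = paste0("C", 1:cc), rep = 1:r,
                        stringsAsFactors = FALSE)
    set.seed(2)
    grid$ta <- runif(nrow(grid))
    an <- anova3(grid)
    expect_equal(an$df[an$term == "Total"], a * b * cc * r - 1L)
    expect_equal(an$df[an$term == "Error"],
                 a * b * cc * r - 1L -
                   ((a - 1) + (b - 1) + (cc - 1) + (a - 1) * (b - 1) +
                      (a - 1) * (cc - 1) + (b - 1) * (cc - 1)))
    expect_equal(sum(an$df[an$term != "Total"]), an$df[an$term == "Total"])
  }
})

test_that("anova3 handles zero variance and rejects unbalanced designs", {
  grid <- expand.grid(algorithm = c("a", "b"), k = c("2", "3"),
                      discretizer = c("x", "y"), rep = 1:3,
                      stringsAsFactors = FALSE)
  grid$ta <- 0.5
  an <- anova3(grid)
  expect_true(all(is.na(an$f[1:6])))
  expect_equal(an$sum_sq[an$term == "Total"], 0)

  unb <- grid[-1, ]
  expect_error(anova3(unb), "unbalanced")
})

test_that("marginal means comparison flags a shifted cell against all others", {
  grid <- expand.grid(algorithm = c("k2", "greedy"), k = c("2", "3"),
                      discretizer = c("ewd", "bikmeans"), rep = 1:10,
                      stringsAsFactors = FALSE)
  set.seed(3)
  grid$ta <- 0.8 + rnorm(nrow(grid), sd = 0.01)
  shift <- grid$algorithm == "greedy" & grid$k == "3" &
    grid$discretizer == "bikmeans"
  grid$ta[shift] <- grid$ta[shift] + 0.1  # +10 sd
  cmp <- marginal_means_comparison(grid, reference_cell = c("greedy", "3",
                                                            "bikmeans"))
  expect_equal(nrow(cmp), 8L)
  ref_row <- cmp$algorithm == "greedy" & cmp$k == "3" &
    cmp$discretizer == "bikmeans"
  expect_false(cmp$significant[ref_row])
  expect_true(all(cmp$significant[!ref_row]))
  expect_equal(cmp$rank[ref_row], 1L)

  # all-equal responses: nothing significant
  grid$ta <- 0.8
  cmp0 <- suppressWarnings(marginal_means_comparison(
    grid, reference_cell = c("k2", "2", "ewd")))
  expect_false(any(cmp0$significant, na.rm = TRUE))
  expect_error(marginal_means_comparison(grid,
                                         reference_cell = c("zz", "9", "qq")),
               "reference cell")
})

test_that("summarize_benchmark reduces to per-cell means and sds", {
  rec <- data.frame(
    dataset_id = rep(c("D1", "D2"), 3),
    algorithm = rep("k2", 6), k = rep(3L, 6),
    discretizer = rep(c("ewd", "efd", "bikmeans"), each = 2),
    sn = c(0.1, 0.3, 0.2, 0.2, 0.5, 0.7),
    sp = c(0.9, 0.7, 0.8, 0.8, 0.95, 0.85),
    ta = c(0.8, 0.6, 0.7, 0.7, 0.9, 0.8))
  s <- summarize_benchmark(rec)
  expect_equal(nrow(s), 3L)
  bik <- s[s$discretizer == "bikmeans", ]
  expect_equal(bik$sn_mean, 0.6)
  expect_equal(bik$ta_sd, sd(c(0.9, 0.8)))
  efd_row <- s[s$discretizer == "efd", ]
  expect_equal(efd_row$ta_sd, 0)
  one <- summarize_benchmark(rec[1, ])
  expect_equal(one$ta_mean, rec$ta[1])
})

test_that("the cli covers the file-level workflow end to end", {
  dir <- withr::local_tempdir()
  grndisc_cli(c("simulate", "--n-genes", "8", "--n-timepoints", "10",
                "--n-datasets", "2", "--n-edges", "5", "--seed", "11",
                "--out-dir", file.path(dir, "suite")))
  expect_true(file.exists(file.path(dir, "suite", "manifest.tsv")))
  expr_file <- file.path(dir, "suite", "D001_expr.tsv")
  grndisc_cli(c("discretize", "--method", "bikmeans", "--k", "3",
                "--in", expr_file, "--out", file.path(dir, "lv.tsv")))
  d <- read_discrete(file.path(dir, "lv.tsv"), k = 3)
  expect_true(all(unclass(d) %in% 1:3))
  grndisc_cli(c("infer", "--algorithm", "greedy", "--in",
                file.path(dir, "lv.tsv"), "--out", file.path(dir, "net.tsv")))
  grndisc_cli(c("evaluate", "--inferred", file.path(dir, "net.tsv"),
                "--truth", file.path(dir, "suite", "D001_net.tsv"),
                "--out", file.path(dir, "report.tsv")))
  expect_true(file.exists(file.path(dir, "report.tsv")))
  rec <- grndisc_cli(c("benchmark", "--suite-dir", file.path(dir, "suite"),
                       "--ks", "2,3", "--out", file.path(dir, "results.tsv")))
  expect_equal(nrow(rec), 2L * 3L * 5L * 2L)
  grndisc_cli(c("benchmark-stats", "--in", file.path(dir, "results.tsv"),
                "--anova", file.path(dir, "anova.tsv")))
  an <- read.delim(file.path(dir, "anova.tsv"))
  expect_equal(an$df[an$term == "Total"], nrow(rec) - 1L)
  expect_error(grndisc_cli(c("nope")), "unknown subcommand")
  expect_error(grndisc_cli(c("discretize", "--k")), "needs a value")
})
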