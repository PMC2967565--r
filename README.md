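# grndisc

Discretization methods for gene regulatory network (GRN) inference from
time-course expression data — and a benchmark of how much the
discretization choice matters.

Inference algorithms for GRNs (Bayesian-network scoring, mutual-information
filters) consume discrete data, but a genes × time-points expression matrix
`E` is continuous. `grndisc` implements five unsupervised discretizers
mapping `E` and an interval count `k` to levels `1..k`:

* **EWD** — per gene, `k` equal-width bins between the row min and max;
* **EFD** — per gene, `k` bins of (approximately) equal occupancy;
* **row k-means / column k-means (cokmeans)** — exact 1-D k-means (dynamic
  programming, deterministic) on each gene row / each time-point column;
* **bikmeans** — row and column k-means each at `k + 1` clusters; a cell
  with row label `r` and column label `s` gets the level `x` with
  `x² ≤ r·s < (x+1)²`, i.e. `x = ⌊√(r·s)⌋`, clamped to `k` at the top
  corner.

Three inference algorithms operate on the discretized matrix:

* **K2** (Cooper–Herskovits marginal likelihood, greedy parent selection)
  with a node ordering by *time of initial change* — the earliest time
  point at least 1.2-fold up or at most 0.7-fold down versus the first
  (baseline) time point; earlier changers are candidate regulators of
  later ones;
* **greedy hill-climbing** DAG search (add/delete/reverse moves, BIC);
* **ARACNE-style** mutual-information filter (`p ≤ 1e-7`, χ² null) with
  data-processing-inequality pruning (`tolerance t = 0.15`).

Inferred networks are scored against ground truth over all `N(N−1)`
ordered gene pairs: sensitivity `Sn = Tp/(Tp+Fn)`, specificity
`Sp = Tn/(Tn+Fp)`, total accuracy `TA = (Tp+Tn)/(all pairs)`. A bundled
simulator generates benchmark suites (by default 100 datasets of 50 genes
× 25 time points with a known 60-edge regulatory DAG each), and
`run_benchmark()` + `anova3()` + `marginal_means_comparison()` reproduce
the full factorial design: algorithm × interval count × discretizer with a
balanced three-way ANOVA (two-way interactions, no three-way term) and
Tukey–Kramer comparison of the 45 design-cell means.

## Worked example

```r
library(grndisc)
cfg   <- sim_config(n_datasets = 3, seed = 1)
suite <- simulate_suite(cfg)

d <- bikmeans(suite[[1]]$expression, 3)
d
#> DiscreteMatrix (bikmeans, k = 3): 50 genes x 25 time points

net <- infer_network(d, "greedy")
confusion(net, suite[[1]]$network)
#> ConfusionCounts (directed): Tp=0 Tn=2343 Fp=47 Fn=60
#>   Sn=0.0000 Sp=0.9803 TA=0.9563

rec <- run_benchmark(suite, ks = c(2, 3, 4))   # 3 x 3 x 5 x 3 = 135 records
anova3(rec)
#>    term   sum_sq  df  mean_sq      f        p
#> 1    S1 0.015125   2 7.56e-03 677.65 4.07e-61
#> 2    S2 0.001104   2 5.52e-04  49.47 6.68e-16
#> 3    S3 0.000974   4 2.43e-04  21.81 3.74e-13
#> 4 S1*S2 0.000480   4 1.20e-04  10.76 2.34e-07
#> 5 S1*S3 0.000650   8 8.12e-05   7.28 1.15e-07
#> 6 S2*S3 0.000771   8 9.64e-05   8.64 5.17e-09
#> 7 Error 0.001183 106 1.12e-05     NA       NA
#> 8 Total 0.020287 134       NA     NA       NA
```

Reading the example: on a sparse 60-edge truth over 2450 ordered pairs,
`TA` is dominated by specificity — the all-negative baseline already gives
`TA ≈ 0.976` — so discretizer/algorithm combinations are separated by how
few false positives they admit. In the ANOVA, S1 = inference algorithm,
S2 = interval count, S3 = discretizer: the algorithm has the largest
effect, and at this toy scale (3 datasets) all terms are significant.

The command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/grndisc.R simulate   --n-datasets 10 --seed 1 --out-dir suite/
Rscript inst/cli/grndisc.R discretize --method bikmeans --k 3 \
    --in suite/D001_expr.tsv --out levels.tsv
Rscript inst/cli/grndisc.R infer      --algorithm k2 --in levels.tsv \
    --expr suite/D001_expr.tsv --out net.tsv
Rscript inst/cli/grndisc.R evaluate   --inferred net.tsv \
    --truth suite/D001_net.tsv --out report.tsv
Rscript inst/cli/grndisc.R benchmark  --suite-dir suite/ --out results.tsv
```

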