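# coexnet

Weighted gene co-expression networks from correlation, mutual information,
and regression association measures — on a common, comparable footing.

## What it does

Given an expression matrix (genes × samples), every network analysis starts
by choosing a pairwise association measure and turning it into an
*adjacency matrix* `A` with `0 ≤ A_ij ≤ 1`, `A_ij = A_ji`, `A_ii = 1`.
coexnet implements the main families of that choice and everything needed
to compare them:

* **Correlations** — Pearson, Spearman, and the robust biweight
  midcorrelation (`bicor`) with an outlier-proportion cap
  (`max_p_outliers`, default 0.02), plus asymptotic p-values.
* **Mutual information** — equal-width discretization (default
  `round(sqrt(m))` bins), plug-in and Miller–Madow entropy estimators, the
  exact identity `MI = LRT / (2m)`, and three entropy-normalized MI
  adjacencies: symmetric uncertainty (ASU) and two "universal" versions
  (AUV1 = ASU/(2 − ASU), AUV2 = MI / max(H_i, H_j)).
* **The cor-MI function** — under bivariate normality,
  `F(s) = log(1 + ε − s²)/log(ε) · (1 − ω) + ω` with
  `ω = 0.43 m^−0.30`, `ε = ω^2.2` predicts AUV2 directly from a
  correlation coefficient.
* **Regression R²** — polynomial (default degree 3) and truncated-power
  cubic-spline model fitting indices as directional association scores,
  symmetrized by min/ave/max.
* **Adjacency transforms** — hard threshold, soft powers
  (unsigned `|cor|^β`, β = 6; signed `(0.5 + 0.5 cor)^β`, β = 12), general
  bounds rescaling, and the topological overlap matrix (TOM).
* **MI network inference** — RELNET, CLR, MRNET, and ARACNE (data
  processing inequality pruning with tolerance ε).
* **Module detection** — average-linkage clustering of `1 − A` with a
  deterministic modularity-guided branch cut, identical settings across
  measures, evaluated by the (unadjusted) Rand index.
* **Simulation benchmarks** — seed-deterministic generators for
  bivariate-normal pair sweeps and module-structured data with quadratic
  gene–gene relationships.

## Worked example

The nonlinear-module benchmark: 200 genes in 3 modules across 200 samples,
two modules containing both linear and quadratic members.

```r
library(coexnet)

sim <- simulate_module_data(seed = 1)

labs_bicor <- modules_pipeline(sim$expr, "bicor-signed")
labs_auv2  <- modules_pipeline(sim$expr, "auv2")

rand_index(labs_bicor, sim$labels)
#> [1] 0.9095477
rand_index(labs_auv2, sim$labels)
#> [1] 1

table(inferred = labs_bicor, truth = sim$labels)
#>         truth
#> inferred  0  1  2  3
#>        0 20  0  0  0
#>        1  0  0  0 60
#>        2  0 30  0  0
#>        3  0 30  0  0
#>        4  0  0 30  0
#>        5  0  0 30  0
```

The signed correlation network splits each nonlinear module into its
quadratic and linear halves (30 + 30) because a quadratic member is nearly
uncorrelated with a linear one, while the mutual-information adjacency
(AUV2) recognises the dependence and recovers the designed modules
exactly; the 20 background genes stay unassigned (label 0).

The robustness of bicor, on a pair with one corrupted sample:

```r
x <- c(0.5, 1.2, -0.3, 2.1, 0.8, -1.0, 1.5, 0.2, 30, -0.6)  # x[9] is an array outlier
y <- c(0.4, 1.1, -0.2, 2.3, 0.9, -1.2, 1.4, 0.1, 0.3, -0.5)
pearson_cor(x, y)   #> 0.0461
bicor(x, y)         #> 0.9607
```

And the cor-MI prediction parameters at m = 1000 samples:

```r
p <- cor_mi_params(1000)
c(p$omega, p$epsilon)   #> 0.05413 0.001635
f_cor_mi(0.8, p)        #> 0.2041  (predicted AUV2 for |cor| = 0.8)
```

## Command line

A thin CLI wraps the same functions (`inst/cli/coexnet.R`):

```sh
Rscript inst/cli/coexnet.R cor --method bicor --in expr.tsv --out cor.tsv
Rscript inst/cli/coexnet.R adjacency --type signed --beta 12 --tom --in expr.tsv --out tom.tsv
Rscript inst/cli/coexnet.R modules --measure auv2 --in expr.tsv --out labels.tsv
Rscript inst/cli/coexnet.R simulate modules --seed 1 --out-prefix sim_
```

All matrices travel as TSV/CSV with identifiers in the header and first
column; `--help` documents every subcommand.

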