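---
title: "Association measures and module detection in coexnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association measures and module detection in coexnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
```

# The problem

Gene co-expression networks encode, for every pair of genes, a connection
strength derived from the similarity of their expression profiles across
samples. coexnet implements a family of pairwise association measures —
correlations, discretization-based mutual information, and regression
model-fitting indices — together with the transforms that turn them into
*adjacency matrices* (entries in $[0,1]$, symmetric, unit diagonal) and a
common module-detection pipeline, so that the measures can be compared on
identical footing.

Throughout, the expression matrix has $n$ genes in rows and $m$ samples in
columns; $x_i$ is the profile of gene $i$. Samples are assumed independent:
every measure here is invariant to permuting the sample order.

# Correlation measures

Pearson and Spearman correlation are standard. The *biweight
midcorrelation* (bicor) replaces means by medians and down-weights
outliers with Tukey's biweight: with $u_i = (x_i - \mathrm{med}(x)) /
(9\,\mathrm{mad}(x))$ (unscaled median absolute deviation, no 1.4826
consistency factor),

$$w_i(x) = (1 - u_i^2)^2\, I(1 - |u_i|),$$

so a point further than nine mads from the median gets weight zero, and

$$\mathrm{bicor}(x,y) = \frac{\sum_i (x_i - \mathrm{med}(x))\, w_i(x)\,
  (y_i - \mathrm{med}(y))\, w_i(y)}
  {\sqrt{\sum_j \left[(x_j - \mathrm{med}(x))\, w_j(x)\right]^2}
   \sqrt{\sum_k \left[(y_k - \mathrm{med}(y))\, w_k(y)\right]^2}}.$$

The `max_p_outliers` argument (default 0.02) caps the proportion of
observations per side of the median that may receive weight zero: on each
side, $u$ is rescaled by the magnitude of its `max_p_outliers` quantile
whenever that magnitude exceeds one. The cap keeps the estimator robust
without discarding more than the stated fraction of data in heavy-tailed
samples. Two degenerate cases are defined explicitly: if
$\mathrm{mad}(x)=0$ but $\mathrm{sd}(x)>0$, the vector falls back to
Pearson-style terms (mean-centred, unit weights), because the biweight is
undefined at zero mad; a fully constant vector is an error everywhere in
the package — no association measure here defines a value for it.

Under bivariate normality bicor and Pearson correlation are practically
indistinguishable; on the package's bivariate-normal benchmark (2000 pairs,
$m = 1000$) their mean absolute difference is below 0.01. The measures
differ exactly where they should: when single arrays carry extreme values.

# Mutual information on discretized profiles

Numeric profiles are discretized by the equal-width rule: $[\min(x),
\max(x)]$ is split into `n_bins` equal intervals (right-open, last bin
closed), with the default $\mathrm{round}(\sqrt{m})$ bins (half away from
zero; the square-root rule leaves the rounding open, and nearest-integer is
the least surprising total choice). Entropy is estimated in nats either by
the plug-in estimator $-\sum_r \hat p_r \log \hat p_r$ or with the
Miller–Madow correction $+(B-1)/(2m)$, $B$ the number of occupied bins
(occupied joint cells for the joint entropy — the correction's own
definition, though the choice for the joint term is a convention this
package fixes rather than inherits).

Mutual information is computed through the entropy identity
$\mathrm{MI} = H(dx) + H(dy) - H(dx,dy)$. For the plug-in estimator this
equals the direct double sum over joint frequencies, and it obeys the exact
identity

$$\mathrm{MI}_{\text{plugin}} = \frac{\mathrm{LRT}}{2m}$$

with the multinomial likelihood-ratio (G) statistic of independence — the
package tests this to $10^{-10}$ on randomized tables, along with the
three entropy upper bounds $\mathrm{MI} \le \min(H_x,H_y) \le (H_x+H_y)/2
\le \max(H_x,H_y)$. The Miller–Madow corrections are additive per entropy
term and need not respect those inequalities, so MI is clamped at zero
from below and all derived adjacencies are clipped into $[0,1]$; clipping
only ever engages on estimator noise.

Three entropy-normalized MI adjacencies are provided:

* symmetric uncertainty, $A^{ASU}_{ij} = 2\,\mathrm{MI}_{ij} / (H_i + H_j)$;
* universal version 1, $A^{UV1} = A^{ASU} / (2 - A^{ASU})$, whose
  complement $1 - A^{UV1}$ is a universal distance (triangle inequality);
* universal version 2, $A^{UV2}_{ij} = \mathrm{MI}_{ij} / \max(H_i, H_j)$,
  also universal in that sense.

UV1 is a monotone transform of ASU (identical rank order); UV1 and UV2
differ but are extremely rank-correlated in practice.

# The cor-MI prediction function

For bivariate-normal pairs discretized with the square-root rule, the UV2
adjacency is an approximately deterministic, monotone function of the
correlation:

$$F(s) = \frac{\log(1 + \varepsilon - s^2)}{\log \varepsilon}(1 - \omega)
  + \omega, \qquad \omega = 0.43\, m^{-0.30},\ \varepsilon = \omega^{2.2},$$

which maps $[0,1]$ into $[0,1]$ with $F(1)=1$ whenever $0 < \varepsilon
\le \omega < 1$ (asserted at construction). `predict_auv2_from_cor()`
applies $F$ to $|{\rm cor}|$, since $F$ is defined on magnitudes via
$s^2$. On the 2000-pair benchmark the prediction tracks the observed UV2
with mean absolute error well under 0.02 and correlation above 0.99 —
`scripts/acceptance.R` recomputes both numbers. The constants 0.43,
−0.30, 2.2 are taken as given, not refitted, and the approximation is
asserted only under its stated conditions (normality, square-root
equal-width binning).

# Regression R² measures

Polynomial regression of degree $d$ (default 3) and cubic spline
regression in the truncated-power basis

$$[\,1, x, x^2, x^3, (x - k_1)_+^3, \dots, (x - k_K)_+^3\,]$$

give model fitting indices $R^2 = \mathrm{cor}(y, \hat y)^2$ used as
association scores. Knots sit at equally spaced interior quantiles of $x$
(placement matters much less than count), with the count following the
rule of thumb: 5 knots for $m > 100$, 3 for $m < 30$, otherwise 4 — read
literally at the boundaries, so $m = 30$ and $m = 100$ both give 4. The
truncated-power basis is used exactly as written rather than a natural
cubic spline basis with linearity constraints beyond the boundary knots;
the two differ in boundary behaviour, and the plain basis is what the
formulas above define. Least squares is solved by rank-aware QR; when the
fitted values or the response are constant, $R^2$ is defined as 0 (a
constant fit explains nothing). The fast matrix path in `r2_matrix()`
computes one orthonormal basis per predictor gene and projects all
targets at once; tests pin it to looped pairwise fits and to an
independent SVD-pseudoinverse solver.

$R^2(x_i \to x_j)$ and $R^2(x_j \to x_i)$ differ in general — regressing
$y = x^2$ on $x$ explains almost everything while the reverse explains
almost nothing when $x$ is symmetric about zero. The non-symmetric matrix
is symmetrized entry-wise by `min`, `ave`, or `max`; `max` is the package
default, matching how the R² measures are compared against MI (the three
choices give very similar adjacencies in practice).

# Adjacency transforms

Hard thresholding ($A_{ij} = 1$ iff $s_{ij} \ge \tau$, inclusive), soft
thresholding (unsigned $|{\rm cor}|^\beta$, default $\beta = 6$; signed
$(0.5 + 0.5\,{\rm cor})^\beta$, default $\beta = 12$), and the general
bounds rescaling $A = ((S - L)/(U - L))^\beta$ are provided; rescaling
with bounds $\pm 1$ reproduces the signed adjacency exactly, and with
lower bound 0, upper bound $(H_i + H_j)/2$, $\beta = 1$ it reproduces the
symmetric-uncertainty MI adjacency. The topological overlap transform

$$\mathrm{TOM}_{ij} = \frac{\sum_{l \ne i,j} A_{il} A_{lj} + A_{ij}}
  {\min(k_i, k_j) - A_{ij} + 1}, \qquad k_i = \sum_{l \ne i} A_{il},$$

replaces direct strength by shared-neighbour overlap. It is computed with
one matrix product (the $l \in \{i, j\}$ terms subtracted) and tested
against the naive triple loop. The default "TOM" network chain is bicor →
signed $\beta = 12$ → TOM.

# MI network inference algorithms

Four post-processing algorithms turn an MI matrix into an inferred
network: RELNET (threshold at $\tau$, inclusive, matching the hard
threshold convention), CLR (per-row background z-scores, pair score
$\sqrt{z_i^2 + z_j^2}$; a zero-variance row warns and contributes 0),
MRNET (maximum-relevance/minimum-redundancy forward selection per target;
the full ordering is scored because no stopping rule is defined —
every candidate is scored at entry, the pair score is the larger of the
two directions, floored at 0, and the redundancy set never contains the
target), and ARACNE (remove edge $(i,j)$ when $\mathrm{MI}_{ij} \le
\min(\mathrm{MI}_{ik}, \mathrm{MI}_{kj}) - \varepsilon$ for some $k$).
ARACNE evaluates all triplets against the original post-threshold matrix
and removes flagged edges simultaneously, making the result independent of
scan order; its surviving edges are always a subset of RELNET's at the
same $\tau$, nested in $\varepsilon$. Argmax ties in MRNET break to the
lowest gene index for determinism. Outputs rescale to adjacencies by
dividing by the maximum off-diagonal score.

# Module detection

All measures feed one pipeline: adjacency → dissimilarity $1 - A$ →
average-linkage (UPGMA) clustering → branch cut → module labels (0 =
unassigned), with clustering settings identical across measures so that
comparisons reflect the measures, not the clustering.

The branch cut deserves comment, because it is the one place where this
package substitutes its own deterministic procedure for an adaptive
published one (dynamic branch cutting). Two simple rules were evaluated
and rejected. A cut at a fixed fraction of the maximum merge height
ignores that the "unrelated genes" dissimilarity plateau depends strongly
on the measure (near 1.0 for a $\beta = 12$ soft adjacency, near 0.93 for
an MI adjacency at $m = 200$), and lands inside the inter-cluster band
for the compressed trees. A cut at the largest gap between consecutive
merge heights is scale-adaptive but fragile whenever biologically related
branches join at heights inside the background band. The rule adopted for
`cut_height = "auto"`: score the partition induced by every distinct cut
height of the tree by its Newman–Girvan modularity on the adjacency, keep
the best, then iteratively unassign genes whose mean adjacency to their
own module is below `strip_ratio` (default 0.5) times the module's mean
internal adjacency. Modularity decides *merges* relative to the network's
own density — branches that interconnect above chance are kept together —
and the stripping pass plays the role of the assignment cleanup in
dynamic cutting, ejecting background genes that ride along on a high cut.
The procedure is deterministic, uses the same settings for every measure,
and honours explicit numeric cut heights unchanged; modules smaller than
`min_module_size` (default 20) are unassigned. Because the cut is not the
published dynamic algorithm, absolute Rand indices are not comparable to
published figures; only orderings between measures are asserted anywhere
in this package.

Partition agreement uses the plain (unadjusted) Rand index — the fraction
of gene pairs on which two partitions agree — with label 0 treated as an
ordinary label.

# Simulation benchmarks

Two generators make every claim testable without external data; both are
seed-deterministic.

**Bivariate-normal pairs.** `simulate_pairs()` draws, for each target
correlation $r$ on a grid (default 2000 values spanning $(-0.999,
0.999)$), $x \sim N(0, I_m)$ and $y = r x + \sqrt{1 - r^2}\,\eta$,
default $m = 1000$. This is the design behind the cor-MI accuracy, the
UV1/UV2 agreement, and the bicor–Pearson comparison.

**Quadratic modules.** `simulate_module_data()` builds 200 genes × 200
samples in 3 modules of 60 (30% of the gene count each) plus 20
independent background genes. Each module has a standard normal seed
profile $e$; linear members are $a e + \epsilon$ and, in the first two
modules, a fraction `quadratic_fraction` (default 0.5) of members are
instead $a (e - \bar e)^2 + \epsilon$, with $\epsilon \sim N(0,
0.5^2)$ and loadings $a \sim \mathrm{Uniform}(0.8, 1.2)$. Since $e$ is
symmetric, $\mathrm{E}[e \cdot (e - \bar e)^2] \approx 0$: a quadratic and
a linear member of the same module are nearly uncorrelated yet strongly
dependent, which is precisely the regime where MI and regression measures
should beat correlations. Loadings are positive by design: with random
signs a signed network must split every module into anti-correlated
halves, and the benchmark could no longer distinguish "misses nonlinear
structure" from "penalized for sign convention". The noise level and
module sizes are package choices (the generative equations are not
published); they were fixed once at values giving within-module
correlations around 0.9 — typical of a strong, clean module — and are not
tuned per analysis.

What the generators do *not* emulate: mean–variance trends, heavy-tailed
technical noise, batch structure, correlated background genes, and
overlapping modules. Passing benchmarks therefore demonstrate correctness
of the estimators and the claimed orderings under clean conditions, not
performance on real microarray or sequencing data.

With these defaults, the quadratic benchmark (10 seeds) reproduces the
expected ordering: the UV2, polynomial-R² and spline-R² pipelines recover
the true modules essentially perfectly, while the signed-bicor pipeline
splits each nonlinear module into its quadratic and linear halves (Rand
near 0.91); with `quadratic_fraction = 0` every pipeline recovers the
truth. `scripts/acceptance.R` recomputes these numbers. The
pruning-style inference networks (ARACNE, MRNET, CLR) output sparse
backbones rather than dense blocks; the module pipeline accepts them, but
branch cutting on a backbone is not a meaningful module detector and no
recovery claim is made for them.

# Numerical conventions

* Entropies and MI in nats; natural logarithm throughout.
* Adjacency axioms checked to $10^{-12}$ ($10^{-8}$ after long transform
  chains); diagonals forced to exactly 1 on validation.
* Equal-width bins right-open, last bin closed, so the maximum is always
  assigned.
* Missing values are rejected at read time: none of the estimators
  defines missing-data handling, and silently dropping samples would
  change $m$ inside every formula.
* All ties (MRNET/CLR argmax, discordance screen) break deterministically
  (lowest index / lexicographic ids).
* Problem sizes in the test-suite benchmarks: 2000 pairs at $m = 1000$
  for the pair design; 10 seeds of the 200 × 200 module design; 1000
  random contingency tables for the exact identities; 50 random instances
  ($n \le 8$) per brute-force oracle.

# Worked example

```{r example, eval = FALSE}
sim <- simulate_module_data(seed = 1)
labs_bicor <- modules_pipeline(sim$expr, "bicor-signed")
labs_auv2  <- modules_pipeline(sim$expr, "auv2")
rand_index(labs_bicor, sim$labels)   # ~0.91: quadratic halves split off
rand_index(labs_auv2, sim$labels)    # 1.0: nonlinear structure captured
```

# Known limitations

* MI estimation is equal-width discretization only — no kernel, k-NN, or
  adaptive binning estimators, and no permutation p-values for MI.
* The cor-MI function is asserted only under bivariate normality with
  square-root binning.
* bicor's outlier cap follows the documented contract of the modified
  estimator but is not guaranteed bit-compatible with any external
  implementation of it.
* The branch cut is a deterministic stand-in for dynamic tree cutting;
  absolute module counts and Rand values will differ from analyses using
  the dynamic algorithm.
* No probe collapsing, normalization, batch correction, GO enrichment, or
  module eigengene summarization.
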