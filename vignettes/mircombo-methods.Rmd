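---
title: "Methods: discriminant-guided cluster refinement and combinatorial marker search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminant-guided cluster refinement and combinatorial marker search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircombo)
```

`mircombo` searches a two-class expression matrix (rows = miRNAs, columns
= samples) for small combinations of miRNAs that jointly discriminate the
classes. This vignette documents the statistical model, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## The discriminant at the core

Every quality criterion in the pipeline is built from Fisher's linear
discriminant. For samples $x_1, \dots, x_n \in \mathbb{R}^d$ in classes
$c_0$, $c_1$ with mean vectors $m_0$, $m_1$, the within-class scatter is

$$S_w = \sum_{x_i \in c_0} (x_i - m_0)(x_i - m_0)^T +
        \sum_{x_i \in c_1} (x_i - m_1)(x_i - m_1)^T,$$

and the projection direction is $w \propto S_w^{-1}(m_0 - m_1)$. We scale
$w$ to unit norm and fix its sign so that $w^T(m_0 - m_1) \ge 0$; this
makes the decision rule coherent: a sample is assigned to $c_0$ exactly
when $w^T x \ge y_0$, with the threshold the class-size-weighted mean of
the projected class means, $y_0 = (n_0 m_0' + n_1 m_1')/(n_0 + n_1)$. The
weighting is deliberately class-size weighted (not the midpoint): with
imbalanced classes it pulls the boundary toward the larger class's
projected mean.

Two numerical choices matter here:

* **Singular scatter.** When a cluster has more miRNAs than there are
  samples (or duplicated rows), $S_w$ is singular. We use the
  Moore–Penrose pseudo-inverse (`MASS::ginv`), the minimum-norm solution;
  `ridge = TRUE` offers $S_w + \lambda I$ with
  $\lambda = 10^{-6}\,\mathrm{tr}(S_w)/d$ for users who prefer a
  regularised inverse. On well-conditioned data the two agree (this is
  tested).
* **Degeneracy.** If $m_0 = m_1$ exactly the direction is undefined and
  `fit_fda()` errors; cluster-level callers catch this, keep the cluster
  unsplit and flag it `degenerate` rather than split along a meaningless
  direction.

## Pipeline stages and their parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| `detection_fraction` | 0.7 | fraction of samples | drop a miRNA undetected in more than 30% of samples; undetected cells are imputed with the row mean of detected values, which distorts row variance less than any constant fill |
| `alpha` | 0.05 | p-value | two-sided Welch screen; a miRNA at exactly p = α is kept (the filter removes p *greater than* α); no multiple-testing correction by default, `bh = TRUE` switches the filter to Benjamini–Hochberg adjusted values |
| `distance_metric` | `"correlation"` | 1 − Pearson r | clusters are meant to capture *co-expression*, which correlation measures scale-free; Euclidean is offered for intensity-scale clustering |
| `inconsistency_threshold` | 1 | dimensionless | cut of the dendrogram by the link inconsistency coefficient (below) |
| `msl_threshold` | 0.65 | MSL′ units | the sorted MSL′ curve of raw clusters typically shows its steepest ascent slightly above 0.6; 0.65 sits at that knee. It is data-derived, so `plot_msl_curve()` exposes the curve and the threshold is a plain argument |
| `k_max` | 4 | combination size | small panels stay biologically interpretable; the over/under-expression pattern of a k-tuple already has $2^k$ states |
| `cv_folds` | 5 | folds | stratified; see below |
| `seed` | — | integer | drives the CV fold assignment and the generator; identical seeds give byte-identical reports |

### Inconsistency coefficient and the cut

For each merge link we compare its height with the links at most 2 levels
beneath it (the link itself plus its child links): the coefficient is
$(h - \bar h)/s_h$ with the *sample* standard deviation, defined as 0 when
the comparison set has no spread (e.g. a link joining two leaves). Depth 2
is fixed: it is the de-facto standard depth for this statistic, and it
bounds the coefficient by $2/\sqrt{3} \approx 1.155$ — which is why
observed coefficients on typical data span 0 to about 1.15, and why 1 is a
usable cut. A link is *consistent* when its coefficient is at most the
threshold **and** every link beneath it is consistent; maximal consistent
subtrees become raw clusters and uncovered leaves become singletons. This
definition guarantees the output is a partition and that the number of
clusters is non-increasing in the threshold (both property-tested).

A consequence worth knowing: inside a homogeneous (exchangeable) block,
*balanced* merges — two child links of nearly equal height — push the
coefficient close to its $1.155$ bound, so a threshold-1 cut tends to
split even a clean correlation block into a few pure fragments rather than
return it whole. The refinement stage is insensitive to this (fragments of
a good cluster also pass the loss criteria), and over-splitting only
enlarges the representative set; the tests therefore assert cluster
*purity* and high Rand index against planted blocks, not exact recovery.

### Projection-loss refinement

A cluster is summarised by one direction $w$; what that summary discards
is measured on the samples in the cluster's feature subspace. With
$\bar x$ the sample mean and $P_h$ the projection onto the hyperplane
through $\bar x$ with normal $w$:

$$\mathrm{MSL} = \frac{1}{n}\sum_i \|P_h(x_i - \bar x)\|^2, \qquad
  \mathrm{MLR} = \frac{1}{n}\sum_i \frac{\|P_h(x_i - \bar x)\|}{\|x_i\|}.$$

MSL grows with the cluster size $m$, so the decision uses
$\mathrm{MSL}' = \mathrm{MSL}/m$ against the 0.65 threshold. MLR is
relative to the *raw* (uncentred) sample norm — intentionally, so that
clusters of low-magnitude samples are judged on relative loss; samples
with $\|x_i\| = 0$ are excluded from the average (all-zero data returns 0
with a warning). The MLR threshold $1 - 1/m^2$ is deliberately loose and
acts as a supplement to MSL′ for clusters whose member variances differ
greatly. A cluster is split when **either** criterion is violated, by
cutting its dendrogram subtree at its top merge and recursing into the two
children; splitting strictly decreases cluster size and singletons always
pass (MSL = MLR = 0 in one dimension), so the recursion terminates.
Binary splitting along the existing tree (rather than re-clustering the
members) is the design choice: it keeps the refined partition nested in
the dendrogram, is deterministic, and needs no extra parameters.

### Representative selection

The discriminant weight magnitude $|w(j)|$ ranks a cluster's members by
their contribution to class separation. Two modes are provided because the
scope of $w$ is genuinely open:

* `w_mode = "global"` (default): one discriminant over *all* kept miRNAs,
  each cluster reading its members' weights off that vector. This is the
  literal reading of the selection rule, and with a pseudo-inverse it is
  defined even when miRNAs outnumber samples.
* `w_mode = "cluster"`: an independent discriminant per cluster. With
  $p \gg n$ the global fit lives in an $n$-dimensional subspace and its
  weights can be numerically fragile; the per-cluster fit is low-dimensional
  and steadier, and is what the planted-marker recovery test exercises.

Baselines for comparison: smallest Welch p-value, largest $|\mathrm{SNR}|$
with $\mathrm{SNR} = (\bar x_0 - \bar x_1)/(s_0 + s_1)$ (absolute value —
the score is a relevance measure, direction-agnostic), and the
centre-gene rule (member nearest the cluster mean under the clustering
metric). All criteria break ties lexicographically by miRNA id, with
scores compared at 10 significant digits so that exact duplicates tie
despite floating-point linear algebra — selection is deterministic and
invariant to member order across platforms.

### Combination scoring

Each combination is scored by a radial-basis-kernel SVM (libsvm via
`e1071`) at library defaults — cost 1, kernel width $1/k$ — under
stratified cross-validation. Choices the numbers depend on:

* **Stratified folds, assigned once.** The fold assignment is a function
  of (labels, folds, seed) only — never of the features being scored — so
  every combination, and the exhaustive oracle, is evaluated on identical
  folds, and a combination appearing in both search and oracle has exactly
  one score. If the smaller class has fewer samples than folds, the fold
  count is reduced with a warning.
* **Pooled confusion counts.** Sensitivity, specificity and total accuracy
  are computed from confusion counts pooled over folds (micro-average);
  per-fold rates are ill-defined when a fold holds few samples of one
  class. Per-fold accuracies are retained in a list column for inspection.
* **Positive class.** Sensitivity counts class $c_0$ — the first label
  token encountered — as positive; the report echoes the mapping.
* **No tuning.** Hyperparameter search would change what a ranking means
  mid-search; the classifier stays fixed at defaults.
* **Total order.** Rankings sort by total accuracy descending, ties broken
  lexicographically on the sorted, `";"`-joined member ids. Every rank is
  therefore well-defined, which the search-quality metrics require.

### Search-quality metrics

Against an exhaustive oracle over all kept miRNAs (same scorer, same
folds, same tie rule), the search's top-$n$ list yields
$\mathrm{AvgRank}_n$ (mean oracle rank; floor $(n+1)/2$, attained iff the
search's top n are exactly the true top n) and $\mathrm{HitRatio}_n$
(fraction with oracle rank $\le n$). The top-$n$ boundary is taken after
the total ordering — no tie expansion — and $n$ is capped at the searched
list length with a warning. The oracle is a benchmarking facility guarded
by a combination budget (default $2 \times 10^6$); the main pipeline never
needs it.

## The synthetic-data generator

`generate_synthetic()` draws equicorrelated Gaussian blocks: block $b$
has a latent sample profile $L_b \sim N(0, I_n)$ and member rows
$\sigma(\sqrt{\rho}\,L_b + \sqrt{1-\rho}\,\varepsilon)$, giving exact
within-block correlation $\rho$ and marginal sd $\sigma$. One designated
member per block receives a between-class mean shift of
`effect_size`$\cdot\sigma$. A `planted_combo` instead gives the designated
members of the named blocks random $\pm\delta$ signs whose *parity*
encodes the class: each member is marginally symmetric noise, but jointly
the tuple separates the classes — the mechanism-level test of why
combination search can beat univariate ranking.

What the generator does **not** emulate: platform intensity distributions
(log-normal skew, saturation), missingness that correlates with intensity,
batch structure, heavy tails, and between-block correlation. Passing tests
on this model therefore demonstrate the *algorithmic* properties —
screening calibration, block purity of the cut, loss-guided splitting,
representative recovery, search-quality accounting — not robustness to
real microarray artefacts. The defaults (5 blocks of 8, $\rho = 0.8$,
40 samples per class, effect size 3, $\sigma = 1$) are the study
conditions used throughout the tests and the acceptance script: effect
size 3 is a strong but realistic marker on detection-filtered arrays, 40
per class is a mid-sized cohort, and $\rho = 0.8$ is tight co-expression.

## Problem sizes used in validation

The test-suite and acceptance-script simulations run at desk scale, chosen
so the full suite completes in minutes while keeping every assertion
statistically meaningful: oracle-equivalence on 12 candidates ($k \le 3$,
298 combinations scored twice), representative recovery over 50 seeds
(5 blocks × 8 members, 80 samples), criterion comparison over 25 seeds
against a 190-pair oracle, and null calibration on 2000 pure-noise
miRNAs at 10 + 10 samples.

## Known limitations

* Two classes only; no multi-class discriminant.
* The expression matrix is taken as given — no normalisation, log
  transform or batch correction is applied, and the pipeline's behaviour
  under non-normalised raw intensities is the user's responsibility.
* Global-mode discriminant weights with $p \gg n$ are minimum-norm
  pseudo-inverse solutions; they are deterministic but can spread weight
  across correlated members, which is exactly why per-cluster mode exists.
* The exhaustive oracle (and hence AvgRank/HitRatio) is only computable at
  desk scale; at realistic p it is a thought experiment the metrics
  approximate by subsampling the candidate set.
* `MSL'`'s 0.65 default is a knee heuristic from typical sorted-loss
  curves; inspect `plot_msl_curve()` on your own data before trusting it.
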