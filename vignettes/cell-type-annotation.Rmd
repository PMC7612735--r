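---
title: "Two-round mini-batch SGD cell-type annotation and cross-tissue composition statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-round mini-batch SGD cell-type annotation and cross-tissue composition statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Large scRNA-seq studies need every cell assigned a label from a controlled
cell-type vocabulary, often at two resolutions: a coarse ("high-hierarchy")
level such as *T cells*, and a fine ("low-hierarchy") level such as
*Tem/emra_CD8*, connected by a many-to-one fine-to-coarse map. Once cells
are labelled, the scientific questions shift to composition: is a cell
type over-represented in one tissue relative to the others, accounting for
the fact that cells come from a handful of donors whose sampling depth and
composition differ?

`sctyper` implements both halves: a linear classifier trained on annotated
reference cells and applied to query datasets, and a donor-stratified
enrichment screen over (cell type, tissue) pairs.

# The classifier

## Model

For a cell with normalized expression vector $x \in \mathbb{R}^G$, class
scores are $s = Wx + b$ with $W \in \mathbb{R}^{K \times G}$, and
probabilities are the softmax $p_k = e^{s_k} / \sum_j e^{s_j}$. Training
minimizes the penalized cross-entropy

$$
L(W, b) \;=\; -\frac{1}{n}\sum_{i=1}^{n} \log p_{y_i}(x_i)
\;+\; \frac{\lambda}{2}\lVert W \rVert_2^2 ,
$$

with intercepts unpenalized. We chose the multinomial (softmax) likelihood
over one-vs-rest because it yields normalized per-cell probabilities and a
single argmax decision rule; a one-vs-rest mode is available behind
`training_config(mode = "ovr")` for users who want independent per-class
scores.

## Optimization

The loss is minimized by mini-batch stochastic gradient descent: each
epoch, cells are shuffled with a seeded RNG and split into consecutive
blocks of `batch_size` (default 1000); the final remainder block is kept,
because discarding cells is worse than one smaller batch. For batch $B$,

$$
\nabla_W = \tfrac{1}{|B|} (P - Y)^\top X_B + \lambda W ,
$$

and the step size follows the inverse-scaling schedule
$\eta_t = \eta_0 / (1 + \lambda \eta_0 t)$ (a constant schedule is
available). Weights start at zero, so a fit is a deterministic function of
(data, config, seed) — model files from identical runs are byte-identical,
which the test suite asserts.

Two defaults deserve explanation. With batches of 1000 cells, an epoch on
a few thousand cells contributes only 3–5 updates, orders of magnitude
fewer than per-sample SGD; and log1p-CP10K features are deliberately not
standardized (inputs stay sparse and a model applies directly to any query
on the same scale), so entries range up to ~9 and gradient magnitudes are
large. At $\eta_0 = 0.1$ the mini-batch loss visibly oscillates before
eventually recovering; at $\eta_0 = 0.02$ with 30 epochs per round the
trajectory is monotone on the reference conditions and converges with a
comfortable margin. Those are the defaults (`learning_rate0 = 0.02`,
`epochs = 30`); both are ordinary config fields and carry no claim of
being the setting used by any published model.

## Two-round training and markers

Round 1 fits on all genes. For each class, genes are ranked by descending
*signed* weight and the top `n_top_genes` (default 300) are taken; the
union over classes — in the original gene order — becomes the feature set
for round 2, whose model is returned. Signed rather than absolute weight
is used because marker genes are defined by positive association with
their class; a gene whose absence characterizes a class is not a marker.
Ties in the ranking are broken by gene order, and ties in the prediction
argmax by class order, so every code path is deterministic.

`extract_markers()` exposes the same ranking per class, which is the
package's marker-derivation facility.

## Prediction across gene universes

A query dataset rarely shares the training gene universe. `align_genes()`
maps the query onto the model's feature list: shared genes keep their
values, missing genes are zero-filled, extra genes are dropped, and the
overlap fraction is reported (warned below 0.5, error at zero). Zero-fill
is a deliberate choice — the alternative, refusing to predict, helps
nobody — but predictions under low overlap should be treated with
suspicion, which is why the fraction is logged on every prediction. Gene
identifiers are matched by exact string equality; symbol harmonization is
a curation problem outside this package's scope.

An optional probability threshold relabels low-confidence cells
`"Unassigned"`; it is off by default since no principled universal value
exists.

## Updating a model

`update_model()` retrains two-round on the concatenation of the old and
new corpora: gene universes are reconciled onto their union with
zero-fill (so markers present in only one corpus survive), new labels are
validated against the hierarchy first, the class set becomes the union,
the version increments, and a provenance line records what was added.
Models do not embed their training data, so both corpora must be supplied.

# Evaluation

Per-class precision, recall and F1 come from the confusion table;
`"Unassigned"` counts as a false negative for the true class and enters no
precision denominator. The summary statistic is the **median of per-class
F1** over classes with non-zero support; the macro mean is reported
alongside, since the two are easy to conflate and reporting both is
cheap. Learning curves hold out a seeded stratified validation split
(default 10%) and score the model at every epoch boundary of both rounds.

# Tissue composition statistics

## Proportions

Cell numbers are first normalized within each tissue (donors pooled),
$p(t, j) = n(t, j) / N(j)$, then each type's within-tissue proportions are
re-expressed across tissues, $q(t, j) = p(t, j) / \sum_{j'} p(t, j')$, so
rows sum to 1. The first step removes tissue sampling-depth differences;
the second makes types comparable regardless of abundance.

## Inclusion filter

A tissue enters the screen when at least `min_donors` (2) donors each
contribute strictly more than `min_cells` (50) cells of the analyzed
compartment. The alternative reading — tissue total above the threshold,
spread over at least two donors — is available via `rule = "total"`.

## Donor-stratified Poisson enrichment

For type $t$ and target tissue $j$, donor-level counts $n(d, g)$ over
groups $g \in \{\text{target}, \text{rest}\}$ are modelled as

$$
\log E[n(d,g)] = \beta_0 + \gamma_d + \beta_1 \mathbf{1}[g=\text{target}]
 + \log N(d,g),
$$

with donor fixed effects $\gamma_d$ and the donor's total compartment size
per group as offset. $\beta_1$ is the log rate ratio of interest; the
reported p-value is the one-sided Wald test of $\beta_1 > 0$ (enrichment),
with a two-sided option. Donors lacking cells in either group carry no
information about $\beta_1$ and are dropped with a log message; fewer than
two usable donors makes the pair not-testable. All testable pairs in a
screen are corrected jointly by Benjamini–Hochberg, and a pair is flagged
when the adjusted p-value is below $\alpha$ (0.05) with $\beta_1 > 0$.

Two numerical notes. First, when one group contains zero cells of the
type, the MLE diverges and the Wald statistic degenerates (the
Hauck–Donner effect: the standard error grows faster than the estimate),
so a Haldane–Anscombe continuity correction — 0.5 added to every
donor-group count — is applied in exactly that case and flagged
`corrected`; this keeps completely tissue-restricted types detectable and
gives depleted types p-values near 1 rather than 0.5. Second, the donor
fixed effects absorb per-donor scale exactly: rescaling one donor's counts
and offsets leaves $\beta_1$ unchanged whenever donors agree on the rate
ratio. When donors disagree, the stratified likelihood weighs donors by
their information content, so a rescaled donor legitimately moves the
pooled estimate — that is stratification working, not failing.

# The synthetic generator

`generate_dataset()` draws a cells-by-genes count matrix in which each
type owns a disjoint block of `markers_per_type` marker genes whose mean
is multiplied by $2^{\text{log2FC}}$ over a common `base_mean`; every
donor contributes a multiplicative lognormal nuisance factor per gene
(log-sd `donor_logfc_sd`), and counts are negative binomial with a shared
dispersion (variance $\mu + \phi\mu^2$). The composition — cells per
(type, tissue, donor) — is a fixed integer table, so planted tissue
restrictions or enrichments are expressed directly and the composition
itself carries no sampling noise; across generator seeds only the
expression draws vary. All draws flow from a single seeded stream.

The benchmark conditions (`default_benchmark_config()`) are 10 types in 3
coarse groups, 2,000 genes, 20 markers per type at log2 fold-change 2,
base mean 0.5, dispersion 0.5, 3 tissues × 3 donors with 50 cells per
combination, one type (`DC_migratory`) restricted to lymph node as a
planted enrichment, donor log-sd 0.1, seed 42. These sizes keep the full
two-round fit around 15 seconds on one core while leaving the problem
non-trivial (cells average ~1,000 UMIs, so marker evidence is genuinely
noisy).

What the generator does **not** emulate: realistic library-size variation,
ambient RNA, doublets, zero inflation beyond the NB, correlated gene
programs, or batch effects. Tests passing on this generator demonstrate
that the machinery is correct under its stated model — not that any
particular F1 will be attained on real tissue atlases, where label noise
and overlapping expression programs dominate.

# Numerical and degenerate-input choices

- QC thresholds are exclusive ("fewer than" semantics): a cell is removed
  iff total UMIs < `min_umi` (1000) or detected genes < `min_genes` (600).
- Cells with zero total counts normalize to all-zero rows and are flagged,
  not dropped silently.
- Softmax is computed with row-max subtraction; probability rows sum to 1
  within 1e-9 by construction.
- Training rejects single-class label sets, empty labels and non-finite
  expression values outright.
- Model files are JSON with base64-encoded little-endian float64 payloads
  (column-major K×G), so round-trips are exact to the byte and the layout
  is readable by independent implementations.
- BH adjustment passes `NA` (not-testable) entries through without
  counting them in the family size.

# Problem sizes used in the tests

The shipped suite trains the benchmark fit once (~4,200 cells × 2,000
genes, two rounds), checks SGD-vs-reference-optimizer agreement on a
201-cell/50-gene/3-class instance (300 full-batch epochs so both sit at
the convex optimum), runs 200 within-donor permutation screens for
calibration and 100 seeds of a planted 5-fold enrichment for power, and
500 single-pair permutation fits for p-value uniformity. The whole suite
runs in about a minute on one core.

# Known limitations

- Linear decision boundaries: types defined by nonlinear gene
  interactions will not separate.
- No probability calibration; confidences are softmax outputs, not
  frequencies.
- The enrichment model conditions on donor totals via offsets; it does
  not model overdispersion between donors beyond the fixed effects, and a
  conditional/exact test is out of scope.
- No majority-voting over clusters, no GPU path, no gene-ID translation,
  no doublet/ambient handling — upstream tools own those steps.
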