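# sctyper

Automated cell-type annotation for single-cell RNA-seq, with cross-tissue
composition statistics.

Annotating cells in scRNA-seq data against a curated reference vocabulary is
a bottleneck of every atlas-scale immune study: clusters must be matched to
known cell types and subtypes, ideally at more than one level of resolution,
and the resulting per-tissue cell-type compositions compared across donors.
`sctyper` packages that workflow for R users:

- **Classifier.** An L2-regularized multinomial logistic regression trained
  by mini-batch stochastic gradient descent in **two rounds**: round 1 fits
  on all genes; each cell type's top-`n` genes by signed weight (its
  markers) are pooled; round 2 refits on that union. For cell *i* with
  normalized expression `x_i` the model scores classes by
  `softmax(W x_i + b)` and is fitted by minimizing
  `-(1/n) Σ_i log p(y_i | x_i) + (λ/2)‖W‖²` over seeded shuffled
  mini-batches. Models predict per-cell probabilities, expose per-class
  marker rankings, support a two-level (fine/coarse) label hierarchy, and
  can be updated by retraining on an extended corpus with new curated
  labels (version and provenance tracked).
- **Evaluation.** Per-class precision/recall/F1 with the median of
  per-class F1 as the summary statistic, learning curves on a stratified
  validation split, and fine/coarse hierarchy-consistency checks.
- **Tissue composition.** Within-tissue proportions re-expressed across
  tissues, a tissue inclusion filter (more than 50 cells in at least two
  donors, by default), and per-(cell type, tissue) enrichment tests using
  Poisson regression stratified by donors —
  `log E[n(d,g)] = β0 + γ_d + β1·1[g = target] + log N(d,g)` — with
  one-sided Wald p-values and Benjamini–Hochberg correction across the
  screen.
- **Synthetic data.** A seeded negative-binomial generator with planted
  per-type marker programs, tissue/donor structure and a planted tissue
  restriction, so the whole pipeline is testable without external data.
- **CLI.** `simulate / train / predict / evaluate / markers / enrich`
  subcommands over the same functions, with config echo files and
  deterministic outputs.

## Worked example

```r
library(sctyper)

cfg <- default_benchmark_config()         # 10 types, 3 tissues x 3 donors
ds  <- generate_dataset(cfg)              # counts + annotations + hierarchy
X   <- normalize_log1p(ds$counts)         # log1p CP10K

fit  <- train_two_round(X, ds$annotations$label, training_config(seed = 1))
pred <- predict_probabilities(fit$model, X)
precision_recall_f1(confusion_counts(ds$annotations$label,
                                     pred$predicted_label))
#> <MetricsReport> median F1 = 1.0000, macro F1 = 0.9998
extract_markers(fit$model, "DC_migratory", k = 3)
#>        gene     weight
#> 1 gene_0193 0.09198506
#> 2 gene_0185 0.09083955
#> 3 gene_0199 0.08833086

res <- enrichment_screen(composition_table(ds$annotations))
subset(res, flagged)
#>      cell_type     tissue    beta1            p        p_adj flagged ...
#> 8 DC_migratory lymph_node 5.202907 1.141982e-10 3.425945e-09    TRUE
```

The training-set median F1 of 1.0 says the two-round model separates the
ten planted expression programs essentially perfectly; the marker table
recovers genes from the type's planted marker block
(`gene_0181`–`gene_0200`); and the screen flags exactly the planted tissue
restriction (`DC_migratory` appears only in lymph node), with `beta1` the
log rate ratio of the type's abundance in the target tissue versus the
rest, stratified by donor.

On disk, the same pipeline runs as:

```sh
Rscript inst/cli/sctyper.R simulate --out sim --seed 42
Rscript inst/cli/sctyper.R train --counts sim \
    --annotations sim/annotations.tsv --hierarchy sim/hierarchy.tsv \
    --min-umi 500 --out run
Rscript inst/cli/sctyper.R predict --model run/model.json --counts sim --out pred
Rscript inst/cli/sctyper.R enrich --annotations sim/annotations.tsv --out enr
```

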