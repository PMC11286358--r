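---
title: "Hierarchy-guided visible neural networks for drug response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchy-guided visible neural networks for drug response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnndrug)
```

## The modelling problem

Tumor genomes carry many rare alterations. A model that scores each gene
independently only learns from alterations common enough to recur in the
training cohort; everything rarer is noise to it. The premise of a visible
neural network (VNN) is that rare alterations are not independent — they
converge on a limited repertoire of multiprotein assemblies, and it is the
state of the *assembly* that shifts a drug response. `vnndrug` builds a
regression model whose architecture is literally a nested map of protein
assemblies, so that (i) rare alterations in different genes of one assembly
pool their evidence, and (ii) every hidden state of the network is a named
biological object that can be interrogated after training.

The observable being predicted is the area under a dose–viability curve
(AUC): 0 means complete killing, 1 no effect, values above 1 a growth
advantage under drug.

## Model

### Inputs

Each sample is an $m \times 3$ binary matrix over a fixed gene panel: one
channel each for nonsynonymous mutation, copy-number amplification and
copy-number deletion. Mutations count only if their type is on the
nonsynonymous whitelist (missense, nonsense, nonstop, frameshift and
in-frame indels, splice variants); silent and non-coding classes are
ignored. Genes a cohort did not assess are encoded as unaltered
(`mask_unassessed()`), which lets a model trained on one panel score samples
profiled on a narrower one.

### Architecture

The gene layer maps each gene's three bits to one value with a per-gene
affine function, followed by `tanh` and batch normalization over the batch,
one normalizer per gene. Above it, the network copies the assembly
hierarchy: an assembly with $K$ child assemblies and $M$ *additional* genes
(direct annotations absent from every descendant) owns an affine block from
its concatenated fan-in of $N K + M$ values to $N$ neurons, again with
`tanh` and batch normalization; during training, dropout is applied to the
block inputs in the deepest `dropout_top_layers` layers. Every assembly —
including the root — carries an auxiliary affine head mapping its $N$
neurons to a scalar prediction; the root head is *the* model output.

The loss aggregates mean squared error across the whole hierarchy:

$$
\mathrm{Loss} \;=\; \mathrm{MSE}(\hat y_{\mathrm{root}}, y)
\;+\; \alpha \sum_{s \neq \mathrm{root}} \mathrm{MSE}(\hat y_s, y)
\;+\; \beta \lVert W \rVert ,
$$

with $\alpha = 0.3$. The auxiliary terms act as deep supervision: every
assembly is pushed to be individually predictive, which both regularizes
and is what later makes per-assembly probes meaningful. The weight penalty
$\beta\lVert W\rVert$ is realized as decoupled weight decay inside the AdamW
update, applied to affine weights only (never biases or normalization
parameters); an explicit L2-in-loss variant is available via
`vnn_config(l2_in_loss = TRUE)` for gradient-checking and comparison.

A note on one dimension statement: the assembly input is implemented as a
length-$(NK+M)$ concatenation per sample mapped to $N$ outputs, i.e. the
weight matrix has shape $(NK+M) \times N$.

### Numerical choices

* **Initialization.** Uniform fan-in scaling,
  $U(-1/\sqrt{\text{fan-in}}, +1/\sqrt{\text{fan-in}})$, fully determined by
  the config seed; construction is bit-reproducible.
* **Batch normalization.** Biased batch variance, $\varepsilon = 10^{-5}$,
  running statistics with momentum 0.1. Evaluation mode uses the stored
  running statistics and disables dropout, so evaluation is a pure
  function; training-mode outputs depend on batch composition, which is the
  standard batch-norm caveat.
* **Backpropagation.** Gradients are analytic (hand-derived through the
  batch-norm, including its batch-statistic terms) and verified against
  central finite differences to $10^{-4}$ in the test suite.
* **Head warm start.** All head biases start at the training-mean response.
  AUCs concentrate near 1 while randomly initialized heads emit values near
  0; without the warm start the optimizer spends hundreds of steps learning
  an offset before any structure.

### Training schedule

AdamW with learning rate $5\times10^{-3}$, minibatches of 32, up to 900
epochs with a step decay (multiply by 0.2 after two thirds of the
schedule), weight decay 0.1. These defaults were chosen on the package's
synthetic task as the schedule with the best *and most stable* held-out
rank accuracy; the cooling phase in particular reduced run-to-run spread
substantially. All of them are plain arguments of `train_config()`.

The default block width is deliberately generous ($N = 24$). A wide neuron
bank behaves like an internal ensemble — the assembly output averages many
partially independent nonlinear views of the same fan-in — and in our
synthetic benchmarks widening the banks improved held-out rank accuracy
more reliably than any explicit regularizer we tried (weight decay
strength, dropout placement, input-bit dropout, restart averaging), while
narrow banks ($N \le 4$) were both weaker and far more variable from seed
to seed. The cost is a larger ridge probe at interpretation time, which is
why the probe requires at least $N + 2$ samples.

Two deliberate deviations from the "select by validation loss" convention
deserve explanation, because both come from the same phenomenon. At cohort
sizes of a few hundred, these networks drive the training MSE below the
noise floor while their *held-out* MSE never beats the mean predictor —
yet their held-out rank correlation is clearly positive. Magnitudes
overfit; ranks generalize. Consequently:

* the validation criterion for early stopping and hyperparameter selection
  defaults to the Spearman correlation of root predictions
  (`val_metric = "spearman"`), the unit in which drug-response models are
  benchmarked; the loss criterion remains available;
* the returned weights default to the final epoch (`checkpoint = "final"`)
  rather than the best-validation epoch: with 30-odd validation samples the
  per-epoch best is usually a lucky outlier, and selecting it measurably
  hurts test-fold performance.

## Hierarchy filtering

`filter_by_panel()` restricts annotations to the clinical panel and keeps
assemblies with at least `min_genes` (default 5) panel genes in their
*total* gene set. Because a child's total gene set is always contained in
its parent's, this filter is subtree-closed: when an assembly falls below
threshold, so do all of its descendants. Children and direct gene
annotations of a dropped assembly are re-attached to the nearest retained
ancestor — for the gene annotations this is substantive (alterations in a
pruned sub-assembly still reach the model through the ancestor, and it
makes filtering idempotent); for child edges it is a defensive rule that
containment hierarchies can never actually trigger.

## Cross-validation and the ensemble

`make_grouped_splits()` builds five outer folds at the *group* level (a
group is, e.g., a cell line with replicate measurements), splitting
64% / 16% / 20% into train / validation / test; replicates never straddle
partitions. Per fold, `run_nested_cv()` scores the hyperparameter
candidates on the validation set, refits the winner on train + validation,
and predicts the untouched test fold; the five fold models form the
ensemble, and external cohorts are scored by the arithmetic mean of the
members (`predict()` on the ensemble). Because removal of samples is at
group level and the five test sets partition the cohort, every sample gets
exactly one out-of-fold prediction.

## Interpretation

### Assembly importance

For a trained model, each assembly's samples-by-$N$ neuron block $P_k$ is
used in a ridge regression (penalty $\alpha_{\mathrm{ridge}}$, default 1;
solved by SVD with an implicit unpenalized intercept via centering) to
reconstruct the model's *own* predicted response $D$. Importance is the
Spearman correlation between the ridge fit and $D$, computed per ensemble
member and averaged. An assembly whose internal state carries the model's
decision scores near 1; one the model routes around scores near 0.

Two structural properties of this score matter when reading results:

* **Self-explanation bias.** $D$ is the model's own output, so the root
  probe reconstructs it almost perfectly *by construction*, and assemblies
  near the root inherit part of that. Even null models trained on noise
  show positive non-root importances. Significance must therefore always be
  read as *observed versus null*, never as distance from zero.
* **Ancestor dominance.** An ancestor's fan-in contains its descendants'
  states, so an ancestor's importance tends to bound its descendants'.
  Recovery of a causal assembly is identifiable against unrelated
  assemblies, not against its own ancestors — the synthetic truth block
  exports `signal_free_assemblies` (assemblies sharing no gene with any
  causal assembly) as the valid control set for exactly this reason.

### Permutation null and significance

`permute_hierarchy()` reshuffles all direct gene annotations globally while
preserving every assembly's annotation count and the entire edge set; the
seed is stored so any null is bit-reproducible. `null_distribution()`
trains a model per permuted hierarchy on the same data (a reduced epoch
budget is permitted and recorded in the returned object) and computes all
assembly importances against that null model's own predictions. The
canonical protocol uses 500 nulls; coarser budgets are legitimate for
type-I smoke checks and carry correspondingly coarse p-value resolution.

`importance_significance()` compares, per assembly, the ensemble's observed
importances against the nulls (one-tailed, observed greater), then applies
Benjamini–Hochberg across assemblies. Two comparison rules are offered, and
the choice matters:

* **Empirical (default).** The observed *mean* importance against the
  empirical null distribution, `p = (1 + #{null >= mean(obs)}) / (1 +
  n_nulls)`. The ensemble members are trained on overlapping folds of a
  single cohort, so they share one data draw: their spread reflects
  optimizer noise, not the between-dataset fluctuation of an assembly's
  importance level. The null models, each with a fresh gene placement, *do*
  display that fluctuation — so the calibrated question is "where does the
  observed mean sit in the null distribution", not "do five
  pseudo-replicates differ from the nulls in a two-sample test".
* **Welch (`method = "welch"`).** The one-tailed two-sample t-test of the
  five member scores against the nulls — the original protocol's rule. With
  hundreds of nulls and large effects its anti-conservatism is immaterial;
  at a 5-member, 50-null desk scale it produces false positives under
  label-shuffled data and we do not recommend it there.

A pooled-null mode (all assemblies' nulls pooled) is available behind a
flag; the per-assembly comparison is the default because null levels differ
systematically by depth (see self-explanation bias above).

Because importance levels also rise with training budget and training-set
size (a better-trained or better-fed network self-explains more), observed
and null models must be trained under the same protocol for the contrast to
be meaningful. `null_distribution(train_subsets = ...)` supports rotating
nulls over the cross-validation folds' train+validation cohorts for exactly
this purpose. Where the full predictive schedule is too expensive to repeat
for every null, the package's own checks use a *significance instrument*: a
separate ensemble and its nulls both trained at a moderate budget (300
epochs), while predictive accuracy is reported from the full-schedule
ensemble. Parity between the compared models matters more than the absolute
budget.

### Core assemblies

`select_core()` keeps assemblies with mean importance $\ge 0.5$ and FDR
$\le 0.1$, scans them in descending importance (ties broken by id, making
the output order-independent), and drops any candidate whose total gene set
has Jaccard similarity $> 0.5$ with an already-kept assembly.

## Downstream analytics

Predictions are turned into labels by thresholds at the median $\pm k$
standard deviations (`compute_thresholds()`, `classify_response()`); with
$k = 0$ both thresholds collapse to the median and no sample is left
undefined. Boundary ties go to the *sensitive* side at $t_{\mathrm{low}}$
and the *resistant* side at $t_{\mathrm{high}}$. The resistant class can be
median-split into partially/strongly resistant; ties at that median go to
partially resistant. Diagnostic and per-alteration odds ratios use the
cross-product with a Haldane–Anscombe $+0.5$ correction only when a zero
cell occurs, and Wald intervals on the log scale.

Alteration-level ranking inside an assembly uses L1-penalized logistic
regression of resistance (top 30% of AUC) versus sensitivity (bottom 30%),
fitted with `glmnet`; the scikit-learn-style inverse regularization $C$
(default 0.01) maps to `lambda = 1/(nC)`. Screen scoring centers guide-level
log fold-changes on the nontargeting-control median per replicate, averages
guides per gene, z-scores across genes and averages replicates. Gene-set
enrichment uses the classic weighted Kolmogorov–Smirnov running sum (weight
exponent 1) with seeded gene-label permutations — the sign-matched
permutation tail gives the p-value and the normalization for NES. The exact
Mann–Whitney path is used when both samples have at most 10 untied values;
otherwise the tie-corrected normal approximation without continuity
correction (so identical groups give the symmetric one-tailed p of 0.5).
Survival comparisons apply administrative censoring at a stated horizon,
then the standard log-rank test with a Cox model for the hazard ratio.

## The synthetic generator

`simulate_dataset()` emulates the full input stack with known truth: a
balanced assembly tree (default: 3 layers, branching 2, 15 genes per leaf =
60 genes over 7 assemblies), independent Bernoulli alterations per channel
(defaults 0.05 / 0.03 / 0.02 — rare, clinical-panel-like event rates), and
responses
$y = \text{baseline} + \sum_c \beta_c \,\min(1, \text{hits}_c) +
\mathcal N(0, \sigma)$
with two causal assemblies at $\beta = 0.3$, baseline 0.5 and $\sigma =
0.1$ by default. The saturating burden is the design point: one alteration
anywhere in a causal assembly shifts the response fully, which is precisely
the "rare alterations converge on assemblies" regime the model exists for;
a linear-burden mode is available behind `saturating = FALSE`. The truth
block stores burdens, effects and the noise-free response, so tests can
reconstruct the signal exactly, and names the signal-free assemblies that
serve as negative controls.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real cohorts: mutational signatures and gene-length
effects, correlated copy-number segments, panel-specific ascertainment,
batch effects between datasets, and dose–curve estimation noise that is not
i.i.d. Gaussian.

## Problem sizes used in the checks

The package's own acceptance checks run the canonical synthetic condition
(200 samples, 7 assemblies, 60 genes) through full nested cross-validation
with the default two-candidate search, interpret the resulting five-model
ensemble, and repeat the pipeline on label-shuffled responses with a
50-null permutation budget. These sizes were chosen so that a complete
recovery-plus-negative-control cycle is a coffee-break computation on a
single CPU while still leaving the planted effects well above the noise
floor ($\beta/\sigma = 3$).

## Known limitations

* Training-mode outputs depend on batch composition (batch normalization);
  only evaluation mode is a pure function.
* The importance score inherits the self-explanation and ancestor-dominance
  biases discussed above; cross-assembly comparisons should stay within a
  depth layer or rely on the permutation null.
* The permutation null preserves annotation counts and topology but not
  gene multiplicity across assemblies in pathological multi-annotation
  cases (a reshuffle is redrawn if it would duplicate a gene within one
  assembly).
* With very small validation folds the tuning step is noisy; the default
  candidate list is deliberately short and conservative.
* The L1 alteration ranking is associational; it identifies alterations
  co-varying with predicted resistance, not causal drivers.
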