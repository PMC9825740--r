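---
title: "Active learning for nanopore signal classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active learning for nanopore signal classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(nanoal)
```

## The problem

Nanopore sequencing produces long ionic-current traces in which each molecule
translocation appears as a blockade *event*: a contiguous stretch of current
below the open-pore level. Classifying these events — which RNA species, which
barcode — normally requires thousands of expert-annotated examples, and
annotating raw current signals is slow, skilled work. Pool-based active
learning (AL) attacks the labeling budget directly: instead of labeling the
pool in bulk, a classifier is trained on a handful of labels, asks an expert
for the labels of only the most informative unlabeled events, and repeats.

An AL run is the tuple (L, C, Q, U, S): labeled pool, classifier, query
strategy, unlabeled pool, supervisor. `run_al()` iterates
train → score → query → label → retrain, recording test accuracy, macro
one-vs-rest AUC and stopping diagnostics per iteration.

## Query strategies

All strategies are reduced to a maximize-informativeness score
$I(x) \in [0, 1]$ so that pool weights compose uniformly:

* **Least confident**: $1 - \max_i p_i$. Only the top posterior matters.
* **Margin** (the default uncertainty flavor): $1 - (p_{(1)} - p_{(2)})$,
  the inverted gap between the two most probable classes. Items the model
  nearly ties between two classes score highest.
* **Entropy**: $-\sum_i p_i \ln p_i \,/\, \ln k$, which weighs every class.
* **Query-by-committee**: a committee of classifiers trained on bootstrap
  resamples of L (query by bagging); disagreement is the vote entropy
  $-\sum_y \frac{V(y)}{C}\ln\frac{V(y)}{C}$, normalized by $\ln k$.
* **Density-weighted**: $(1 - \text{margin}) \times$ normalized kernel
  density, computed with Manhattan (L1) distances and a Gaussian kernel, so
  queries favor items that are uncertain *and* representative. The default
  bandwidth is the median pairwise L1 distance of the pool.
* **Random**: uniform sampling, the baseline every strategy must beat.

On binary problems the first three orderings coincide (all are monotone in
$|p_1 - p_2|$); they diverge only for three or more classes. The literature
uses "uncertainty sampling" for both margin- and entropy-based selection;
both are available here and `margin` is the default.

## The bias constraint

Nanopore pools contain *noise sequences* — truncation artifacts and strange
shapes that sit between or far from the class clusters. They look maximally
informative to every uncertainty score, yet they are the events experts
mislabel most and the ones whose labels generalize worst, and actively
sampled empirical risk is already a biased estimator. The bias constraint
counteracts this: before each query round,

1. embed labeled ∪ pool in 2-D (`pca_embedding()` by default),
2. set $O$ = centroid of the embedded *labeled* points,
3. compute each pool item's distance $w'_n$ to $O$,
4. invert and normalize: $w_n = 1 - \text{minmax}(w'_n)$.

The nearest pool item gets weight 1, the farthest 0, and the final query
score is $w_n \cdot I(x_n)$. Multiplication was chosen as the combination
rule because it preserves the intent — far, hard-to-label points can never
dominate a round — and reduces exactly to unconstrained selection when all
weights are 1, which gives a clean ablation identity (verified in the test
suite). With `mislabel_rate > 0` in the simulated supervisor, the events the
constraint suppresses are also the ones whose labels would have been wrong.

**What our synthetic benchmark shows — and does not.** On the built-in
generator with a *perfect* supervisor, the constraint demonstrably does what
it says (noise-class queries drop sharply and queries concentrate on the
confusable class pair) yet *raises* the labels-to-target count: here the
noise class is one of the seven classes the test set scores, its three shape
families are learnable, and its labels are always correct, so noise queries
are useful rather than wasted. The constraint's benefit materializes when
far-from-centroid events carry unreliable or unlearnable labels, which is
precisely the regime it was designed for and one the default simulator
deliberately does not manufacture.

## The embedding contract

Any function with the `pca_embedding()` signature — fit on a matrix, return
embedded `points` plus a `project(newx)` closure — can serve as the 2-D map
used by the bias constraint and the stopping evaluator. The default is the
first two principal directions of the column-standardized feature matrix:
linear, deterministic, and cheap, so selections and stopping decisions are
exactly reproducible. A t-SNE wrapper can be plugged in through the same
contract (fit t-SNE on the reference set, project new points by feature
standardization); it is not the default because t-SNE is stochastic and
non-metric, which would make distance-to-centroid reasoning — and every
downstream regression test — unstable.

## The stopping evaluator

When the full-data ceiling is unknown (the realistic case), the loop needs a
stopping rule. The geometric evaluator asks whether the newly queried batch
still *differs* from the training set: embed the labeled pool, take its
centroid $O$ and the circle of radius $r$ (the 0.95 quantile of labeled
distances to $O$, configurable), project the queried batch, and count the
points with $d > r$. A count above $T = n/2$ ($n$ = number of classes) means
the batch brings genuinely new territory — continue; a count below $T$ means
the queries have converged onto known ground — stop, without buying that
batch's labels. An exact tie continues (training more is the safe side;
ties only arise for even $n$ since $T$ is fractional otherwise), and
`patience` consecutive sub-threshold batches can be required before stopping.

**Known limitation.** With a 10-item initial pool spanning all classes, the
0.95-quantile radius of the embedded labeled set already covers the
inter-class region where margin-uncertain queries live, so on the built-in
benchmark the rule fires at the first iteration — far before the accuracy
plateau. The rule is sound as *plateau confirmation* (its original framing:
first iterate until performance stops improving, then verify the plateau is
not local), but as a from-scratch stopping criterion under a linear embedding
it is premature. We report this honestly rather than patching it with a
burn-in heuristic; `apply_threshold_stop()` lets you replay the rule over any
recorded run and judge for yourself, and `T_override`, `radius_quantile` and
`patience` are exposed.

## SavedRate

Labeling cost is summarized as $SR = 1 - EA/FS$: `EA` expert-annotated
labels actually bought before reaching the target performance, `FS` the full
label budget of the dataset. `saved_rate(160, 1020)` — a run that needed 160
labels of a 1020-sample pool — gives $SR = 0.843$. Two run modes produce
`EA`: *oracle-best* (stop when test accuracy first reaches a known ceiling;
a benchmarking device) and *threshold* (the geometric evaluator; no ceiling
knowledge). Report tables aggregate SR across seeds as mean ± sample
(n−1) standard deviation.

## The synthetic generator

Every stage is testable without instrument data through a generator that
emulates two kinds of nanopore data:

* **Blockade events** (`simulate_rna_event()`): seven classes — six signal
  classes with class-specific blockade levels (0.2, 0.35, 0.5, 0.6, 0.75,
  0.9 as fractions of the open-pore current) and log-normal dwell lengths
  (medians 100–180 samples, sdlog 0.3), plus one noise class mixing three
  heterogeneous shapes (spike train, drifting ramp, bounded random walk).
  The 0.5 and 0.6 classes use a multi-level shape (2–3 sub-levels, offsets
  of sd 0.08) so their event means overlap and form a genuinely confusable
  pair. Flat-shape samples are i.i.d. Gaussian around the class level, so an
  event's sample mean concentrates as $\sigma/\sqrt{n}$.
* **Long traces** (`simulate_long_trace()`): events separated by open-pore
  baseline (level 1.0), with exact half-open ground-truth boundaries; event
  samples are capped at 0.97 so threshold segmentation at 0.985 recovers
  boundaries exactly on noiseless baselines.
* **Barcode trains** (`simulate_barcode_trace()`): 3-bit codes '000'–'111'
  as peak trains — start delimiter, three bit slots, end delimiter — with
  ±20% width/gap jitter, always ≤ 700 samples before padding.

What the generator does *not* emulate: sampling-rate and event-detection
physics, baseline drift and flicker noise, class imbalance beyond the noise
fraction, and annotator ambiguity (the supervisor's mislabel model is
uniform, not difficulty-dependent). Passing tests on this generator
demonstrate the machinery is correct and the comparative claims hold under
controlled conditions; they do not by themselves establish effect sizes on
instrument data.

## Signal processing and features

Classifier inputs come in two forms. Feature-based models use the fixed
11-statistic vector (`feature_names()`): length, mean, median, std, min,
max, range, skewness, kurtosis, noise (sd of first differences), and area
(sum of samples) — standard dwell/level/noise descriptors, computed on the
raw unpadded event with population (n) moment denominators and excess
kurtosis. The set is declared centrally so it can be swapped wholesale.
Raw-signal models take fixed-length inputs from `pad_to_length()`: 700
samples, shorter events padded with i.i.d. Gaussian noise (μ = 0,
σ = 0.072), longer events head-truncated (the identity of a barcode train is
front-loaded). Segmentation is threshold-run extraction — maximal runs below
the open-pore threshold, minimum length 10 — which is a deliberate stand-in
for hardware event detection, not a model of it.

## Numerical and design choices

* **Benchmark sizes.** The shipped benchmark uses a 600-item pool, 600-item
  test set, 10 initial labels, batches of 10 and 10 replicate seeds; a
  random-forest fit on ≤ 610 × 11 features takes tens of milliseconds, so a
  full 59-iteration curve costs about a second and the whole comparison
  suite a few minutes on one core.
* **Initial pool.** The 10 seed labels are a uniform random draw, not
  stratified — matching how a practitioner would bootstrap from an unlabeled
  pile — so early labeled pools can miss classes; the classifier adapter
  pads missing classes' posteriors with zeros.
* **Determinism.** Every stochastic entry point takes a seed and restores
  the caller's RNG state; per-iteration seeds are derived from the run seed.
  Ties in batch selection break toward the smallest pool index.
* **Degenerate inputs.** Constant events get skewness/kurtosis 0; a
  degenerate pool (all equidistant from $O$) gets all bias weights 1; a
  single-class labeled pool yields a trivial always-that-class model.
* **Classifier default.** `rf_classifier()` (100 trees) on the 11 features.
  The probabilistic-classifier contract (`al_classifier()`) accepts any
  `fit`/`predict_posteriors` pair, including deep models on padded
  700-vectors; none is bundled because the package's claims are about the
  query loop, not a particular network.
* **AUC.** Multi-class AUC is the macro average of one-vs-rest AUCs
  (computed with pROC), reported as `NA` when the truth is single-class.
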