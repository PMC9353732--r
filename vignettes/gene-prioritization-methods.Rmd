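---
title: "Methods: graph-convolutional gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-convolutional gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gcnprio)
```

## The model

`gcnprio` scores genes for disease relatedness by semi-supervised node
classification on a weighted gene-interaction network. Inputs are (i) an
undirected graph whose nodes are candidate genes and whose positive edge
weights are functional-association confidences (log-likelihood-score-like),
(ii) a per-gene real-valued feature matrix (tissue-expression-like), and
(iii) balanced positive/negative gene lists. Genes with no interactions carry
no network evidence and are pruned before encoding (`prune_isolated()`),
with the removed identifiers reported.

**Encoder.** Every graph-convolution layer applies the self-loop-augmented,
symmetrically degree-normalized operator

\[
\hat A = D'^{-1/2} (A + I)\, D'^{-1/2}, \qquad D' = \mathrm{diag}\big(\textstyle\sum_j (A+I)_{ij}\big),
\]

followed by a trainable linear map and ReLU: \(X_{l+1} = \mathrm{ReLU}(\hat A X_l W_l)\).
\(\hat A\) is symmetric with spectrum in \([-1, 1]\) (verified by property
tests), so stacking layers neither explodes nor oscillates; a depth-\(N\)
stack makes each gene's embedding a function of its \(\le N\)-hop
neighbourhood, which the tests check literally on path graphs. Depth is
restricted to 1–4 — the range the ablation harness explores — unless forced.

Two modelling points were genuinely open and are resolved as follows:

* *Normalization symmetry.* The symmetric form \(D'^{-1/2} A' D'^{-1/2}\) is
  used. An asymmetric variant \(D'^{1/2} A' D'^{-1/2}\) is not a similarity
  rescaling of the graph and loses the spectral guarantees above; the
  symmetric operator is the standard graph-convolution propagation rule and
  is what the rest of the package assumes.
* *Trainable layer weights.* Each layer carries its own weight matrix \(W_l\)
  (no bias). Without per-layer weights, stacking would be pure smoothing and
  the depth ablation would be meaningless; with them the encoder genuinely
  learns feature mixing.

**Decoder.** Each gene's embedding is treated as a one-channel 1-D signal and
passed through four convolutional blocks — kernel size 3 with filter counts
32, 64, 32, 16, each followed by batch normalization and ReLU — then
flattened, passed through dropout and one fully connected layer to two
softmax logits. Classification is per gene, so the convolutions run along
the embedding dimension of one gene at a time (a batch of genes is processed
in parallel, but no information crosses genes except through batch-norm
statistics during training). Padding, stride and pooling are not dictated by
the architecture table we follow, so the decoder uses same-padding, stride 1
and no pooling: embeddings are short (default 32), and downsampling would
discard most of the signal.

**Loss.** Binary cross-entropy on the positive-class probability,
\(-y\log p - (1-y)\log(1-p)\), averaged over the labelled batch (mean rather
than sum, so the learning-rate schedule is independent of the number of
labelled genes). Probabilities are clipped into \([10^{-7}, 1-10^{-7}]\)
before the logarithms. With a two-logit softmax this equals two-class
cross-entropy, and its closed forms (e.g. \(\log 2\) at \(p = 0.5\)) are
asserted in the tests to \(10^{-12}\).

## Training

Full-batch Adam (\(\beta_1 = 0.9\), \(\beta_2 = 0.999\),
\(\epsilon = 10^{-8}\)) for 50 epochs; learning rate 0.01, reduced to one
tenth after 40 epochs (`lr_at()` exposes the schedule; the recorded per-epoch
history is asserted to match it exactly). One gradient step per epoch is
appropriate at the few-hundred-gene scale. Dropout (rate 0.5) acts once,
between the flatten and the fully connected layer, only in training mode.
Batch normalization uses per-channel statistics with running-stat momentum
0.1; training uses the batch statistics of the labelled training genes (the
batch the loss sees), inference uses the stored running statistics, which
makes prediction deterministic — asserted bitwise in the tests.

Everything random — Glorot-uniform weight initialization, dropout masks, fold
assignment, negative-sampling in the generator — is driven by one master seed
per run; per-fold child seeds are drawn deterministically from it. Two runs
with the same seed produce bitwise-identical loss histories and reports.

The decoder's fused forward/backward pass is implemented in compiled code
(RcppArmadillo) because a 10-fold cross-validation of 50-epoch trainings is
dominated by the conv-block algebra. Computation there runs in single
precision — the standard training precision for models of this kind — while
parameters, gradients and the Adam state are kept in double precision on the
R side (mixed precision with double master weights). The user-facing
`decode()` keeps a pure double-precision R forward pass, asserted to agree
with the compiled path to \(10^{-5}\); gradients are verified through a
double-precision R reference backward that is itself checked against central
finite differences, with the compiled step asserted against that reference.

## Evaluation

Cross-validation is stratified 10-fold and transductive: the graph and
feature matrix stay whole in every fold and only the held-out genes' labels
are masked (removing nodes would change \(\hat A\) fold to fold, conflating
graph perturbation with label masking). Fold assignment deals each class
round-robin after a seeded shuffle, carrying the dealing position across
classes so total fold sizes differ by at most one — at 284 genes and ten
folds this yields four folds of 29 and six of 28, each near-balanced.

ROC curves sweep every distinct score as a threshold (ties form one step) and
record (FPR, recall) anchored at (0,0) and (1,1); precision–recall curves
record (recall, precision) with the zero-prediction end anchored at precision
1 by the standard convention. Areas are trapezoidal over the achieved points;
for ROC this equals the tie-corrected Mann–Whitney statistic, which the tests
verify pairwise to \(10^{-10}\) (and cross-check against pROC). AUPR is
deliberately the trapezoid over achieved points, not interpolated average
precision — the two differ and only the former matches a curve-area reading.
AUC/AUPR are computed per fold and averaged; pooled-prediction variants are
reported alongside, since which of the two a printed number refers to is often
ambiguous in the literature.

Baselines run on shared folds with shared seeds: the encoder with a linear
softmax head (GCN-only), the convolutional head on raw features (CNN-only),
a 500-tree random forest, and 5-nearest-neighbours on per-fold-standardized
features. These settings are fixed, not tuned.

## The synthetic benchmark

`generate_benchmark()` draws a two-block stochastic graph: edges within a
class appear with probability `p_within = 0.3`, across classes with
`p_between = 0.075` (a 4:1 homophily ratio), weighted by log-normal draws
(meanlog 0.5, sdlog 0.5 — positive and right-skewed, the shape of
log-likelihood association scores). Features are i.i.d. Gaussian per gene
with class means separated by `effect_size = 2` standard deviations across
all 32 features. Defaults are 284 genes, half positive, mirroring the scale
of a curated disease-gene study (142 positives plus 142 sampled negatives),
so cross-validation fold arithmetic matches that setting. Generation is
deterministic given the seed, and the tests confirm the planted parameters
are recovered empirically (edge frequencies within three standard errors at
500 genes; class-mean separation within sampling error).

What the generator does *not* emulate: hub-dominated degree distributions of
real interaction networks, correlated tissue-expression structure, unbalanced
label sets, or label noise. Passing the recovery checks therefore shows the
pipeline learns planted homophily-plus-feature signal correctly — it does not
certify performance on real curated data. At the default settings the signal
is strong (a 2-sd shift in each of 32 independent features is ≈11 sd of
combined separation), so all methods saturate near AUC 1; the companion null
benchmark (`effect_size = 0`, `p_within = p_between`) verifies the other side,
staying at chance level (the acceptance script computes ≈0.48–0.55 across
seeds with ten folds of ~28 test genes, within the expected spread around
0.5).

## Numerical and design choices

* Hidden width defaults to 32, matching the feature dimension of the default
  benchmark and keeping the parameter count (~30k) proportionate to a
  ~284-gene training set; it is configurable (`hidden_dim`).
* Duplicate edge records collapse to the maximum weight (deterministic and
  order-independent); self-interaction records are rejected rather than
  silently dropped. Node order is first-appearance order in the input and is
  recorded in every output for cross-file auditability.
* Raw edge weights are used as-is; a min–max rescale to (0, 1] is available
  behind `rescale_weights` for networks whose score scales are extreme.
* The self-loop adds exactly 1 to each diagonal even though off-diagonal
  weights live on the association-score scale; degree normalization then
  guarantees \(D'_{ii} \ge 1\), so the operator is always well defined.
* The graph Laplacian \(L = D - A\) is exposed (`graph_laplacian()`) as a
  structural descriptor and for testing; the forward pass never uses it.
* Feature columns are z-scored over all nodes before training
  (`standardize = TRUE`), an unsupervised transform consistent with
  transductive evaluation.
* Batch-norm \(\epsilon = 10^{-5}\); probability clipping \(10^{-7}\);
  Glorot-uniform limits \(\sqrt{6/(n_{in}+n_{out})}\).
* Undefined threshold metrics (zero denominators) signal a typed warning and
  return `NA`; curve code substitutes the standard precision-1 anchor.

## Problem sizes used by the tests

Unit and property tests run on graphs of 1–8 nodes (including every
unit-weight graph on up to 5 nodes against an entrywise oracle) and
benchmarks of 20–500 genes. The signal-recovery and trend checks use the full
study-scale setting — 284 genes, ten folds, five seeds for both the signal
and null benchmarks — and the acceptance script reruns the depth ablation and
the five-method comparison at that same scale.

## Limitations

* Transductive only: a trained model scores the genes of the graph it was
  trained on; there is no inductive out-of-graph prediction.
* No uncertainty quantification on AUC/AUPR (no DeLong tests or confidence
  intervals) — reports carry per-fold spreads instead.
* The planted benchmark saturates at the default effect size; depth and
  method comparisons on it show ties at the ceiling rather than the graded
  differences one would expect on noisy real data.
* Binary classification only; no multi-disease or multi-class extension.
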