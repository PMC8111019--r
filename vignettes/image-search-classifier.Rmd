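---
title: "Image search as a classifier: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image search as a classifier: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxrsearch)
```

## The method

`cxrsearch` implements content-based image retrieval used *as a classifier*
for pneumothorax screening on frontal chest radiographs. Rather than
training an end-to-end classifier, the pipeline tags every archived image
with a descriptor, retrieves the `k` archived images nearest to a query
under Euclidean distance, and reports the fraction `m/k` of retrieved
images labelled positive as the query's class likelihood. The attraction of
this design in a clinical setting is explainability: alongside the
likelihood, the system can surface the matched historical cases themselves.

Three descriptor configurations exploit the approximate bilateral symmetry
of the thorax:

* **Configuration 1** — one backbone descriptor of the whole image
  (1024 values with the default 1024-wide backbone contract);
* **Configuration 2** — descriptors of the left half and of the
  *horizontally flipped* right half, concatenated (2048 values). Flipping
  acts as a coarse registration: on a symmetric thorax the two halves
  align, so a one-sided pleural abnormality shows up as a descriptor
  mismatch;
* **Configuration 3** — both halves plus the whole image (3072 values),
  fixed segment order `[left, right_flipped, whole]`.

The backbone is a frozen, pluggable contract (`backbone()`): any
deterministic map from a 224×224×3 array to a fixed-length vector, such as
the global-average-pooled final convolutional layer of a DenseNet-121-style
network. The package ships a deterministic *stub* backbone (32×32 block
means followed by a fixed seeded projection to 1024 values) so that every
stage is exercisable, byte-reproducibly, without pretrained weights.

## The autoencoder compressor

Concatenated descriptors are long; the compressor reduces the 3072-value
configuration-3 vector to a 256-value code (a 12-fold reduction) in two
steps, both with the Adam optimizer, batch size 128, 10 epochs, and
dropout 0.2 after every non-final layer:

1. **Unsupervised pre-training.** A symmetric autoencoder (default funnel
   3072 → 1024 → 512 → 256, mirrored decoder) is trained with outputs set
   equal to inputs under mean-squared-error loss.
2. **Class-weighted supervised fine-tuning.** The decoder is removed and a
   one-unit sigmoid head appended after the bottleneck. Training minimizes
   binary cross-entropy with per-class weights
   `W_cj = S / (C · S_cj)` (`S` samples, `C` classes, `S_cj` samples in
   class `c_j`), which makes each class contribute the same total loss mass
   — essential at ~6% prevalence. After training the head is removed; the
   remaining encoder is the deterministic compression map.

The weights of the final epoch are used as-is (no early stopping). A
per-epoch train/validation loss history is recorded; the validation split
is a seeded 10% hold-out of the training archive.

Design points the source description left open, decided here:

* hidden widths between 3072 and 256 are not fixed by the architecture
  summary; we use a geometric taper (1024, 512), configurable via
  `encoder_spec()`;
* hidden activations are rectified-linear; the decoder output is linear;
  the only named activation (the sigmoid head) is kept as specified;
* the 256-value code is taken *after* the bottleneck activation — the same
  signal the decoder and head saw during training;
* the learning rate is the Adam convention, 1e-3, recorded in the spec.

The engine itself (forward/backprop, inverted dropout, Adam) is implemented
in base R matrix algebra on BLAS; training is exactly reproducible from the
spec seed (initialization, shuffling, dropout masks and the validation
split all derive from it).

## Search, voting and evaluation

Retrieval is an exact exhaustive Euclidean scan — no approximate index —
with distance ties broken by archive insertion order, so results are fully
deterministic. `k` larger than the archive clips to the archive with a
truncation flag, and the vote uses the effective retrieved count.

Evaluation follows the retrieval protocol end to end under stratified
tenfold cross-validation (`run_cv()`): each fold in turn is the query set,
the other nine folds are the archive, and — in `autothorax` mode — the
encoder is trained from scratch on that fold's archive only, so no query
information leaks into the compressor. Stratification by label is our
choice (the protocol description says only "divided into 10 groups"):
at 6% prevalence an unstratified small sample can easily leave a fold
without a single positive.

ROC curves are computed over the `m/k` likelihood grid with the `>=`
decision rule, thresholds at midpoints between consecutive unique scores
plus sentinels; AUC is trapezoidal, equal to rank concordance with ties
credited 1/2. The operating point is the Youden maximizer
(J = sensitivity + specificity − 1), ties resolved toward the smaller
threshold (higher sensitivity). The Youden threshold is selected on the
same validation fold it is reported on, matching the protocol as described
— an optimistic convention, noted as such. Paired per-fold comparisons use
a two-sided Wilcoxon signed-rank test with mid-ranks for ties, exact by
sign-flip enumeration (via a rank-sum convolution) up to 25 non-zero
differences and tie-corrected normal approximation beyond.

The PCA baseline (`pca_compress()`, via `stats::prcomp`) is the optimal
*linear* compressor at a given width; the package's comparison workflow
(`run_cv(..., mode = "pca")` plus `wilcoxon_paired()`) reproduces the
autoencoder-versus-PCA experiment shape.

## What the synthetic generators emulate — and what they do not

The original experiments draw on three public corpora of 551,383 frontal
radiographs at roughly 6% pneumothorax prevalence; those data are not
shipped or downloaded. Two generators stand in:

* **Thorax phantoms** (`generate_phantoms()`): mirror-symmetric base
  anatomy (elliptical lung fields, mediastinal band, rib-like sinusoidal
  texture, all functions of the distance to the midline) plus additive
  Gaussian pixel noise; positives carry a darkened pleural crescent of
  configurable contrast (default 0.35) and width (default 0.12 of the
  image side) on one randomly chosen side. The construction makes the
  left/flipped-right symmetry assumption *literally* true for negatives
  and broken for positives — it validates the plumbing and the symmetry
  logic, not radiographic realism. Real radiographs have patient
  positioning variation, exposure differences, devices and chest tubes,
  and far subtler pleural lines; phantom results therefore bound what the
  pipeline can do on clean signal, nothing more.
* **Feature clusters** (`generate_feature_clusters()`): two unit-variance
  isotropic Gaussian classes in 3072 dimensions whose mean difference is
  confined to a 256-dimensional informative subspace with norm
  `separation` (default 6) at 6% prevalence. This emulates the key
  statistical property the compressor exploits — discriminative signal
  concentrated in a subspace no larger than the bottleneck. On the oracle
  projection the Bayes AUC is `pnorm(separation / sqrt(2))`; real deep
  features are neither Gaussian nor isotropic, and their informative
  structure is not axis-aligned.

Default study sizes were chosen once for desk-scale runs: the feature
benchmark uses n = 2000 at the full 3072 dimensions with a reduced encoder
funnel 3072 → 512 → 256 → 128 → 64 (tenfold CV trains the encoder ten
times; the default funnel remains 3072 → 1024 → 512 → 256); the phantom
benchmark uses 300 images at 224×224. Toy-scale training tests shrink
batches rather than the data so the optimizer takes a step count
comparable to corpus-scale epochs.

## Numerical and degenerate-input conventions

* Bilinear resizing uses centre-aligned sampling with border clamping and
  no anti-alias prefilter; an input already at the target size passes
  through unchanged; odd widths split as (floor, ceil) and concatenation
  reproduces the input exactly.
* Grayscale views are replicated to three channels at extraction time;
  input normalization is owned by the backbone plugin.
* No feature normalization is applied before search (raw Euclidean
  matching).
* `positive_fraction` materializes as exactly `round(n · fraction)`
  positives.
* Class weights require strictly positive counts; `Σ W_cj · S_cj = S`
  holds to floating-point precision.
* Encoder training aborts with the epoch index on non-finite loss.
* `knn` requires matching dimensions; empty archives cannot be indexed;
  an empty store encodes to an empty store.

## Known limitations

* The stub backbone is linear in coarse pixel statistics; it demonstrates
  the pipeline, not transfer-learning performance. Plug a real pretrained
  extractor into `backbone()` for imaging studies.
* Fold-local Youden thresholds are optimistic relative to carrying a
  threshold from a disjoint tuning split.
* The exhaustive scan is O(n·d) per query — appropriate at desk scale;
  an approximate index would need tie-identical validation against it.
* Phantom realism is deliberately minimal (see above); no DICOM handling,
  lung segmentation or lesion localization is provided.
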