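---
title: "Methods: a binarized depthwise-separable ECG beat classifier and its integer-only inference algebra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binarized ECG beat classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bitbeat)
```

## The model

`bitbeat` implements a five-class heartbeat classifier whose weights and
activations are all single bits. A beat is a 300-sample window (100 left,
200 right of the annotated R peak, at 360 Hz) rendered as a 32×32 binary
image; the network is

* conv1: 3 binary 3×3 kernels, valid convolution, stride 1, activation
  `binarize(x) = 1 iff x > 0`, **no batch norm** — the threshold is exactly 0;
* 2×2 max-pool, stride 2 — on bits this is a logical OR;
* depthwise 3×3 per channel (integer popcounts, held as small integers, not
  binarized) + pointwise 1×1 to 18 channels, batch norm, binarize;
* FC1: 13·13·18 image features plus a 4-bit RR code → 32 units, batch norm,
  binarize;
* FC2: 32 → 5 classes, batch norm, softmax (training) / argmax (deployment).

Two fixed conventions matter downstream. First, class order is N, S, V, F, Q
everywhere and argmax ties break toward the earliest class. Second, the
flattened FC1 feature order is channel-major (channel, then column-major
position), with the RR bits appended last; the blockwise engine relies on
owning exactly the rows of one position.

The 4-bit RR code width makes the FC1 input 13·13·18 + 4 = 3,046 wide —
four auxiliary inputs beyond the image features. This is deliberately the
narrowest code that still separates the rhythms of interest: the preceding
RR interval is normalized by the record-median RR and quantized as
`round(8·ratio)` clamped to 0…15, so a nominal interval maps to 8 and the
~60% interval typical of a premature supraventricular beat maps to 5.
Supraventricular ectopy has essentially normal morphology; without the RR
code the S class is not learnable from the image alone.

## Why the first layer has no batch norm

The merged convolution–pooling rewrite below requires the identity
`binarize(popcount) = OR` — which holds only when the activation threshold
is 0. Keeping conv1 free of batch norm is therefore a structural
commitment, not an omission: it is what licenses replacing
conv → binarize → pool with a single pass at deployment.
`build_mcpk()` refuses to merge across a nonzero threshold for the same
reason, with an explanatory error.

## Merged convolution–pooling

For a `KO×KO` kernel at stride `SO` followed by a `P×P` OR-pool at stride
`SP`, the merged kernel ORs `P²` copies of the kernel shifted by `SO` in
each direction:

* size `KR = KO + SO·(P−1)`, stride `SR = SO·SP`;
* anchor convention: the original kernel's (0,0) sits at the merged frame's
  (0,0); shifts go down/right;
* any merged weight equal to 0 can be pruned — it can never influence an
  OR-reduction; `prune()` returns the surviving positions and the pruned
  application is exactly equal to the dense one.

The equivalence is exact on bits, and the test suite verifies it
exhaustively over all 2^16 4×4 images × 50 random kernels and on 10,000
random 32×32 images. Operation accounting uses a 2-operations-per-window
convention for the baseline's 2×2 pooling step (comparator trees cost one
OR-level per pair), giving 30²·3·9 + 15²·3·2 = 25,650 baseline operations
against 15²·3·16 = 10,800 merged ones at the default geometry.

## Blockwise incremental inference

The layerwise engine materializes every feature map. The blockwise engine
instead walks the `MD×MD = 13×13` output grid; output position (i, j) is
fed by the 8×8 input window starting at (2i, 2j) (in general
`KR + SR·(KD−1)` on a side). Each block yields a 3×3 bit-grid per channel
(MCP), one popcount per channel (depthwise), 18 bits (pointwise +
threshold), and those bits select FC1 weight rows that accumulate into the
32 FC1 sums. Because integer addition commutes, the accumulated FC1
pre-activations are *bit-identical* to the layerwise ones — this is a
theorem about the implementation, and the suite checks it on 1,000 random
weight/image draws plus a degenerate single-block geometry.

Latency is modeled analytically, one listed micro-step = one cycle:
`L = MC² + 2·MD² + KP·MD²` layerwise (= 3,605),
`LB = (KD² + 1 + 1 + KP)·MD²` blockwise (= 4,901), and with the next
block's feature extraction overlapped under the current FC1 work,
`KP·MD²` (= 3,042). The simulator reports model cycles, never wall-clock,
and excludes control overhead by construction; the pipeline overlap is
modeled by the closed form rather than an event simulator because the
formula fully determines the quantity. Storage is counted per stage:
{1024, 675, 507, 3042, 3042} elements layerwise vs {64, 27, 3, 18, 18}
blockwise.

## Batch-norm folding and the FC2 lookup table

Batch norm normalizes `x̂ = γ(x−μ)/√(σ²+ε) + β`. When a binarization
follows and the pre-activation `s` is an integer, the whole stage is one
comparison: for γ > 0, `x̂ > 0 ⇔ s > ⌊μ − β·√(σ²+ε)/γ⌋`. The floor is
taken (not round-half), because `s > t ⇔ s > ⌊t⌋` for integer `s`. For
γ < 0 the comparison flips (`s < ⌈t⌉`), which `fold_bn_threshold()`
handles and flags; γ = 0 is not invertible and errors. The equivalence is
checked exhaustively over s ∈ 0…200 for hundreds of random parameter
draws, including negative γ.

FC2 is followed by batch norm but not by a binarization, so it folds into
a lookup table instead: each class's popcount can only take the integers
0…(number of set weights), so all attainable outputs are precomputed in
software at fold time. Two views of the table exist:

* `build_fc2_lut()` returns the hardware view: entries quantized to 13-bit
  signed fixed point with 6 fractional bits (step 1/64), erroring on
  overflow. Six fractional bits keep the batch-norm output ranges a
  trained model produces representable within 13 bits.
* the folded model also stores the exact entries as computed, and
  classification compares those. Rounding to a 1/64 grid is monotone and
  can therefore never swap two entries, but it can collapse a pair closer
  than the quantization step into a tie; comparing the exact stored
  values instead makes the invariant "folded and reference models agree
  on every input" hold exactly rather than almost always. Inference
  remains integer-only in the operational sense — AND, popcount,
  accumulate, compare, table lookup; no arithmetic on reals happens at
  inference time, only comparisons of constants precomputed at fold time.
  Since argmax is invariant under any shared monotone reading of the
  table, where the comparison happens is immaterial to the result.

Strict mode additionally checks the declared register widths (4-bit
depthwise popcounts, 12-bit FC1 accumulators, 5-bit FC2 popcounts,
13-bit table entries) and warns on violation; strict and default modes
always classify identically.

## Training

The reference network trains with the straight-through estimator, the
standard recipe for binarized networks:

* latent real weights, binarized at `> 0` in every forward pass; the
  gradient of the binarization is passed straight through inside the unit
  window (`|pre-activation| ≤ 1` after batch norm; popcount ≤ 1 for the
  batch-norm-free first layer) and latents are clipped to [−1, 1];
* latents initialize uniformly in ±0.1 so early steps can flip weight
  signs (Adam's per-parameter step is ≈ the learning rate, so a ±1 init
  would need a thousand steps per flip);
* Adam, cosine learning-rate decay 10⁻³ → 10⁻⁴, cross-entropy loss,
  batch size 128, early stopping on validation loss with patience 10,
  best weights restored;
* batch norm uses batch statistics during training; running statistics
  (used for inference and folding) are seeded from the first batch and
  then tracked with momentum 0.9, so even short trainings fold with
  calibrated statistics;
* OR-max-pool routes gradient to the first window cell attaining the
  maximum; every stochastic choice is seeded.

Softmax exists only on the training/reference path; deployment
classification is the argmax of the FC2 batch-norm outputs, to which
softmax is monotone.

## The synthetic generator, and what passing tests do not show

Real annotated ECG archives cannot be bundled, so the package carries a
phenomenological beat generator: each beat is a sum of five Gaussian
bumps (P, Q, R, S, T) with class-specific nominal amplitude/offset/width
tables, ±10% per-beat jitter, and white noise at 20 dB SNR. Ventricular
beats widen the QRS and drop the P wave; fusion beats average the N and V
tables; unknown beats draw a randomized morphology; supraventricular
beats share the N morphology and are expressed through a preceding RR
interval at 60% of the nominal 0.8 s (±8% jitter). The R peak is pinned
to the annotated sample so annotations are exact.

The generator emulates the *structure* of real recordings — 360 Hz
sampling, annotated peaks, class-dependent morphology and rhythm — and is
deliberately easy: classes are separable by construction, which is what
makes it a fitness test for the pipeline (a seeded 2,000-beat run must
exceed 60% five-class accuracy against a 20% chance floor; in practice it
reaches ~90%). It does not model baseline wander, electrode artifacts,
lead placement, inter-patient morphology drift, or the extreme class
imbalance of clinical data. Passing on synthetic beats therefore
validates the implementation — the algebra, the training loop, the
integer datapath — not clinical performance; accuracies on real archives
are a property of data and training, and the package makes no claim about
them beyond supporting such runs through the same CSV reader.

## Preprocessing conventions

The rasterization of a beat is underdetermined by any verbal description,
so the package fixes one: normalize the 300 samples to a 128-row canvas
(minimum amplitude at the bottom row; a flat trace maps to the middle
row), draw a 1-px connected polyline between consecutive samples, and
block-max downscale to 32×32 (rows in blocks of 4, columns in floor-spaced
blocks of 9–10). Block-max rather than area-averaging is essential at
this resolution: an averaged thin trace would vanish under a 0.5
threshold. This is a declared convention, not a reconstruction of any
particular tool's resampling.

Z-score augmentation balances training classes by re-dressing z-scored
copies of minority-class beats with perturbed moments (μ′ uniform in
μ ± 0.1σ, σ′ uniform in σ·[0.9, 1.1]); small perturbations preserve class
identity. Augmentation never touches validation or test partitions.
Splitting is patient-specific by default — within each record, 70% train,
then 30%/70% of the remainder to validation/test (net 70/9/21), matching
integer rounding per record — or patient-wise, assigning whole records to
partitions, as a configuration option. The first beat of a record, which
has no preceding interval, takes the record-median RR rather than being
discarded.

## Numerical and degenerate-input choices

* Undefined metric ratios (zero denominators on degenerate confusion
  matrices) are reported as `NA` with a warning, never silently 0;
  display rounding is 2 decimals, round-half-even; raw ratios are always
  available.
* Records with fewer than 2 beats go wholly to train (with a warning)
  under patient-specific splitting.
* A degenerate flat beat still renders (single middle row); an all-zero
  image classifies deterministically from thresholds and table entries.
* Training aborts with a diagnostic on non-finite loss.
* Accumulators: FC1 sums are bounded by the 3,046 inputs; the 12-bit
  hardware width is checked in strict mode rather than assumed.

## Problem sizes in the test suite

The suite runs at desk scale by choice: exhaustive 4×4 enumeration
(65,536 images × 50 kernels) plus 10,000 random full-size images for the
merge theorem; 1,000 random draws for blockwise and integer/float
agreement; one 2,000-beat end-to-end training (30 epochs, batch 128) for
the pipeline fitness check. These sizes make every claim checkable in a
few minutes on one CPU while keeping the properties exact — the
equivalence tests are bitwise, with zero tolerance.

## Known limitations

* The generator's separability means reported synthetic accuracies say
  nothing quantitative about clinical data (see above).
* The latency model counts idealized micro-steps; real control logic adds
  overhead that is out of scope here.
* WFDB binary archives are not parsed; records enter through the CSV
  sample/annotation representation (the synthetic writer emits it, and
  converting real records to it is a one-liner in any WFDB tool).
* Training in plain R is minutes-scale for thousands of beats; the
  package is a reference implementation and verification harness, not a
  high-throughput trainer.
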