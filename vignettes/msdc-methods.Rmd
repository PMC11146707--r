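---
title: "Multi-scale dilated convolution blocks for AF detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale dilated convolution blocks for AF detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmsdc)
```

## The problem and the model

Atrial fibrillation (AF) shows up in a single-lead ECG through three
linked signatures: the P wave before each QRS complex vanishes, a
low-amplitude 4–10 Hz fibrillatory (f-wave) oscillation appears in its
place, and the ventricular RR intervals become highly irregular and
serially uncorrelated. A 1D convolutional network can learn these
signatures directly from the raw trace, and a residual (ResNet-style)
stack of wide-kernel convolutions is the standard strong baseline.

Wide kernels are what make that baseline expensive: a block's weight
count grows linearly in the kernel size, while the receptive field —
the number of input samples that influence one output value — grows at
the same rate. The multi-scale dilated convolution (MSDC) block buys
the receptive field more cheaply. It replaces the single wide kernel
with several *parallel dilated branches*: each branch has a small
kernel whose taps are spread out by a dilation factor, and the branches
use different kernel/dilation combinations so they observe the input at
different scales. Branch outputs are concatenated on the channel axis;
because the branch filter counts sum to the residual block's 32
channels, an MSDC block is a drop-in replacement inside the residual
topology.

### Dilation convention

We follow the convention in which a *dilation factor* `d = 0` denotes a
plain convolution and the spacing between consecutive matched input
samples is `max(d, 1)`; `d = 0` and `d = 1` are therefore synonyms for
contiguous taps. This is the only reading under which the canonical
block table is internally consistent, and `tap_positions()` implements
it directly: branch `(k, s, d, f)` touches input offsets
`{i * max(d, 1) : i = 0..k-1}`.

### Receptive field accounting

`block_receptive_field()` counts the *distinct* input positions touched
when one output value is produced: the union of each branch's tap
positions, all branches anchored at offset 0. For the canonical blocks:

```{r}
architecture_report()
```

One published value is not reproducible: the four-branch block
(`msdc_b`) is listed with receptive field 13, but the union of its
printed branch tuples has 11 elements — the two `k = 1` branches
contribute only the anchor position regardless of their dilation
factors, so no reading of the printed tuples reaches 13 without also
changing the printed parameter count of 128. The analyzer returns the
rule's value and flags the discrepancy rather than hiding either
number. A perturbation oracle (randomly initialize the block with
linear response, wiggle each input cell, count which cells move the
output) independently confirms the tap-union arithmetic; the test suite
runs it on the canonical blocks and on randomly drawn ones.

### Parameter accounting

Two conventions are deliberately exposed.

* **Tabulated** (`block_param_count(b)`): `k * f` summed over branches.
  This is the design-stage bookkeeping used when comparing block
  designs; it ignores input-channel multiplicity and biases, and it
  reproduces the published per-block counts 512 / 224 / 128 / 256
  exactly.
* **Full** (`block_param_count(b, "full", in_channels)`): the
  engineering truth `in_channels * k * f + f` per branch, which is what
  the built model actually allocates. `network_param_count()` extends
  it to a whole network (stem, per-block normalization, shortcut
  projections, head) and is verified against `count_params()` on the
  built model — two independent code paths that must agree to the
  parameter.

Published *network-level* totals for the full-scale models (in "M"
units) are not derivable from the described 15-block stacks under
either convention, so only block-level counts are treated as
verifiable ground truth; the network-level claim we do check is
directional — at identical depth and schedule, every MSDC network
undercuts the residual baseline's full-convention count.

## The built blocks and networks

`build_block()` realizes a block as a pre-activation unit: one shared
batch normalization and rectifier on the block input, then the parallel
dilated branch convolutions, channel concatenation, and a shortcut that
adds the input (a pointwise projection when stride or channel counts
differ). We chose a *single shared* BN+ReLU rather than one per branch:
the two are equivalent in expressive terms (each branch still sees
normalized, rectified input before its convolution), and sharing keeps
the activation memory and compute of a four-branch block identical to
the single-branch case. The shortcut is retained because the MSDC block
is defined as a replacement *inside* the residual topology; whether the
original design also carried internal shortcut additions is not
recoverable, so the surrounding-residual reading is the conservative
one. Same-length zero padding is applied per branch (concatenation
requires equal branch lengths); a causal (left-only) padding mode
exists for linear-response analyses, and `padding = "valid"` errors
explicitly when the input is shorter than the largest branch span.
`k = 1` branches are pointwise convolutions — dilation is a no-op for a
single tap — which is exactly what preserves the printed count of 128
for the four-branch block.

`build_network()` stacks `n_blocks` identical-type blocks behind a stem
convolution, with temporal halving (stride 2 on all branches and on the
shortcut projection) at scheduled block indices, then a final BN+ReLU,
global average pooling over time, and a linear head. Global pooling
makes the head length-agnostic, so variable-length records batch by
zero-padding to the batch maximum. The full-scale configuration uses 15
blocks with halving every 4th block — the depth of the published
networks; the downsampling schedule itself is not specified there, and
halving every 4th block is our choice to keep 15-block activations
tractable. Weight initialization is fan-in-scaled Gaussian under a
user-supplied seed; two builds with the same spec and seed are
bit-identical.

The engine itself — im2col dilated convolutions (compiled via
RcppArmadillo), batch normalization, Adam, softmax cross-entropy — is
part of the package and is verified against naive-loop convolution
oracles and central-difference gradient checks in the test suite.

## The synthetic rhythm generator

The generator exists so that every downstream stage — windowing,
training, evaluation, the CLI — is testable at desk scale without any
data download. It encodes the class phenomenology, not cardiac
electrophysiology:

* **Sinus ("normal")**: RR intervals from a truncated normal law
  (default mean 0.8 s, CV 0.05; the class constraint is CV ≤ 0.08), a
  positive P bump before each QRS, no f wave.
* **AF**: RR intervals i.i.d. truncated lognormal (mean 0.7 s, CV 0.25;
  constraint CV ≥ 0.20 — irregular and serially uncorrelated), no P
  wave, and a frequency-jittered sinusoidal f-wave baseline at 7 Hz
  (amplitude 0.08 mV, the low end of coarse fibrillatory waves).
* **Other**: sinus with premature beats — a shortened interval followed
  by a compensatory pause, one concrete mechanism standing in for a
  heterogeneous class.
* **Noise**: band-limited Gaussian noise with no beat structure.

Beats are sums of Gaussian bumps for P/Q/R/S/T at fixed latencies; the
R peak is the global maximum. Sensor noise is Gaussian, band-limited to
0.1–40 Hz (the long-record regime's stated bandwidth), and outputs are
clipped to ±5 mV. Both study regimes are emulated: fixed 10-s segments
at 250 Hz (binary task) and 9–30 s records at 300 Hz (four-class task).
Everything is a pure function of `(params, fs, duration, seed)`.

What passing tests on this generator *do* show: the architecture can
learn the class-defining structure (irregular RR, absent P, f waves),
the protocol machinery (splits, early stopping, metrics) is correct,
and the whole pipeline is deterministic. What they do *not* show:
performance on real ECG — real recordings carry baseline wander,
electrode artifacts, ectopy, and inter-patient morphology variation the
generator deliberately omits, and the published real-data
sensitivity/specificity/F1 figures are not reproducible at desk scale.

The package's R-peak detector (used by the generator's own sanity
checks) band-passes into 5–25 Hz and thresholds local maxima, with a
crest-factor gate: QRS complexes are sparse spikes, so a signal whose
band-passed peak is less than 8× its median absolute amplitude is
treated as having no beat structure at all. The gate is what makes the
noise class yield essentially zero "plausible" R peaks rather than one
per threshold crossing.

## Windowing, splits, protocol

Long annotated records are cut into non-overlapping windows that
*restart at every rhythm boundary*: a window is emitted only if it lies
entirely inside one rhythm interval, so an interval of `L` samples
yields exactly `floor(L / (window_s * fs))` windows and no window ever
straddles a rhythm change. Non-overlap is the conservative reading of
the published segment counts; only purity is actually specified. The
binary label set treats `AFIB` as AF and everything else — including
atrial flutter and junctional rhythm — as non-AF. Intervals use
0-based, half-open `[start, end)` coordinates throughout.

Splits are 8:1:1 by largest-remainder rounding under a seed, optionally
stratified per class (ratio holds within one element per class). The
default split is segment-level, mirroring the published protocol; note
that segment-level splitting of windowed long records lets windows from
one patient appear on both sides of the split, which inflates
real-data estimates — a known property of the protocol being mirrored,
not of this implementation.

Training follows the published protocol by default: Adam at learning
rate 1e-4, at most 100 epochs, stopping when the best validation loss
has not strictly improved for 10 successive epochs (no minimum delta),
with the best-validation-loss weights restored. Cross-entropy over
softmax scores is our choice of loss (unstated in the source), with no
class weighting; batch size defaults to 64. Per-segment normalization
(zero mean, unit variance) is applied before the network.

## Desk-scale study conditions

The learning-sanity experiment trains the reduced 4-block variant of
each block type on 800 balanced synthetic AF/normal 10-s segments with
100 validation segments, batch 32, learning rate 1e-3, at most 8 epochs
(patience 3). The reduced geometry uses a stride-10 stem and temporal
halving at blocks 2 and 4: rhythm-scale structure survives 25 Hz
feature rates, and this keeps one full training run around a minute on
one CPU while the task remains comfortably learnable — all three block
types reach validation accuracy ≥ 0.95, typically 1.00 by the second
epoch. The higher learning rate relative to the full-scale default is
deliberate: at 4 blocks and 800 segments the loss surface is benign and
1e-4 merely slows convergence. A held-out sanity floor for the task
itself: a bare RR-interval CV threshold on detected peaks separates the
synthetic classes at ≥ 95% accuracy, so a network failing the criterion
would indicate an engine defect, not an impossible task.

## Numerical choices and degenerate inputs

* Batch normalization uses biased batch variance, momentum 0.9 running
  statistics, epsilon 1e-5; evaluation mode uses running statistics.
* Softmax cross-entropy clamps probabilities at 1e-12 before the log.
* Ties in argmax prediction resolve to the first (lowest-index) class.
* `split_811()` requires n ≥ 10 (three nonempty parts); `simulate_rr()`
  rejects mean RR ≤ 0.2 s as nonphysiological; segment durations are
  restricted to [1, 120] s; `window_record()` emits nothing for
  intervals shorter than one window rather than erroring.
* RR laws are truncated (sinus to [0.3, 2] s, AF to [0.25, 2.5] s);
  truncation biases the realized CV by far less than the 20% tolerance
  the generator promises over long durations.
* All randomness flows through explicit integer seeds; per-segment
  seeds derive from the master seed by a fixed affine map mod 2^31 - 1.

## Known limitations

* The engine is CPU-only and double-precision; full-scale 15-block
  training on 82k real segments is out of its intended range.
* The WFDB support covers format-16 signals and the annotation subset
  needed for rhythm labels (SKIP/AUX pseudo-annotations, '+' rhythm
  changes); exotic formats and beat-level annotations are not read.
* The single-file dataset container is an R serialization, chosen for
  zero-dependency portability within R rather than cross-language use.
* The "other" rhythm class is one mechanism (premature beats), not the
  heterogeneous reality of the four-class task's catch-all class.
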