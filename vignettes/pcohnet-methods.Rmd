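---
title: "Fused phase/amplitude connectivity and graph classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused phase/amplitude connectivity and graph classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state and task EEG contain two complementary kinds of coupling
between scalp channels: phase synchrony (how consistently two channels'
oscillations lead or lag one another) and amplitude coherence (how strongly
their spectral power co-varies). Classifiers for neuro-developmental
conditions such as ADHD often build a *functional connectivity matrix* from
one of these quantities alone. `pcohnet` implements a pipeline that fuses
both into a single connectivity index, turns it into a binary brain graph,
and classifies five-second EEG segments with a graph-convolutional network
(GCN) whose node features are learned per-channel time- and
frequency-domain encodings.

## Pipeline

1. **Preprocess** (`harmonize_montage`, `bandpass`, `resample_recording`,
   `segment_recording`): the 19-channel 10--20 montage is harmonized
   (T7/P7/P8/T8 renamed to T3/T5/T6/T4 and reordered), the signal
   band-passed to 0.5--60 Hz, resampled to 128 Hz, and cut into
   non-overlapping 5-s segments of 19 x 640 samples. A trailing partial
   window is discarded.
2. **Connectivity** (`pli_matrix`, `coh_matrix`, `pcoh_matrix`): per
   segment, the phase lag index `PLI_kl = |mean_m sign(dphi_kl(t_m))|`
   from Hilbert phases and the band-averaged magnitude-squared coherence
   `COH_kl = mean_f |S_kl(f)|^2 / (S_kk(f) S_ll(f))` are fused elementwise
   through `F(PLI + COH)`, where `F` maps [0, 2] onto [0, 1] by a
   continuous piecewise-exponential curve that shrinks small values and
   amplifies large ones.
3. **Binarization** (`select_threshold`, `binarize`): the fused matrix is
   thresholded at the value in {0.30, 0.31, ..., 0.70} that maximizes the
   small-worldness sigma of the resulting graph; entries greater than or
   equal to the threshold become edges.
4. **Node features** (`train_time_extractor`, `train_freq_extractor`): a
   single-layer LSTM (on standardized raw sequences) and a small 1-D CNN
   (on 640-point magnitude spectra) are trained per channel with shared
   weights, each emitting two pre-softmax activations per channel; stacking
   gives the 19 x 4 node-feature matrix.
5. **Classification** (`gcn_train`): a two-layer GCN with the symmetric
   normalization `D^{-1/2}(A + I)D^{-1/2}`, widths 16 and 32, neighborhood
   max-pooling after each layer, global mean pooling, a 64-unit
   fully-connected layer with 50% dropout, and two output units trained
   with cross-entropy and Adam.
6. **Evaluation** (`run_pipeline`): five-fold cross-validation with
   per-fold extractor and classifier training, accuracy/recall/precision
   with 1000-resample percentile bootstrap intervals, a Mann-Whitney U
   test on pooled fused-connectivity entries, and group-average
   connectivity maps exportable for brain-network viewers.

## Numerical and design choices

**Fusion mapping.** The denominator of `F` is `2e - 2`; this is the unique
reading under which the two exponential branches meet at `F(1) = 1/2` and
the stated range [0, 2] to [0, 1] holds exactly. The identity
`F(z) + F(2 - z) = 1` is used as a property test.

**Phase differences are wrapped.** PLI uses the difference of two wrapped
Hilbert phases, re-wrapped to [-pi, pi) before taking the sign. Without
this, a pair with a constant true lag would show spurious sign flips every
time the raw difference crosses +/- pi, and the analytic constant-lag case
would not reach PLI = 1.

**Zero-phase filtering.** The 0.5--60 Hz bandpass is a 4th-order
Butterworth applied forward and backward. Any phase-warping filter would
bias the very quantity PLI measures, so zero phase is non-negotiable here.

**Fourier resampling.** Downsampling truncates the spectrum at the new
Nyquist frequency and inverts at the new length: ideal anti-aliasing,
exact for the band-limited signals the bandpass stage produces, and free
of the passband gain error FIR polyphase designs can introduce.

**Coherence estimation.** Welch averaging (128-sample Hann windows, 50%
overlap, 9 windows per segment) is mathematically required: an unaveraged
periodogram makes magnitude-squared coherence identically 1. Two known
finite-sample effects matter for interpretation: under independence the
averaged coherence is biased to about `1/n_avg` (about 0.11 here), and in
general the estimate sits above the true coherence `C` by roughly
`(1 - C)^2 / n_avg`. The frequency average runs over the retained in-band
grid (0.5--60 Hz).

**Small-worldness.** `sigma = (C / C_rand) / (L / L_rand)` with `C` the
mean local clustering coefficient (nodes of degree < 2 contribute 0), `L`
the characteristic path length over connected pairs of the largest
component, and the reference the mean over 20 seeded uniform random graphs
with the same node and edge count. Computing `L` on the largest component
keeps sigma finite for fragmented graphs while clustering still penalizes
them. References are cached by (node count, edge count, seed): the
41-point threshold search re-uses the ensemble for every segment that
lands on the same density, which changes nothing numerically. If the
random reference has zero clustering while the graph does not, sigma is
reported as `+Inf` with a warning; edgeless binarizations score `-Inf`
in the threshold search, ties break toward the smallest threshold, and an
all-degenerate grid falls back to 0.5 with a warning.

**Thresholding is per segment** by default: each segment's own fused
matrix is searched, and its binarized graph is that segment's GCN input.
A `threshold_mode = "global"` variant computes one threshold from the
training-fold average matrix instead; both are exposed in
`pipeline_config()`.

**Per-channel extractors with shared weights.** The stated 19 x 2 outputs
are only consistent with applying one model per channel; the CNN's 5 x 5
kernel degenerates to a length-5 kernel on a height-1 per-channel input.
Features are the two pre-softmax output activations (post-softmax pairs
are redundant). Sequences are standardized per channel and segment before
the LSTM; spectra are max-normalized per channel before the CNN. The full
640-column two-sided magnitude spectrum is retained.

**GCN details.** The intermediate "pooling" stages preserve node count
(closed-neighborhood max-pooling) because the architecture still has 19
nodes at global pooling; global pooling is the mean over nodes. Weights
use fan-average uniform initialization; training clips the global
gradient norm at 5; the forget-gate bias of the LSTM starts at 1. All
training is bit-reproducible given a seed. Before the GCN, node features
are column-standardized with training-fold statistics - the same
stabilization applied at the extractor entrance, and computed only from
the training portion so no held-out information leaks.

**Cross-validation unit.** The default unit is the segment, matching the
practice of treating every 5-s epoch as a sample; because segments of one
subject then span folds, subject identity can leak across the split, so
`cv_unit = "subject"` is provided and tested. The bootstrap resamples
held-out (prediction, label) pairs rather than retraining.

**Mann-Whitney pooling.** The test pools individual upper-triangle fused
connectivity entries across segments per group (two-sided, tie-corrected,
normal approximation at these sample sizes). This is the reading under
which group differences of a few dozen coupled pairs among tens of
thousands of entries remain detectable.

## The synthetic cohort generator

No public accession is bundled, so every experiment runs on synthetic
cohorts (`cohort_spec`, `generate_cohort`) built from the two ingredients
the connectivity stage measures:

* **Shared lagged oscillators.** Each `coupling_spec` drives two or more
  channels from one band-limited (8--12 Hz) unit-variance source; the j-th
  channel receives it delayed by `(j - 1) * phase_lag` (a fractional-sample
  Fourier delay; an exact constant phase shift in the pure-sinusoid mode
  used for analytic tests). `mixing_weight` sets the fraction of the
  channel's oscillatory amplitude taken from the source; a channel in
  several couplings has its mixture renormalized to unit amplitude.
  Couplings of three channels form a clique from a single generator - the
  footprint of one neural source over an electrode cluster - which gives
  binarized graphs nonzero clustering, so the small-worldness search has
  something to optimize; isolated single edges would leave sigma undefined
  at every threshold.
* **Shared slow envelopes.** With `envelope_coupling > 0`, all channels of
  a coupling are modulated by one positive < 1 Hz envelope, raising
  coherence without forcing the phase index to 1.
* **Background rhythms and noise.** Every channel carries an independent
  band-limited oscillator whose center frequency follows a 6--14 Hz
  anterior-to-posterior gradient (`rhythm_gradient`), emulating the
  spatial spectral gradient of resting EEG. This gives each channel a
  recognizable spectral identity, which is what makes the learned node
  features informative about *which* region a node is - without it, all
  channels are statistically exchangeable and the GCN can only see degree
  sums. White noise with `noise_sd = 0.25` (a quarter of the oscillator
  scale) is added everywhere.

The default study conditions are 12 subjects per group, 60 s per subject
at 128 Hz (288 segments), with disjoint group coupling maps: a posterior
clique plus a parietal pair for controls (mixing 0.85), and for cases a
prefrontal clique, three further pairs (mixing 0.95) plus one *diffuse*
weak (0.45) central-parietal clique. The diffuse clique moderately raises
many pairwise entries - the broad elevation of resting-state connectivity
described for ADHD - and is what a rank test over all pooled entries
detects; focal relocation alone leaves the pooled distributions nearly
identical. These settings were fixed by probing the measurement physics
(PLI/COH of a coupled pair as a function of noise and mixing; the fused
values of coupled pairs must clear the 0.30 grid floor while uncoupled
pairs stay near 0.07--0.1) and are not tuned thereafter.

What the generator does **not** emulate: ocular/muscle artifacts, volume
conduction (zero-lag mixing), per-band connectivity differences, and
non-stationarity beyond the slow envelope. Passing recovery experiments
on these cohorts therefore demonstrates that the pipeline measures and
classifies the coupling structure it targets - not that it is robust to
clinical-grade artifacts.

## Experiment sizing

The recovery experiments run the full pipeline on the 288-segment default
cohort with a reduced training configuration chosen for a single-CPU
workstation: LSTM hidden size 16, 3 extractor epochs, 60 GCN epochs at
learning rate 1e-2. The package defaults in `pipeline_config()` remain
the standard operating point (hidden 128, 10 epochs, 100 epochs at 1e-3);
the larger desk-scale learning rate compensates for having roughly 400
optimizer steps instead of thousands. Under these conditions the pipeline
reaches perfect five-fold accuracy on the default cohort, the pooled
Mann-Whitney p-value is below 1e-100, and a segment-label permutation
control stays within the 99% binomial band around chance.

## Known limitations

* PLI on broadband (0.5--60 Hz) analytic phases mixes rhythms; per-band
  connectivity is out of scope.
* The Welch parameters (128/50%/Hann) are exposed but not adaptively
  chosen; coherence carries the finite-averaging bias described above.
* Segment-level cross-validation leaks subject identity by construction;
  use `cv_unit = "subject"` when subjects matter.
* The small-worldness reference model (uniform G(n, m)) is the standard
  choice but not the only one; degree-preserving rewiring is not
  implemented.
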