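---
title: "Hierarchical sparse coding of speech: model, statistics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical sparse coding of speech: model, statistics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmax)
```

## The model

`shmax` implements an unsupervised hierarchical sparse-coding network for
cochleogram-filtered speech, together with the analysis suite used to
compare its computing units with auditory-pathway physiology. The network
alternates two kinds of layers:

* **S layers (sparse coding).** Each S layer owns a dictionary of `m`
  atoms $b_j \in \mathbb{R}^{k \times k \times u}$ learned from random
  patches of its input by minimizing
  $$\sum_k \lVert x^k - B r^k \rVert_2^2 + \lambda \lVert r^k \rVert_1
    \quad \text{s.t. } \lVert b_j \rVert_2 \le 1,$$
  with $\lambda = 1$ by default. At inference each atom is
  cross-correlated with the input ("valid" region, stride 1 or 2), giving
  `m` feature maps; `encode_optimize()` provides the slower reference
  encoder that solves the lasso at every position.
* **C layers (pooling).** Overlapping max pooling, window 2, stride 1:
  each C map has one fewer row and column than its S source. Average
  pooling and a pass-through ("none") variant exist as controls.

The full-scale default (`default_architecture()`) is twelve layers:
six S layers with 10x10 kernels, convolution strides 2, 2, 1, 1, 1, 1, and
feature-map counts 100, 200, 300, 400, 500, 500, each followed by pooling.
Receptive-field extents follow the standard composition rule (an S layer
adds $(k-1) \cdot \text{jump}$, a pooling layer $(w-1) \cdot \text{jump}$,
and strides multiply the jump), giving

```{r}
layer_geometry(default_architecture())
```

so the hierarchy starts at a 10 ms window in S1 and ends at 194 ms in C6.

## Front end

`cochleogram()` converts 16 kHz waveforms to a channels-by-frames energy
matrix: a 4th-order gammatone filterbank (default 194 channels, center
frequencies 73--7630 Hz, uniform on an ERB-rate scale), half-wave
rectification, a 2nd-order Butterworth lowpass at 100 Hz, and sampling
every 1 ms. The cited cochlear front end's exact filter shapes are not
reproduced; a gammatone bank with the stated channel count and span is the
standard stand-in, and all downstream computation is agnostic to filter
minutiae. Energies are used raw by default (`compress = log1p` is
available but off, since nothing in the model requires compression).

## The synthetic corpus

Licensed phonetically transcribed speech corpora cannot be redistributed,
so the package ships a seeded formant-synthesis generator whose output is
the default input everywhere (a `.PHN`/WAV reader covers real
TIMIT-format data). `make_inventory()` draws a phoneme inventory over four
classes with class-specific acoustics:

* vowels: impulse-train excitation at F0 (90--220 Hz) through second-order
  resonators at F1/F2, with linear formant contours whose slopes differ
  across phonemes (distinct temporal-variation indices);
* nasals: the same source with a low F1 (230--350 Hz), weak F2, and
  reduced amplitude;
* plosives: a silence of voice-onset-time length followed by a
  band-shaped, exponentially decaying burst at a spectral peak
  (500--4000 Hz);
* fricatives: resonator-shaped noise around a peak at 2000--6000 Hz.

`synthesize()` concatenates tokens (balanced and shuffled) with 20--80 ms
gaps, longer 150--250 ms pauses every ~12 tokens (phrase pauses; they also
guarantee that deep layers, whose output frames integrate up to ~74 ms of
input, have frames lying entirely in silence for the active-unit screen),
and 200 ms lead/trail silence. Per token, F0/F1/F2/VOT/spectral peak are
jittered by a multiplicative lognormal factor (`jitter_sd = 0.05`),
emulating within-phoneme variability across talkers; the ground truth
records the jittered values actually synthesized, per 1-ms frame (F0, F1,
F2; `NaN` outside voiced spans) and per token (VOT, spectral peak).
Waveforms are quantized to 16-bit steps so a fixed seed reproduces the
corpus byte for byte.

What the generator does *not* emulate: coarticulation, higher formants
(F3+), pitch contours, amplitude prosody, or talker-specific vocal-tract
differences beyond the scalar jitter. Passing tests therefore show that
the implementation reproduces the method's behaviour on clean,
class-structured input -- not that the model would reach the same
statistics on natural speech.

One physical limit is worth noting: a vowel's cochleogram peak sits on
the F0 harmonic nearest F1, so F1 can only be recovered to within F0/2 Hz
from the spectrum. The formant-recovery test asserts agreement within
one channel on a filterbank whose spacing matches that resolution limit
(48 channels over 73--7630 Hz), not on an arbitrarily fine one.

## Dictionary learning

`learn_dictionary()` is online dictionary learning: minibatch lasso coding
(vectorized coordinate descent over patches) followed by a block
coordinate-descent dictionary update on running second-moment accumulators
with atoms projected to the unit ball. Three numerical choices matter:

* **Initialization.** Atoms start at k-means centers of the normalized
  patches (`init = "kmeans"`). Random-patch initialization (available as
  `init = "patches"`) frequently converges to mixed-atom local minima on
  sparse-combination data; k-means centers start near the generating
  directions. `nstart` adapts to the atom count and the k-means step
  subsamples at most 2000 patches.
* **Forgetting.** The accumulators are scaled by 0.9 per minibatch so that
  codes computed against stale dictionaries are down-weighted; without it
  the first epoch's codes dominate and learning stalls.
* **Maintenance and renormalization.** After each epoch (except the last)
  unused or near-duplicate atoms are reinitialized to the worst-
  reconstructed patches; after training all atoms are renormalized to unit
  norm, so the constraint holds with equality (within 1e-6) even for atoms
  the data never activated.

The coding step uses soft-threshold coordinate descent with tolerance
1e-7 (training) or as requested (`encode_optimize()`, default 1e-8);
an L2 (ridge) penalty replaces the lasso for the regularizer control
experiment.

## STRF composition and parameterization

The receptive field (STRF) of an S1 unit is its atom. For higher S layers
the STRF is composed top-down: each weight of the layer's atom is placed
on the input grid at the spacing of the layer's input (the cumulative
product of convolution strides below it), the slice is zero-padded by the
intervening pooling offset, convolved ("full" mode) with the lower layer's
STRFs, and summed over input maps. With this *dilated* placement (the
default) the composed matrix has exactly the receptive-field extent
returned by `rf_extent()` at every layer, and on a purely linear stack
(stride 1, pooling disabled) it equals the network's exact input gradient
-- both properties are tested. The nearest-neighbor variant
(`expansion = "nearest"`), which duplicates each weight into a d x d
block, is retained as the conventional visualization; it inflates the
extent by d - 1 wherever the input spacing d exceeds 1, which is why it is
not the default. C-layer units share the preceding S units' STRF (pooling
only enlarges the region slightly), so `compose_strf()` addresses S
layers.

`strf_profiles()` takes the rank-1 SVD of the STRF; signs are fixed so
each profile's largest-magnitude element is positive, with the
compensating sign carried on `sigma`. `strf_parameters()` derives the four
scalars: center frequency and Best T are the energy peaks of the spectral
and temporal profiles (Best T is reported as the peak location in ms --
the profile-peak reading; a Fourier-peak variant is reported alongside as
`temporal_modulation`); bandwidth and duration are the smallest contiguous
windows around the peak holding 90% of the squared-profile energy, with
ties expanded toward symmetry, converted to Hz (summed channel widths on
the ERB grid) and ms. Spectral modulation, used for the
temporal/spectral tradeoff scatter, is the DC-excluded peak of the
spectral profile's magnitude spectrum in cycles per channel span -- a
documented convention, since no standard definition exists for
ERB-spaced channels.

## Selectivity statistics

A *unit* for the selectivity analyses is one feature map at the analysis
layer; the map is max-reduced over the frequency axis before amplitudes
are extracted (top-layer maps are nearly global in frequency). A unit's
response amplitude for a phoneme instance is the maximum absolute
response over the output frames whose receptive fields overlap the
instance; phoneme length is not normalized. Silence responses are the
per-frame values at output frames lying entirely inside silence
intervals.

* **Active units**: one-sided rank-sum test, responses at up to 1000
  randomly selected speech frames vs silence frames, p < 0.001.
* **PSI**: for each phoneme, the count of other phonemes whose amplitude
  distribution is statistically smaller (one-sided rank-sum, p < 0.01,
  no multiple-testing correction -- the statistic is defined with raw
  thresholds). With 33 phonemes the ceiling is 32.
* **Clustering**: `hclust` with Euclidean distance and Ward linkage
  (`ward.D2`), cut at 6 groups, applied along both axes for the heatmap
  layout. The linkage is exposed because only "agglomerative, Euclidean"
  is inherent to the method.
* **F-ratio**: between- over within-group variability of the PSI vectors,
  exactly the two-sum formula; an infinite ratio (zero within-group
  variability) is signalled with a warning.
* **Lifetime sparseness**: $S = 1 - (E[r])^2 / E[r^2]$. In layer-level
  summaries it is computed on absolute responses (code magnitudes), since
  the raw codes are roughly symmetric about zero and would make $S$
  saturate near 1 regardless of concentration.

Rank-sum tests use `stats::wilcox.test` (exact for small untied samples,
mid-rank normal approximation otherwise); decisions are cross-checked
against an exhaustive enumeration oracle in the tests.

The penalty sweep (`lambda_sweep()`) retrains one S layer's dictionary
per penalty value with all lower layers fixed, re-encodes that layer, and
reports mean lifetime sparseness and F-ratio. The swept layer is encoded
with the lasso encoder by default: the penalty then controls response
sparseness directly at inference, which is the premise of the sweep
(with the convolutional encoder the penalty acts only through the learned
atoms and the sparseness range collapses).

## Acoustic decoding

Per-instance parameters come from the ground-truth tracks: F0/F1/F2 as
the median of the per-frame track over the transcribed interval, the
spectral peak as the center frequency of the maximum-energy cochleogram
cell within the instance, VOT from the per-token table (an LPC tracker is
deliberately not bundled; for real corpora the same shapes can be
supplied from any tracker). `linear_decode_cv()` is 20-fold
cross-validated least squares (minimum-norm solution when the design is
rank-deficient): per fold the training-split RMSE defines correctness
(|test error| < training RMSE), and accuracy is the fraction correct. The
chance reference draws uniformly between the training targets' minimum
and maximum and is scored with the same thresholds; the two accuracy sets
are compared with a pooled-variance Student's t-test. Two calibration
facts anchor the criterion and are tested: with Gaussian residuals the
accuracy tends to erf(1/sqrt(2)) ~ 0.683, and with target-independent
features it falls to about 2 RMSE / range. The 170-ms onset-aligned
cochleogram window (`cochleogram_baseline()`) is the input-level control.

At desk scale the decoder can saturate: with ~25 active units and only
~24 plosive instances the training fit is near-exact, the RMSE threshold
collapses, and VOT accuracy is 0 for linear and random decoders alike.
This is a sample-size artifact, not a property of the method, and is why
the aggregate decode-vs-chance test pools evidence across the five
parameters.

## Formant dynamics

`build_contours()` resamples every voiced instance's F1/F2 track to 50
points (the method needs a common length; 50 points resolve the linear
contours used here) and averages per phoneme. `tvi()` runs PCA across the
phoneme contours -- column-centered, the standard convention, with the
uncentered projection available -- fixes the PC1 sign by its
largest-magnitude element, and returns the signed projections. The TVI
variance equals PC1's eigenvalue (asserted as a PCA identity), and
`tvi_correlation()` is the Pearson correlation between a unit's mean
per-phoneme responses and the TVIs.

## Pipelines, profiles, and problem sizes

`run_config()` defines two profiles. The `"test"` profile is the package's
desk scale, used by the test suite and chosen to keep a full
corpus-to-analyses cycle under a minute: a 12-phoneme inventory, 96
tokens (~17 s of audio), 96 cochlear channels, a 6-layer network with
16/24/32 maps (strides 2, 2, 1), 2000 training patches per layer, 3
learning epochs. The `"full"` profile preserves the study-scale defaults
(33 phonemes, 194 channels, the 12-layer architecture, 50000 patches per
layer) and is the configuration a study-scale run would use. Stochastic
trend checks (selectivity depth trend, penalty sweep, pooling contrast,
decode-vs-chance) use three seeded corpus/model replicates and assert
medians across them; per-seed fluctuations at this scale are real and
expected. The trend comparisons span the upper half of the test network
(S2..C3), mirroring the full-scale analysis, which evaluates
phoneme-selectivity statistics only in the upper two-thirds of the
hierarchy where units' receptive fields approach phoneme length.

`run_pipeline()` writes every artifact (WAV, `.PHN`, ground-truth TSVs,
model banks, selectivity/decoding/TVI tables) with an MD5 manifest;
identical configurations reproduce identical hashes. `variant_suite()`
trains the pooling variants (max/average/none) and the L2-regularizer
control on the same corpus and seed. Model serialization is a plain-text
container (an architecture table plus one TSV of atom columns per layer)
readable without the package.

## Known limitations

* The synthetic corpus is a stand-in: quantitative statistics (F-ratio
  magnitudes, decoding accuracies, active-unit counts) are not comparable
  to values obtained on natural multi-talker speech; only the qualitative
  contrasts are.
* STRF composition is linear and therefore increasingly approximate for
  deep layers of a max-pooling network; the package follows the
  linear-combination convention and validates it on linearized stacks.
* The normalized reverse-correlation STRF estimate (an external
  validation route) and population-sparseness measures are out of scope.
* `encode_optimize()` at full scale is markedly slower than the
  convolutional encoder and is intended for reference comparisons and the
  penalty sweep, not bulk encoding.
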