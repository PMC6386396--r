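# shmax

Hierarchical sparse coding of speech, as a model of the auditory pathway.

The auditory system processes sound through a cascade of stages — cochlea,
midbrain, cortex — whose neurons encode progressively more abstract
features, from spectro-temporal energy patterns to phonetic categories.
`shmax` implements a computational account of that cascade: an
unsupervised network of alternating **sparse-coding layers** (S) and
**max-pooling layers** (C) trained on cochleograms of speech. Each S layer
learns a dictionary of atoms $b_j$ by solving

$$\min_{B,\,r^k} \sum_k \lVert x^k - B\,r^k \rVert_2^2
  + \lambda \lVert r^k \rVert_1
  \qquad \text{s.t.}\ \lVert b_j \rVert_2 \le 1,$$

over patches $x^k$ of its input, then encodes the input by convolution
with the learned atoms; each C layer applies overlapping max pooling
(window 2, stride 1). In the default twelve-layer architecture the units'
receptive fields grow from 10 ms (S1) to 194 ms (C6), and the package
provides the full analysis suite for comparing units with physiology:

* spectro-temporal receptive field (STRF) composition across layers and
  SVD parameterization (center frequency, bandwidth, Best T, duration);
* phoneme selectivity indices (PSI), active-unit screening, hierarchical
  clustering, and the F-ratio measure of phonetic-feature selectivity;
* linear decoding of acoustic parameters (F0, F1, F2, voice-onset time,
  spectral peak) with a 20-fold scheme, a training-RMSE correctness
  criterion, and a uniform random-decoder significance test;
* temporal variation indices (TVI) of formant contours and unit-response
  correlations;
* lifetime sparseness and a sparseness-penalty sweep;
* control variants: average pooling, no pooling, L2 regularization,
  alternative kernel sizes.

Because the speech corpus the method was developed on is licensed, the
package ships a seeded **formant-synthesis corpus generator**
(`make_inventory()`, `synthesize()`) producing labelled continuous speech
— vowels, nasals, plosives, fricatives with class-appropriate acoustics —
plus per-frame/per-token ground truth (F0, F1, F2, VOT, spectral peak),
written as WAV + TIMIT-style `.PHN` transcripts + TSV. It is the default
input everywhere; real TIMIT-format data can be read with `read_wav()` /
`read_phn()`.

Audience: computational neuroscientists and speech researchers who want a
self-contained, reproducible implementation of hierarchical sparse coding
with the accompanying phoneme-selectivity statistics.

## Worked example

```r
library(shmax)

# receptive-field arithmetic of the full-scale architecture
arch <- default_architecture()
layer_geometry(arch)
#>    layer  rf jump
#> 1     S1  10    2
#> 2     C1  12    2
#> 3     S2  30    4
#> 4     C2  34    4
#> 5     S3  70    4
#> 6     C3  74    4
#> 7     S4 110    4
#> 8     C4 114    4
#> 9     S5 150    4
#> 10    C5 154    4
#> 11    S6 190    4
#> 12    C6 194    4
```

`rf` is each layer's receptive-field extent (channels and frames; at the
1 ms frame step the time extent is in ms — 10 ms at S1, 194 ms at C6) and
`jump` the output-grid spacing in input frames.

A desk-scale run — synthetic corpus, cochleogram, 6-layer network,
top-layer selectivity, and decoding — takes under a minute:

```r
inv <- make_inventory(12, seed = 7)
corpus <- synthesize(inv, n_tokens = 96, jitter_sd = 0.05, seed = 101)
corpus
#> speech corpus: 17.00 s at 16000 Hz, 96 tokens, 12 phoneme labels

fb <- build_filterbank(96, 73, 7630, 16000)
coch <- cochleogram(corpus$wave, fb)
net <- shmax_architecture(n_maps = c(16, 24, 32), kernels = 10,
                          strides = c(2, 2, 1))
model <- train_network(list(coch), net, n_patches = 2000, seed = 201)

geo <- model$geometry
top <- layer_selectivity(model$activations[["C3"]][[1]], corpus$transcript,
                         rf = geo$rf[6], jump = geo$jump[6])
length(top$active)   # 30 of 32 units respond above silence (p < 0.001)
top$f_ratio          # 34.9 : between/within-group PSI variability
top$psi[1:4, 1:6]    # PSI entries, e.g.
#>   f01 f02 n01 n02 p01 p02
#> 1   1   1   2   2   0   0
#> 2   1   1   1   1   1   0
#> 3   1   1   3   1   1   0
#> 5   2   4   0   0   0   0

params <- estimate_params(coch, corpus$transcript, corpus)
X <- amplitude_matrix(top$table, top$active)
dec <- decode_param(X, params$f1, folds = 20, seed = 11, param_name = "f1")
mean(dec$linear$accuracy)  # 0.41  fraction of test F1 predictions within
                           #       the training RMSE
mean(dec$random)           # 0.06  uniform random decoder, same criterion
dec$p_value                # 2.1e-04 (Student's t over the 20 folds)
```

Each PSI entry counts how many other phonemes a unit responds to
significantly less than the indexed phoneme (rank-sum, p < 0.01): a unit
with PSI 11 for one phoneme in this 12-phoneme corpus would be perfectly
selective. The F1 decoding accuracy of 0.41 against a chance level of
0.06 (p = 2e-4) shows that formant information is linearly readable from
the top layer's response amplitudes.

End-to-end pipelines with artifact manifests live behind `run_config()` /
`run_pipeline()` / `variant_suite()`, and a thin command-line wrapper is
installed at `inst/cli/shmax.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/shmax.R", package="shmax"))')" rf --layer C6
#> C6 receptive field: 194 channels x 194 frames (194 ms at 1 ms/frame)
```

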