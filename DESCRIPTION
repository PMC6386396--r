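Package: shmax
Title: Hierarchical Sparse Coding Model of the Auditory Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised hierarchical sparse coding (alternating sparse-coding
    and max-pooling layers) trained on cochleograms of speech, together with the
    analysis suite used to compare model units with auditory-pathway physiology:
    spectro-temporal receptive field (STRF) composition and SVD parameterization,
    phoneme selectivity indices and F-ratio statistics, linear decoding of
    acoustic parameters (F0, F1, F2, voice-onset time, spectral peak), formant
    temporal-variation indices, and lifetime-sparseness measures. Includes a
    seeded formant-synthesis corpus generator producing labelled speech with
    ground-truth acoustic parameters, a gammatone cochleogram front end, and
    end-to-end pipelines with pooling/regularization control variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    signal,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
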