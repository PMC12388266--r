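Package: piezodenoise
Title: Denoising of Throat-Attached Piezoelectric Vibration Signals with
    Adam-Optimized Deep Belief Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal-enhancement pipeline for throat-attached piezoelectric
    (PVDF) vibration recordings. Embeds a 1-D voltage trace into a Hankel
    trajectory matrix with per-column normalization, offers short-time Fourier
    analysis with Hanning windowing and optional spectral-magnitude masking,
    and reconstructs clean signals with a Gauss-Bernoulli deep belief network
    pre-trained by contrastive divergence and fine-tuned with a from-scratch
    Adam optimizer under a joint time/frequency loss. Includes a
    one-dimensional convolutional encoder-decoder comparator, an evaluation
    suite (spectral flatness, Pearson correlation, local noise energy, energy
    ratio, weighted composite score), a seeded generator of vocal-fold-like
    test signals, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
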