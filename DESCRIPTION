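Package: CTdenoise
Title: Patch-Based ICA Denoising of CT Images with Wavelet and Classical Comparators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing additive and multiplicative Gaussian noise from
    two-dimensional grayscale computed-tomography images. The core method fits an
    independent component analysis (FastICA, negentropy fixed-point iteration) to
    overlapping image patches and denoises by sparse-code shrinkage of the
    component responses. Comparators include an orthogonal-wavelet soft/hard
    threshold denoiser (VisuShrink universal threshold), and mean, median and
    locally adaptive Wiener spatial filters. Also provides Gaussian degradation
    models with their mean/variance estimators, PSNR/RMSE/MSE image-quality
    scoring, diagnostic sensitivity/specificity/accuracy summaries, a synthetic
    kidney-CT-like phantom generator, and a reproducible benchmark harness that
    sweeps noise levels and methods. PNG and TIFF images (8/16-bit grayscale) are
    read and written losslessly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'CTdenoise-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'image_io.R'
    'noise.R'
    'metrics.R'
    'ica.R'
    'wavelet.R'
    'baselines.R'
    'phantom.R'
    'benchmark.R'
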