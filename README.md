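# CTdenoise

Denoising of 2-D grayscale CT images by independent component analysis
(ICA), with wavelet-threshold and classical spatial filters as comparators,
objective image-quality scoring, and a reproducible benchmark harness.

CT images are degraded by quantum and photon noise, modelled here as i.i.d.
Gaussian fields applied additively, `g = z + n`, or multiplicatively,
`g = z(1 + n)` (the latter becomes additive under a log transform). The core
method treats the noisy image as a mixture of source structure and noise and
separates them in an ICA basis learned from the image's own patches:

- **FastICA** — negentropy-based fixed-point iteration. For whitened patch
  data `z`, each unit-norm component `w` iterates
  `w <- E[z g(w'z)] - E[g'(w'z)] w` with the log-cosh nonlinearity
  `g = tanh(a1 u)` (Gaussian-kernel contrast selectable), deflation with
  Gram–Schmidt orthogonalisation, and convergence on
  `|<w_k, w_{k-1}>| > 1 - tol`.
- **Sparse-code shrinkage** — patch responses `c` are soft-thresholded,
  `s(c) = sign(c) max(0, |c| - t)`, with `t = sigma_i^2 / scale_i`, where
  `sigma_i` is the pixel noise level propagated through component `i`'s
  analysis filter and `scale_i` the robust scale of the component's signal
  content. The image is rebuilt by overlap-add averaging.
- **Comparators** — VisuShrink wavelet denoising (db4, universal threshold
  `sigma sqrt(2 ln AB)`, soft/hard), mean, median, and locally adaptive
  Wiener filters.
- **Metrics** — `MSE = (1/AB) Σ (z - z')²`, `RMSE = √MSE`,
  `PSNR = 10 log10(L²/MSE)` dB, plus diagnostic
  sensitivity/specificity/accuracy from 2×2 tables.
- **Phantom** — a synthetic kidney-CT-like test image (elliptical organ and
  lesion with exact ground truth) so every experiment runs without clinical
  data.

## Worked example

```r
library(CTdenoise)

clean <- generatePhantom(PhantomSpec(seed = 7))          # 256 x 256, L = 255
noisy <- degradeImage(clean, NoiseSpec(sigma = 20, seed = 11))
qualityReport(clean, noisy)
#> QualityReport: PSNR = 22.108 dB, RMSE = 20.01, MSE = 400.2 (L = 255)

denoised <- icaDenoise(noisy, sigma = 20, seed = 1)
qualityReport(clean, denoised)
#> QualityReport: PSNR = 31.457 dB, RMSE = 6.819, MSE = 46.49 (L = 255)

qualityReport(clean, waveletDenoise(noisy, WaveletConfig(noiseSigma = 20)))
#> QualityReport: PSNR = 30.032 dB, RMSE = 8.035, MSE = 64.55 (L = 255)
qualityReport(clean, meanFilter(noisy, 3))
#> QualityReport: PSNR = 30.061 dB, RMSE = 8.007, MSE = 64.11 (L = 255)
```

Noise at `sigma = 20` costs ~18 dB of PSNR; the ICA denoiser recovers
9.3 dB of it and clearly outperforms both the wavelet and the 3×3 mean
filter (higher PSNR, lower RMSE). Diagnostic summaries work from reported
rates or raw counts:

```r
diagnosticSummary(confusionFromRates(95.0, 97.5, 40, 40))
#> sensitivity specificity    accuracy
#>        95.0        97.5        96.3
```

A full method × noise-level sweep with per-cell means and standard
deviations:

```r
tab <- runSweep(c("ica", "wavelet", "mean", "none"),
                sigmas = c(10, 20, 30, 40), nSeeds = 3, seed = 1)
summarizeSweep(tab)
```

## Command line

A thin Rscript front end is installed under `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ctdenoise.R", package = "CTdenoise"))')
Rscript $CLI phantom  --out clean.png --seed 1
Rscript $CLI addnoise --in clean.png --out noisy.png --sigma 20 --seed 2
Rscript $CLI denoise  --in noisy.png --out out.png --method ica --sigma 20
Rscript $CLI score    --ref clean.png --test out.png
Rscript $CLI benchmark --methods none,mean --out sweep.csv
```

Every command takes `--seed`, writes a JSON manifest beside its output, logs
to stderr, and exits 0/1/2 for ok/usage/data errors. `benchmark` accepts a
YAML config with keys `methods`, `sigmas`, `n_seeds`, `shape`, `seed`.

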