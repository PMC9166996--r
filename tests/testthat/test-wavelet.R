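test_that("detail bands of a constant image are exactly zero", {
  pyr <- waveletDecompose(matrix(7, 64, 64), WaveletConfig())
  for (lv in pyr$details) for (band in lv) expect_lt(max(abs(band)), 1e-12)
})

test_that("decompose/reconstruct is a perfect-reconstruction pair", {
  set.seed(3)
  for (wav in c("haar", "db2", "db4")) {
    for (d in list(c(64L, 64L), c(37L, 53L))) {   # even and odd sizes
      m <- matrix(rnorm(prod(d), sd = 50), d[1], d[2])
      cfg <- WaveletConfig(wavelet = wav, levels = 2)
      rec <- waveletReconstruct(waveletDecompose(m, cfg))
      expect_lt(max(abs(rec - m)) / max(abs(m)), 1e-9)
    }
  }
})

test_that("orthogonal transform conserves energy (Parseval)", {
  set.seed(4)
  m <- matrix(rnorm(64 * 64, sd = 20), 64, 64)
  pyr <- waveletDecompose(m, WaveletConfig(levels = 3))
  energy <- sum(pyr$approx^2) +
    sum(vapply(pyr$details, function(lv) sum(vapply(lv, function(b)
      sum(b^2), numeric(1))), numeric(1)))
  expect_lt(abs(energy - sum(m^2)) / sum(m^2), 1e-6)
})

test_that("coefficient thresholding follows the soft/hard rules", {
  set.seed(5)
  m <- matrix(rnorm(32 * 32), 32, 32)
  pyr <- waveletDecompose(m, WaveletConfig(levels = 1))
  # manual t = 0 is the identity
  id <- thresholdCoefficients(pyr, WaveletConfig(thresholdRule = "manual",
                                                 thresholdValue = 0))
  expect_equal(id$details, pyr$details)
  # hard mode with a huge threshold kills every detail
  dead <- thresholdCoefficients(pyr, WaveletConfig(thresholdRule = "manual",
                                                   thresholdValue = 1e6,
                                                   mode = "hard"))
  for (lv in dead$details) for (band in lv) expect_true(all(band == 0))
  expect_equal(dead$approx, pyr$approx)   # approximation untouched
  # soft rule: d = 10, t = 3 -> 7; magnitudes never grow
  pyr$details[[1]]$d[1, 1] <- 10
  soft <- thresholdCoefficients(pyr, WaveletConfig(thresholdRule = "manual",
                                                   thresholdValue = 3))
  expect_equal(soft$details[[1]]$d[1, 1], 7)
  expect_true(all(abs(soft$details[[1]]$h) <= abs(pyr$details[[1]]$h)))
  # universal rule reproduces sigma * sqrt(2 ln AB)
  uni <- thresholdCoefficients(pyr, WaveletConfig(), sigma = 2)
  t_exp <- 2 * sqrt(2 * log(32 * 32))
  man <- thresholdCoefficients(pyr, WaveletConfig(thresholdRule = "manual",
                                                  thresholdValue = t_exp))
  expect_equal(uni$details, man$details)
})

test_that("wavelet denoising improves noisy phantoms and respects identities", {
  flat <- GrayImage(matrix(128, 64, 64))
  expect_equal(pixels(waveletDenoise(flat)), pixels(flat), tolerance = 1e-9)
  clean <- generatePhantom(tiny_phantom_spec())
  noisy <- degradeImage(clean, NoiseSpec(sigma = 20, seed = 1))
  out <- waveletDenoise(noisy, WaveletConfig(noiseSigma = 20))
  expect_gt(imagePSNR(clean, out), imagePSNR(clean, noisy))
  # automatic sigma performs comparably
  outAuto <- waveletDenoise(noisy)
  expect_gt(imagePSNR(clean, outAuto), imagePSNR(clean, noisy))
})

test_that("multiplicative noise routed through log/exp stays positive", {
  clean <- generatePhantom(tiny_phantom_spec())
  noisy <- degradeImage(clean, NoiseSpec("multiplicative_gaussian",
                                         sigma = 0.15, seed = 2))
  out <- waveletDenoise(noisy, WaveletConfig(noiseSigma = 0.14,
                                             logTransform = TRUE))
  expect_true(all(pixels(out) > 0))
  expect_gt(imagePSNR(clean, out), imagePSNR(clean, noisy))
  neg <- GrayImage(matrix(c(-1, 1, 2, 3), 2, 2))
  expect_error(waveletDenoise(neg, WaveletConfig(logTransform = TRUE)),
               "positive")
})

test_that("infeasible decomposition depths are rejected", {
  expect_error(waveletDecompose(matrix(0, 4, 4), WaveletConfig(levels = 1)),
               "too small")
  expect_error(WaveletConfig(thresholdRule = "manual", thresholdValue = -1),
               "thresholdValue")
})
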