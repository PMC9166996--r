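#' Sample a Gaussian noise field
#'
#' Draws an i.i.d. Gaussian field with mean `mu` and standard deviation
#' `sigma`; noise at different pixels is independent (no spatial
#' correlation). Deterministic given the spec's seed. For the multiplicative
#' model the field multiplies the image as (1 + n), so draws with
#' n <= -1 are resampled (truncation) to keep 1 + n strictly positive and
#' the log-domain conversion to additive noise well defined.
#'
#' @param spec a \linkS4class{NoiseSpec}.
#' @param shape integer (A, B), field dimensions.
#' @return A numeric A x B matrix.
#' @export
sampleNoise <- function(spec, shape) {
  stopifnot(is(spec, "NoiseSpec"))
  validObject(spec)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("'shape' must be two positive integers")
  with_seed(spec@seed, {
    n <- matrix(stats::rnorm(prod(shape), spec@mu, spec@sigma),
                shape[1], shape[2])
    if (spec@kind == "multiplicative_gaussian") {
      bad <- which(n <= -1)
      while (length(bad)) {
        n[bad] <- stats::rnorm(length(bad), spec@mu, spec@sigma)
        bad <- bad[n[bad] <= -1]
      }
    }
    n
  })
}

#' Degrade an image with a noise model
#'
#' Applies the additive (g = z + n) or multiplicative (g = z(1 + n))
#' Gaussian degradation. The output is NOT clipped to [0, L] — clipping
#' happens only at write time — so the additive residual `degraded - clean`
#' reproduces the sampled field exactly. The provenance tag records the
#' degradation.
#'
#' @param img a \linkS4class{GrayImage}.
#' @param spec a \linkS4class{NoiseSpec}.
#' @return A degraded \linkS4class{GrayImage}.
#' @examples
#' img <- generatePhantom(PhantomSpec())
#' noisy <- degradeImage(img, NoiseSpec(sigma = 20, seed = 7))
#' qualityReport(img, noisy)
#' @export
degradeImage <- function(img, spec) {
  stopifnot(is(img, "GrayImage"))
  validObject(img)
  n <- sampleNoise(spec, dim(img@pixels))
  g <- if (spec@kind == "additive_gaussian") img@pixels + n
       else img@pixels * (1 + n)
  tag <- sprintf("%s + %s(mu=%g, sigma=%g, seed=%s)",
                 ifelse(nzchar(img@origin), img@origin, "image"),
                 spec@kind, spec@mu, spec@sigma,
                 ifelse(is.na(spec@seed), "unset", spec@seed))
  GrayImage(g, grayRange = img@grayRange, origin = tag)
}

#' Mean intensity of a noise field
#'
#' The empirical mean (1/AB) sum n(x, y) over all pixels.
#'
#' @param field numeric matrix (or \linkS4class{GrayImage}).
#' @return A scalar.
#' @export
noiseMean <- function(field) {
  n <- as_pixel_matrix(field)
  if (length(n) == 0L) stop("empty noise field")
  mean(n)
}

#' Variance of a noise field
#'
#' The fluctuation of the noise intensity about its mean:
#' (1/AB) sum (n(x, y) - mu)^2, with mu from [noiseMean()]. Note the
#' population (1/AB) normalisation, not the n-1 sample variance.
#'
#' @param field numeric matrix (or \linkS4class{GrayImage}).
#' @return A non-negative scalar; 0 iff the field is constant.
#' @export
noiseVariance <- function(field) {
  n <- as_pixel_matrix(field)
  if (length(n) == 0L) stop("empty noise field")
  mean((n - mean(n))^2)
}

#' Robust noise standard-deviation estimate
#'
#' Median absolute deviation of the finest diagonal-detail wavelet
#' coefficients divided by 0.6745 (the Gaussian consistency constant): the
#' diagonal band of an orthonormal wavelet transform of signal-plus-white-
#' noise is dominated by the noise, whose coefficients remain N(0, sigma).
#' The estimate is invariant to adding a global constant to the image.
#'
#' @param img a \linkS4class{GrayImage} or numeric matrix.
#' @param wavelet wavelet family used for the single decomposition level
#'   (default "db4").
#' @return Estimated noise standard deviation (gray levels).
#' @export
estimateSigma <- function(img, wavelet = "db4") {
  p <- as_pixel_matrix(img)
  if (nrow(p) < 2L || ncol(p) < 2L)
    stop("image too small for one wavelet decomposition level")
  flt <- .wavelet_filters[[wavelet]]
  if (is.null(flt)) stop("unknown wavelet '", wavelet, "'")
  d <- .dwt2_level(p, flt)$HH
  stats::median(abs(d)) / 0.6745
}
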