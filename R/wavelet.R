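## Orthonormal Daubechies analysis/synthesis filter bank. Coefficients are
## the standard published values (extremal-phase family); the synthesis
## operator is the transpose of the analysis operator, so only the analysis
## pair is stored.
.wavelet_filters <- local({
  lo <- list(
    haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255092145, 0.22414386804185735,
            0.836516303737469, 0.48296291314469025),
    db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965))
  lapply(lo, function(h) {
    p <- length(h)
    g <- rev(h) * (-1)^(seq_len(p) - 1)   # quadrature-mirror highpass
    list(lo = h, hi = g, length = p)
  })
})

## One periodized 1-D analysis step applied to every column of `m`.
## Returns rbind(approx, detail), each with ceiling(n/2) rows (n padded to
## even by edge replication when odd). Periodization keeps the operator
## square and orthogonal: perfect reconstruction and Parseval are exact.
.dwt1_cols <- function(m, flt) {
  n <- nrow(m)
  odd <- n %% 2L == 1L
  if (odd) { m <- rbind(m, m[n, , drop = FALSE]); n <- n + 1L }
  half <- n %/% 2L
  a <- matrix(0, half, ncol(m))
  d <- matrix(0, half, ncol(m))
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_len(flt$length)) {
    idx <- (base + j - 1L) %% n + 1L
    a <- a + flt$lo[j] * m[idx, , drop = FALSE]
    d <- d + flt$hi[j] * m[idx, , drop = FALSE]
  }
  list(a = a, d = d, odd = odd)
}

## Transpose (inverse) of .dwt1_cols for even original length; `odd` says
## whether a padding row must be removed afterwards.
.idwt1_cols <- function(a, d, flt, odd = FALSE) {
  half <- nrow(a)
  n <- 2L * half
  x <- matrix(0, n, ncol(a))
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_len(flt$length)) {
    ## for fixed j the target rows are distinct (even base spacing mod n)
    idx <- (base + j - 1L) %% n + 1L
    x[idx, ] <- x[idx, ] + flt$lo[j] * a + flt$hi[j] * d
  }
  if (odd) x <- x[-n, , drop = FALSE]
  x
}

## One separable 2-D level: columns then rows. Returns LL, LH, HL, HH and
## the odd-padding flags needed to invert.
.dwt2_level <- function(m, flt) {
  colStep <- .dwt1_cols(m, flt)
  rowA <- .dwt1_cols(t(colStep$a), flt)
  rowD <- .dwt1_cols(t(colStep$d), flt)
  list(LL = t(rowA$a), LH = t(rowA$d),   # LH: horizontal detail
       HL = t(rowD$a), HH = t(rowD$d),   # HL: vertical, HH: diagonal
       oddRows = colStep$odd, oddCols = rowA$odd)
}

.idwt2_level <- function(lv, flt) {
  a <- t(.idwt1_cols(t(lv$LL), t(lv$LH), flt, lv$oddCols))
  d <- t(.idwt1_cols(t(lv$HL), t(lv$HH), flt, lv$oddCols))
  .idwt1_cols(a, d, flt, lv$oddRows)
}

#' Multilevel 2-D wavelet decomposition
#'
#' Separable periodized orthonormal discrete wavelet transform. The pyramid
#' holds the final approximation band plus horizontal/vertical/diagonal
#' detail bands per level, finest level first. The transform is orthogonal:
#' reconstruction is exact and total coefficient energy equals total pixel
#' energy (Parseval).
#'
#' The effective depth is min(requested levels, log2(min(A, B)) - 2) so the
#' coarsest band keeps a sensible size; fewer than one feasible level is an
#' error.
#'
#' @param img a \linkS4class{GrayImage} or numeric matrix.
#' @param cfg a \linkS4class{WaveletConfig}.
#' @return A pyramid: list with `approx` (matrix), `details` (list per
#'   level, finest first, each with `h`, `v`, `d` matrices), `wavelet`,
#'   `imageDim`, and internal padding flags.
#' @seealso [waveletReconstruct()], [thresholdCoefficients()]
#' @export
waveletDecompose <- function(img, cfg = WaveletConfig()) {
  p <- as_pixel_matrix(img)
  validObject(cfg)
  flt <- .wavelet_filters[[cfg@wavelet]]
  maxLev <- floor(log2(min(dim(p)))) - 2
  levels <- min(cfg@levels, maxLev)
  if (levels < 1L)
    stop("image ", nrow(p), "x", ncol(p), " too small for one ",
         "decomposition level at the configured cap")
  details <- vector("list", levels)
  odd <- vector("list", levels)
  cur <- p
  for (lev in seq_len(levels)) {
    if (min(dim(cur)) < flt$length)
      stop("subband smaller than the '", cfg@wavelet,
           "' filter at level ", lev, "; reduce 'levels'")
    sub <- .dwt2_level(cur, flt)
    details[[lev]] <- list(h = sub$LH, v = sub$HL, d = sub$HH)
    odd[[lev]] <- c(sub$oddRows, sub$oddCols)
    cur <- sub$LL
  }
  structure(list(approx = cur, details = details, wavelet = cfg@wavelet,
                 imageDim = dim(p), oddFlags = odd),
            class = "waveletPyramid")
}

#' Invert a wavelet pyramid
#'
#' Exact inverse of [waveletDecompose()] (transpose of the orthogonal
#' analysis operator).
#'
#' @param pyramid a pyramid from [waveletDecompose()].
#' @return A numeric matrix of the original image dimensions.
#' @export
waveletReconstruct <- function(pyramid) {
  stopifnot(inherits(pyramid, "waveletPyramid"))
  flt <- .wavelet_filters[[pyramid$wavelet]]
  cur <- pyramid$approx
  for (lev in rev(seq_along(pyramid$details))) {
    dt <- pyramid$details[[lev]]
    cur <- .idwt2_level(list(LL = cur, LH = dt$h, HL = dt$v, HH = dt$d,
                             oddRows = pyramid$oddFlags[[lev]][1],
                             oddCols = pyramid$oddFlags[[lev]][2]), flt)
  }
  cur
}

#' Threshold the detail bands of a wavelet pyramid
#'
#' Applies soft (sign(d) max(0, |d| - t)) or hard (d 1[|d| > t])
#' thresholding to every detail coefficient; the approximation band is left
#' untouched. Under the universal (VisuShrink) rule
#' t = sigma sqrt(2 ln(AB)) with AB the pixel count of the original image;
#' the manual rule uses the configured threshold directly.
#'
#' @param pyramid a pyramid from [waveletDecompose()].
#' @param cfg a \linkS4class{WaveletConfig} (threshold rule and mode).
#' @param sigma noise standard deviation (universal rule), >= 0.
#' @return The thresholded pyramid.
#' @export
thresholdCoefficients <- function(pyramid, cfg = WaveletConfig(), sigma = 0) {
  stopifnot(inherits(pyramid, "waveletPyramid"))
  if (sigma < 0) stop("'sigma' must be >= 0")
  t <- if (cfg@thresholdRule == "universal")
    sigma * sqrt(2 * log(prod(pyramid$imageDim)))
  else cfg@thresholdValue
  shrink <- if (cfg@mode == "soft")
    function(d) sign(d) * pmax(0, abs(d) - t)
  else
    function(d) d * (abs(d) > t)
  pyramid$details <- lapply(pyramid$details, function(lv) lapply(lv, shrink))
  pyramid
}

#' Wavelet-threshold denoising
#'
#' The classical three-stage flow: wavelet transform, detail-coefficient
#' thresholding, inverse transform. The noise level is taken from the
#' configuration or estimated from the finest diagonal band
#' ([estimateSigma()]). With `logTransform` the image is routed through
#' log/exp so multiplicative noise g = z(1 + n) becomes additive in the log
#' domain (requires strictly positive intensities; output is then strictly
#' positive).
#'
#' @param img a \linkS4class{GrayImage}.
#' @param cfg a \linkS4class{WaveletConfig} (default: db4, 3 levels,
#'   universal soft threshold, estimated sigma).
#' @return A denoised \linkS4class{GrayImage}.
#' @examples
#' clean <- generatePhantom(PhantomSpec())
#' noisy <- degradeImage(clean, NoiseSpec(sigma = 20, seed = 1))
#' out <- waveletDenoise(noisy, WaveletConfig(noiseSigma = 20))
#' imagePSNR(clean, out) > imagePSNR(clean, noisy)
#' @export
waveletDenoise <- function(img, cfg = WaveletConfig()) {
  stopifnot(is(img, "GrayImage"))
  validObject(img)
  validObject(cfg)
  p <- pixels(img)
  if (cfg@logTransform) {
    if (any(p <= 0))
      stop("'logTransform' requires strictly positive intensities")
    work <- GrayImage(log(p), grayRange = img@grayRange)
  } else {
    work <- img
  }
  sigma <- if (is.na(cfg@noiseSigma)) estimateSigma(work, cfg@wavelet)
           else cfg@noiseSigma
  pyr <- waveletDecompose(work, cfg)
  pyr <- thresholdCoefficients(pyr, cfg, sigma)
  out <- waveletReconstruct(pyr)
  if (cfg@logTransform) out <- exp(out)
  GrayImage(out, grayRange = img@grayRange,
            origin = sprintf("waveletDenoise(%s, %s, sigma=%.4g)",
                             ifelse(nzchar(img@origin), img@origin, "image"),
                             cfg@wavelet, sigma))
}
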