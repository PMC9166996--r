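#' GrayImage: canonical 2-D grayscale image
#'
#' The single currency all modules operate on: a real-valued intensity matrix
#' together with its gray-value range L (the maximum representable intensity,
#' e.g. 255 for 8-bit data) and a free-text provenance tag. Intensities are
#' stored as reals and are deliberately NOT clipped or quantized; quantization
#' happens only when an image is written to disk.
#'
#' @slot pixels numeric matrix of intensities, rows A >= 1, cols B >= 1.
#' @slot grayRange positive scalar L.
#' @slot origin character scalar provenance tag.
#'
#' @seealso [readGrayImage()], [writeGrayImage()], [normalizeImage()]
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", grayRange = "numeric", origin = "character"),
  prototype(pixels = matrix(0, 1, 1), grayRange = 255, origin = ""))

setValidity("GrayImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels))
    msg <- c(msg, "'pixels' must be a numeric matrix")
  if (nrow(object@pixels) < 1L || ncol(object@pixels) < 1L)
    msg <- c(msg, "image must have at least one row and one column")
  if (length(object@grayRange) != 1L || !is.finite(object@grayRange) ||
      object@grayRange <= 0)
    msg <- c(msg, "'grayRange' must be a single positive number")
  if (length(object@origin) != 1L)
    msg <- c(msg, "'origin' must be a single character string")
  if (length(msg)) msg else TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of intensities.
#' @param grayRange maximum representable intensity L (default 255).
#' @param origin provenance tag.
#' @return A \linkS4class{GrayImage}.
#' @examples
#' img <- GrayImage(matrix(0:255, 16, 16), grayRange = 255)
#' dim(img)
#' @export
GrayImage <- function(pixels, grayRange = 255, origin = "") {
  if (is.vector(pixels)) pixels <- matrix(pixels, nrow = 1L)
  new("GrayImage", pixels = pixels, grayRange = as.numeric(grayRange),
      origin = origin)
}

#' NoiseSpec: parameters of an image degradation model
#'
#' Describes Gaussian noise with mean `mu` and standard deviation `sigma`,
#' applied either additively (g = z + n) or multiplicatively (g = z(1 + n)).
#' Noise at different pixels is independent (no spatial correlation). The
#' optional seed makes sampling reproducible.
#'
#' @slot kind "additive_gaussian" or "multiplicative_gaussian".
#' @slot mu noise mean.
#' @slot sigma noise standard deviation, >= 0.
#' @slot seed integer seed or NA for unseeded draws.
#' @export
setClass("NoiseSpec",
  representation(kind = "character", mu = "numeric", sigma = "numeric",
                 seed = "integer"),
  prototype(kind = "additive_gaussian", mu = 0, sigma = 0, seed = NA_integer_))

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("additive_gaussian", "multiplicative_gaussian"))
    msg <- c(msg, "'kind' must be 'additive_gaussian' or 'multiplicative_gaussian'")
  if (length(object@sigma) != 1L || is.na(object@sigma) || object@sigma < 0)
    msg <- c(msg, "'sigma' must be a single non-negative number")
  if (length(object@mu) != 1L || is.na(object@mu))
    msg <- c(msg, "'mu' must be a single number")
  if (length(msg)) msg else TRUE
})

#' Construct a NoiseSpec
#'
#' @param kind noise model, "additive_gaussian" (default) or
#'   "multiplicative_gaussian".
#' @param mu noise mean (default 0).
#' @param sigma noise standard deviation (default 0).
#' @param seed optional integer seed for reproducible sampling.
#' @return A \linkS4class{NoiseSpec}.
#' @examples
#' NoiseSpec(sigma = 20, seed = 1)
#' @export
NoiseSpec <- function(kind = c("additive_gaussian", "multiplicative_gaussian"),
                      mu = 0, sigma = 0, seed = NA) {
  kind <- match.arg(kind)
  new("NoiseSpec", kind = kind, mu = as.numeric(mu), sigma = as.numeric(sigma),
      seed = as.integer(seed))
}

#' ICAModel: fitted FastICA unmixing state
#'
#' Produced by [fasticaFit()]. Holds the per-dimension data mean, the
#' whitening transform (centered data -> unit covariance), its inverse, the
#' unit-norm component vectors (rows of `W`, mutually orthogonal in whitened
#' space), the contrast function used, and per-component iteration counts and
#' convergence flags.
#'
#' @slot dataMean numeric vector, per-dimension mean removed before whitening.
#' @slot whitening matrix K (k x d): z = K (x - mean) has identity covariance.
#' @slot dewhitening matrix (d x k), right-inverse of K.
#' @slot W matrix (m x k) of unit-norm component rows in whitened space.
#' @slot contrast "G1" (log-cosh) or "G2" (Gaussian kernel).
#' @slot a1,a2 contrast-function parameters.
#' @slot nIter integer vector, fixed-point iterations per component.
#' @slot converged logical vector, per-component convergence flags.
#' @export
setClass("ICAModel",
  representation(dataMean = "numeric", whitening = "matrix",
                 dewhitening = "matrix", W = "matrix", contrast = "character",
                 a1 = "numeric", a2 = "numeric", nIter = "integer",
                 converged = "logical"))

setValidity("ICAModel", function(object) {
  msg <- character()
  if (nrow(object@W) > 0) {
    norms <- sqrt(rowSums(object@W^2))
    if (any(abs(norms - 1) > 1e-6))
      msg <- c(msg, "component rows of W must have unit Euclidean norm")
    g <- object@W %*% t(object@W)
    if (max(abs(g - diag(nrow(g)))) > 1e-6)
      msg <- c(msg, "component rows of W must be mutually orthogonal")
  }
  if (!object@contrast %in% c("G1", "G2"))
    msg <- c(msg, "'contrast' must be 'G1' or 'G2'")
  if (length(msg)) msg else TRUE
})

#' PatchConfig: how an image is cut into patches for ICA
#'
#' Square patches of side `patchSize` are slid over the image at the given
#' `stride` (right/bottom edges are covered by final patches clamped to the
#' border) and flattened into vectors. With `removeDC` each patch's mean is
#' stored separately and re-added at reconstruction, so the ICA model sees
#' only patch structure, not local brightness.
#'
#' @slot patchSize integer >= 2, square patch side (default 8).
#' @slot stride integer >= 1, step between patch origins (default 4).
#' @slot removeDC logical, subtract per-patch means (default TRUE).
#' @export
setClass("PatchConfig",
  representation(patchSize = "integer", stride = "integer", removeDC = "logical"),
  prototype(patchSize = 8L, stride = 4L, removeDC = TRUE))

setValidity("PatchConfig", function(object) {
  msg <- character()
  if (object@patchSize < 2L) msg <- c(msg, "'patchSize' must be >= 2")
  if (object@stride < 1L) msg <- c(msg, "'stride' must be >= 1")
  if (object@stride > object@patchSize)
    msg <- c(msg, "'stride' must not exceed 'patchSize' (full coverage)")
  if (length(msg)) msg else TRUE
})

#' Construct a PatchConfig
#'
#' @param patchSize square patch side in pixels (default 8).
#' @param stride step between patch origins (default 4).
#' @param removeDC subtract and restore per-patch means (default TRUE).
#' @return A \linkS4class{PatchConfig}.
#' @export
PatchConfig <- function(patchSize = 8L, stride = 4L, removeDC = TRUE) {
  new("PatchConfig", patchSize = as.integer(patchSize),
      stride = as.integer(stride), removeDC = isTRUE(removeDC))
}

#' WaveletConfig: wavelet-threshold denoiser parameters
#'
#' @slot wavelet orthogonal wavelet family name ("haar", "db2", "db4").
#' @slot levels requested decomposition depth (>= 1, default 3); the effective
#'   depth is capped at log2(min(A,B)) - 2 for an A x B image.
#' @slot thresholdRule "universal" (sigma * sqrt(2 ln AB), VisuShrink) or
#'   "manual".
#' @slot thresholdValue threshold for the manual rule (>= 0), NA otherwise.
#' @slot mode "soft" (default) or "hard" thresholding.
#' @slot noiseSigma known noise standard deviation, or NA to estimate it
#'   from the finest diagonal subband (median absolute coefficient / 0.6745).
#' @slot logTransform route the image through log/exp so multiplicative
#'   noise becomes additive before thresholding (default FALSE).
#' @export
setClass("WaveletConfig",
  representation(wavelet = "character", levels = "integer",
                 thresholdRule = "character", thresholdValue = "numeric",
                 mode = "character", noiseSigma = "numeric",
                 logTransform = "logical"),
  prototype(wavelet = "db4", levels = 3L, thresholdRule = "universal",
            thresholdValue = NA_real_, mode = "soft", noiseSigma = NA_real_,
            logTransform = FALSE))

setValidity("WaveletConfig", function(object) {
  msg <- character()
  if (!object@wavelet %in% names(.wavelet_filters))
    msg <- c(msg, paste0("unknown wavelet '", object@wavelet, "'; available: ",
                         paste(names(.wavelet_filters), collapse = ", ")))
  if (object@levels < 1L) msg <- c(msg, "'levels' must be >= 1")
  if (!object@thresholdRule %in% c("universal", "manual"))
    msg <- c(msg, "'thresholdRule' must be 'universal' or 'manual'")
  if (object@thresholdRule == "manual" &&
      (is.na(object@thresholdValue) || object@thresholdValue < 0))
    msg <- c(msg, "manual rule requires a non-negative 'thresholdValue'")
  if (!object@mode %in% c("soft", "hard"))
    msg <- c(msg, "'mode' must be 'soft' or 'hard'")
  if (!is.na(object@noiseSigma) && object@noiseSigma < 0)
    msg <- c(msg, "'noiseSigma' must be >= 0 (or NA for automatic estimation)")
  if (length(msg)) msg else TRUE
})

#' Construct a WaveletConfig
#'
#' @param wavelet wavelet family (default "db4").
#' @param levels decomposition depth (default 3).
#' @param thresholdRule "universal" (default) or "manual".
#' @param thresholdValue threshold when `thresholdRule = "manual"`.
#' @param mode "soft" (default) or "hard".
#' @param noiseSigma noise standard deviation; NA or "auto" (default) to
#'   estimate from the image.
#' @param logTransform treat the noise as multiplicative via a log/exp wrap.
#' @return A \linkS4class{WaveletConfig}.
#' @export
WaveletConfig <- function(wavelet = "db4", levels = 3L,
                          thresholdRule = c("universal", "manual"),
                          thresholdValue = NA_real_,
                          mode = c("soft", "hard"),
                          noiseSigma = NA, logTransform = FALSE) {
  if (identical(noiseSigma, "auto")) noiseSigma <- NA_real_
  new("WaveletConfig", wavelet = wavelet, levels = as.integer(levels),
      thresholdRule = match.arg(thresholdRule),
      thresholdValue = as.numeric(thresholdValue), mode = match.arg(mode),
      noiseSigma = as.numeric(noiseSigma), logTransform = isTRUE(logTransform))
}

#' QualityReport: objective image-quality scores
#'
#' Bundle of peak signal-to-noise ratio (dB), root-mean-square error and
#' mean-square error between a reference and a test image, together with the
#' gray range L used by the PSNR. PSNR is +Inf exactly when MSE is zero
#' (perfect reconstruction).
#'
#' @slot psnr PSNR in decibels (+Inf iff mse == 0).
#' @slot rmse root-mean-square gray-level error.
#' @slot mse mean-square gray-level error.
#' @slot grayRange the L used in the PSNR.
#' @seealso [qualityReport()], [imagePSNR()], [imageRMSE()], [imageMSE()]
#' @export
setClass("QualityReport",
  representation(psnr = "numeric", rmse = "numeric", mse = "numeric",
                 grayRange = "numeric"))

setValidity("QualityReport", function(object) {
  msg <- character()
  if (object@mse < 0) msg <- c(msg, "'mse' must be >= 0")
  if (abs(object@rmse^2 - object@mse) >
      1e-12 * max(object@mse, .Machine$double.eps))
    msg <- c(msg, "'rmse' must equal sqrt(mse)")
  if ((object@mse == 0) != is.infinite(object@psnr))
    msg <- c(msg, "'psnr' must be +Inf exactly when mse == 0")
  if (length(msg)) msg else TRUE
})

#' ConfusionTable: 2x2 diagnostic counts
#'
#' True/false positives and negatives of a diagnostic test on diseased and
#' non-diseased groups; input to [diagnosticSummary()].
#'
#' @slot tp,fn,tn,fp non-negative integer counts.
#' @export
setClass("ConfusionTable",
  representation(tp = "integer", fn = "integer", tn = "integer", fp = "integer"))

setValidity("ConfusionTable", function(object) {
  cnt <- c(object@tp, object@fn, object@tn, object@fp)
  if (any(is.na(cnt)) || any(cnt < 0L))
    "counts must be non-negative integers" else TRUE
})

#' Construct a ConfusionTable
#'
#' @param tp true positives.
#' @param fn false negatives.
#' @param tn true negatives.
#' @param fp false positives.
#' @return A \linkS4class{ConfusionTable}.
#' @examples
#' diagnosticSummary(ConfusionTable(tp = 36, fn = 4, tn = 39, fp = 1))
#' @export
ConfusionTable <- function(tp, fn, tn, fp) {
  new("ConfusionTable", tp = as.integer(tp), fn = as.integer(fn),
      tn = as.integer(tn), fp = as.integer(fp))
}

#' PhantomSpec: synthetic kidney-CT-like phantom parameters
#'
#' A piecewise-smooth test image: dark background, a bright elliptical
#' "parenchyma" organ, an embedded "lesion" ellipse, and optional
#' low-amplitude smooth texture. Ellipse centers/axes are in pixel units,
#' angles in radians; the lesion must lie inside the organ.
#'
#' @slot shape integer (A, B), image size (default 256 x 256).
#' @slot grayRange gray range L (default 255).
#' @slot backgroundLevel,parenchymaLevel,lesionLevel region intensities in
#'   [0, L].
#' @slot organCenter,organAxes,organAngle organ ellipse geometry.
#' @slot lesionCenter,lesionAxes,lesionAngle lesion ellipse geometry.
#' @slot textureAmp standard deviation of the smooth texture field (gray
#'   levels); 0 disables texture.
#' @slot seed integer seed for the texture field.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", grayRange = "numeric",
                 backgroundLevel = "numeric", parenchymaLevel = "numeric",
                 lesionLevel = "numeric",
                 organCenter = "numeric", organAxes = "numeric",
                 organAngle = "numeric",
                 lesionCenter = "numeric", lesionAxes = "numeric",
                 lesionAngle = "numeric",
                 textureAmp = "numeric", seed = "integer"),
  prototype(shape = c(256L, 256L), grayRange = 255,
            backgroundLevel = 40, parenchymaLevel = 140, lesionLevel = 220,
            organCenter = c(128.5, 128.5), organAxes = c(95, 72),
            organAngle = 0.35,
            lesionCenter = c(112, 152), lesionAxes = c(24, 16),
            lesionAngle = -0.5,
            textureAmp = 4, seed = 1L))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 2L || any(object@shape < 8L))
    msg <- c(msg, "'shape' must be two integers >= 8")
  lv <- c(object@backgroundLevel, object@parenchymaLevel, object@lesionLevel)
  if (any(lv < 0) || any(lv > object@grayRange))
    msg <- c(msg, "all levels must lie within [0, grayRange]")
  if (any(object@organAxes <= 0) || any(object@lesionAxes <= 0))
    msg <- c(msg, "ellipse axes must be positive")
  if (object@textureAmp < 0) msg <- c(msg, "'textureAmp' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults give a 256 x 256, 8-bit-range phantom with background 40,
#' parenchyma 140 and lesion 220 gray levels and a faint (sd 4) smooth
#' texture.
#'
#' @param shape image size (A, B).
#' @param grayRange gray range L.
#' @param backgroundLevel,parenchymaLevel,lesionLevel region intensities.
#' @param organCenter,organAxes,organAngle organ ellipse (center row/col,
#'   semi-axes, rotation in radians).
#' @param lesionCenter,lesionAxes,lesionAngle lesion ellipse.
#' @param textureAmp texture standard deviation in gray levels (0 = none).
#' @param seed texture seed.
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' img <- generatePhantom(PhantomSpec(textureAmp = 0))
#' length(unique(as.vector(pixels(img))))   # 3 tissue levels
#' @export
PhantomSpec <- function(shape = c(256L, 256L), grayRange = 255,
                        backgroundLevel = 40, parenchymaLevel = 140,
                        lesionLevel = 220,
                        organCenter = (shape + 1) / 2,
                        organAxes = pmax(4, shape * c(0.37, 0.28)),
                        organAngle = 0.35,
                        lesionCenter = organCenter + c(-0.06, 0.09) * shape,
                        lesionAxes = pmax(2, shape * c(0.094, 0.0625)),
                        lesionAngle = -0.5,
                        textureAmp = 4, seed = 1L) {
  spec <- new("PhantomSpec", shape = as.integer(shape),
              grayRange = as.numeric(grayRange),
              backgroundLevel = as.numeric(backgroundLevel),
              parenchymaLevel = as.numeric(parenchymaLevel),
              lesionLevel = as.numeric(lesionLevel),
              organCenter = as.numeric(organCenter),
              organAxes = as.numeric(organAxes),
              organAngle = as.numeric(organAngle),
              lesionCenter = as.numeric(lesionCenter),
              lesionAxes = as.numeric(lesionAxes),
              lesionAngle = as.numeric(lesionAngle),
              textureAmp = as.numeric(textureAmp), seed = as.integer(seed))
  .check_lesion_inside_organ(spec)
  spec
}

#' Subjective image-quality grade
#'
#' Four-level rubric for subjective evaluation of denoised CT images:
#' 1 = Poor (quality changes affect the observation), 2 = General
#' (deterioration directly observable), 3 = Good (slight changes, observation
#' unaffected), 4 = Excellent (no change in quality).
#'
#' @param level integer grade in 1..4.
#' @return A list with `level` and the fixed `label`.
#' @examples
#' subjectiveGrade(4)$label   # "Excellent"
#' @export
subjectiveGrade <- function(level) {
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 1L || level > 4L)
    stop("'level' must be an integer in 1..4")
  labels <- c("Poor", "General", "Good", "Excellent")
  list(level = level, label = labels[level])
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "GrayImage", function(object) {
  p <- object@pixels
  cat(sprintf("GrayImage: %d x %d, L = %g, intensities in [%.4g, %.4g]\n",
              nrow(p), ncol(p), object@grayRange, min(p), max(p)))
  if (nzchar(object@origin)) cat("  origin:", object@origin, "\n")
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("NoiseSpec: %s, mu = %g, sigma = %g, seed = %s\n",
              object@kind, object@mu, object@sigma,
              ifelse(is.na(object@seed), "unset", object@seed)))
})

setMethod("show", "ICAModel", function(object) {
  cat(sprintf(
    "ICAModel: %d component(s) in %d-dim whitened space, contrast %s\n",
    nrow(object@W), ncol(object@W), object@contrast))
  cat(sprintf("  converged: %d/%d; iterations: %s\n",
              sum(object@converged), length(object@converged),
              paste(utils::head(object@nIter, 8), collapse = " ")))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: PSNR = %s dB, RMSE = %.4g, MSE = %.4g (L = %g)\n",
              ifelse(is.infinite(object@psnr), "Inf",
                     sprintf("%.3f", object@psnr)),
              object@rmse, object@mse, object@grayRange))
})

setMethod("show", "ConfusionTable", function(object) {
  cat(sprintf("ConfusionTable: TP=%d FN=%d TN=%d FP=%d\n",
              object@tp, object@fn, object@tn, object@fp))
})

## ---- accessors -------------------------------------------------------------

#' @describeIn GrayImage pixel matrix.
#' @param object,value see generic.
#' @export
setMethod("pixels", "GrayImage", function(object) object@pixels)

#' @describeIn GrayImage replace pixel matrix (dimensions must match).
#' @export
setReplaceMethod("pixels", "GrayImage", function(object, value) {
  stopifnot(identical(dim(value), dim(object@pixels)))
  object@pixels <- value
  validObject(object)
  object
})

#' @describeIn GrayImage gray range L.
#' @export
setMethod("grayRange", "GrayImage", function(object) object@grayRange)

#' @describeIn GrayImage provenance tag.
#' @export
setMethod("origin", "GrayImage", function(object) object@origin)

#' @describeIn GrayImage image dimensions (rows, cols).
#' @param x a GrayImage.
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @describeIn QualityReport gray range used for the PSNR.
#' @export
setMethod("grayRange", "QualityReport", function(object) object@grayRange)

#' @describeIn ICAModel unit-norm component rows in whitened space.
#' @export
setMethod("icaComponents", "ICAModel", function(object) object@W)

#' @describeIn ICAModel per-component convergence flags.
#' @export
setMethod("converged", "ICAModel", function(object) object@converged)
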