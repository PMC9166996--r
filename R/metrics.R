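#' Mean-square error between two images
#'
#' (1/AB) sum (z_ij - z'_ij)^2 over all pixels.
#'
#' @param ref reference \linkS4class{GrayImage} or matrix.
#' @param test test image of the same shape.
#' @return A non-negative scalar.
#' @export
imageMSE <- function(ref, test) {
  r <- as_pixel_matrix(ref); t <- as_pixel_matrix(test)
  if (!identical(dim(r), dim(t)))
    stop("image shapes differ: ", paste(dim(r), collapse = "x"), " vs ",
         paste(dim(t), collapse = "x"))
  mean((r - t)^2)
}

#' Root-mean-square error between two images
#'
#' The gray-level difference between a processed image and its reference,
#' sqrt of [imageMSE()].
#'
#' @inheritParams imageMSE
#' @return A non-negative scalar.
#' @export
imageRMSE <- function(ref, test) sqrt(imageMSE(ref, test))

#' Peak signal-to-noise ratio in decibels
#'
#' 10 log10(L^2 / MSE) with L the gray range; the larger, the better the
#' image quality. Returns +Inf exactly when the images are identical
#' (MSE = 0).
#'
#' @inheritParams imageMSE
#' @param L gray range; defaults to the reference image's when `ref` is a
#'   \linkS4class{GrayImage}, else 255.
#' @return PSNR in dB.
#' @examples
#' imagePSNR(matrix(0, 2, 2), matrix(25.5, 2, 2), L = 255)  # 20 dB
#' @export
imagePSNR <- function(ref, test, L = if (is(ref, "GrayImage")) grayRange(ref) else 255) {
  if (length(L) != 1L || !is.finite(L) || L <= 0)
    stop("'L' must be a single positive number")
  m <- imageMSE(ref, test)
  if (m == 0) Inf else 10 * log10(L^2 / m)
}

#' Bundle PSNR, RMSE and MSE into a QualityReport
#'
#' @inheritParams imagePSNR
#' @return A \linkS4class{QualityReport}.
#' @export
qualityReport <- function(ref, test,
                          L = if (is(ref, "GrayImage")) grayRange(ref) else 255) {
  m <- imageMSE(ref, test)
  new("QualityReport", psnr = imagePSNR(ref, test, L), rmse = sqrt(m), mse = m,
      grayRange = as.numeric(L))
}

#' Diagnostic sensitivity, specificity and accuracy
#'
#' Percentages from a 2x2 table of diagnostic outcomes:
#' sensitivity = 100 TP/(TP+FN), specificity = 100 TN/(TN+FP),
#' accuracy = 100 (TP+TN)/(TP+FN+TN+FP). Values are reported rounded to one
#' decimal, half away from zero (so 93.75 reports as 93.8).
#'
#' @param ct a \linkS4class{ConfusionTable}.
#' @return Named numeric vector with `sensitivity`, `specificity`,
#'   `accuracy` (percent).
#' @examples
#' diagnosticSummary(ConfusionTable(tp = 38, fn = 2, tn = 39, fp = 1))
#' @export
diagnosticSummary <- function(ct) {
  stopifnot(is(ct, "ConfusionTable"))
  validObject(ct)
  pos <- ct@tp + ct@fn
  neg <- ct@tn + ct@fp
  if (pos == 0L) stop("sensitivity undefined: no diseased cases (tp + fn = 0)")
  if (neg == 0L) stop("specificity undefined: no non-diseased cases (tn + fp = 0)")
  c(sensitivity = round_half_away(100 * ct@tp / pos, 1),
    specificity = round_half_away(100 * ct@tn / neg, 1),
    accuracy = round_half_away(100 * (ct@tp + ct@tn) / (pos + neg), 1))
}

#' Build a ConfusionTable from reported rates
#'
#' Convenience inverse of [diagnosticSummary()]: converts a reported
#' sensitivity/specificity (percent) and group sizes back into integer
#' counts. Counts must come out whole (to 1e-6), otherwise the rates are
#' inconsistent with the group sizes.
#'
#' @param sensitivity,specificity percentages.
#' @param nDiseased,nHealthy group sizes.
#' @return A \linkS4class{ConfusionTable}.
#' @examples
#' diagnosticSummary(confusionFromRates(90, 97.5, 40, 40))
#' @export
confusionFromRates <- function(sensitivity, specificity, nDiseased, nHealthy) {
  tp <- sensitivity / 100 * nDiseased
  tn <- specificity / 100 * nHealthy
  if (abs(tp - round(tp)) > 1e-6 || abs(tn - round(tn)) > 1e-6)
    stop("rates are inconsistent with the group sizes (non-integer counts)")
  ConfusionTable(tp = round(tp), fn = nDiseased - round(tp),
                 tn = round(tn), fp = nHealthy - round(tn))
}
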