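## Classical spatial comparator filters. All use reflect padding (the
## nearest padded sample repeats the edge pixel) and preserve image shape.

.check_kernel <- function(k, A, B) {
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("'k' must be an odd integer >= 3")
  if (k > min(A, B)) stop("kernel size ", k, " exceeds image size")
  k
}

## Stack of k^2 shifted copies of the padded image, as an (A*B) x k^2 matrix;
## shared by the three filters.
.window_stack <- function(p, k) {
  r <- k %/% 2L
  A <- nrow(p); B <- ncol(p)
  pp <- pad_reflect(p, r)
  out <- matrix(0, A * B, k * k)
  col <- 1L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    out[, col] <- as.vector(pp[(1L + di):(A + di), (1L + dj):(B + dj)])
    col <- col + 1L
  }
  out
}

.wrap_like <- function(img, m, tag) {
  if (is(img, "GrayImage"))
    GrayImage(m, grayRange = img@grayRange,
              origin = sprintf("%s(%s)", tag,
                               ifelse(nzchar(img@origin), img@origin, "image")))
  else m
}

#' Mean (box) filter
#'
#' k x k moving average with reflect padding; shape preserved.
#'
#' @param img a \linkS4class{GrayImage} or numeric matrix.
#' @param k odd window side >= 3 (default 3).
#' @return The filtered image, same class as the input.
#' @export
meanFilter <- function(img, k = 3L) {
  p <- as_pixel_matrix(img)
  k <- .check_kernel(k, nrow(p), ncol(p))
  m <- matrix(rowMeans(.window_stack(p, k)), nrow(p), ncol(p))
  .wrap_like(img, m, "meanFilter")
}

#' Median filter
#'
#' k x k moving window median with reflect padding; removes isolated
#' impulses while preserving step edges.
#'
#' @inheritParams meanFilter
#' @return The filtered image, same class as the input.
#' @export
medianFilter <- function(img, k = 3L) {
  p <- as_pixel_matrix(img)
  k <- .check_kernel(k, nrow(p), ncol(p))
  st <- .window_stack(p, k)
  ## middle order statistic of each row (k^2 is odd)
  mid <- (k * k + 1L) %/% 2L
  med <- apply(st, 1L, function(v) sort.int(v, partial = mid)[mid])
  .wrap_like(img, matrix(med, nrow(p), ncol(p)), "medianFilter")
}

#' Locally adaptive (spatial Wiener) filter
#'
#' Per-pixel shrinkage towards the local mean using local statistics over a
#' k x k window: with local mean m and local variance s^2,
#' \deqn{out = m + \frac{\max(0, s^2 - \sigma^2)}{\max(s^2, \sigma^2)}
#'   (pixel - m).}
#' In flat regions (s^2 <= sigma^2) the output is exactly the local mean;
#' where local structure dominates the pixel passes nearly unchanged. With
#' `noiseVar = "auto"` sigma^2 is the mean of the local variances (the
#' classical automatic estimate).
#'
#' @inheritParams meanFilter
#' @param noiseVar noise variance sigma^2 (>= 0), or "auto".
#' @return The filtered image, same class as the input.
#' @export
wienerFilter <- function(img, k = 3L, noiseVar = "auto") {
  p <- as_pixel_matrix(img)
  k <- .check_kernel(k, nrow(p), ncol(p))
  st <- .window_stack(p, k)
  m <- rowMeans(st)
  s2 <- rowMeans(st^2) - m^2
  s2[s2 < 0] <- 0                       # numeric guard
  if (identical(noiseVar, "auto")) noiseVar <- mean(s2)
  if (!is.numeric(noiseVar) || length(noiseVar) != 1L || noiseVar < 0)
    stop("'noiseVar' must be a single non-negative number or \"auto\"")
  gain <- pmax(0, s2 - noiseVar) / pmax(s2, noiseVar)
  gain[s2 == 0 & noiseVar == 0] <- 0    # constant window, no noise: keep mean
  out <- m + gain * (as.vector(p) - m)
  .wrap_like(img, matrix(out, nrow(p), ncol(p)), "wienerFilter")
}
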