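## Signed ellipse membership: value <= 1 means the pixel center is inside.
.ellipse_q <- function(rows, cols, center, axes, angle) {
  dr <- outer(rows - center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2])
  u <- cos(angle) * dr + sin(angle) * dc
  v <- -sin(angle) * dr + cos(angle) * dc
  (u / axes[1])^2 + (v / axes[2])^2
}

## Parameter check shared by the PhantomSpec constructor: the lesion
## boundary must lie inside the organ ellipse.
.check_lesion_inside_organ <- function(spec) {
  th <- seq(0, 2 * pi, length.out = 64L)
  br <- spec@lesionCenter[1] +
    cos(spec@lesionAngle) * spec@lesionAxes[1] * cos(th) -
    sin(spec@lesionAngle) * spec@lesionAxes[2] * sin(th)
  bc <- spec@lesionCenter[2] +
    sin(spec@lesionAngle) * spec@lesionAxes[1] * cos(th) +
    cos(spec@lesionAngle) * spec@lesionAxes[2] * sin(th)
  q <- vapply(seq_along(th), function(i)
    .ellipse_q(br[i], bc[i], spec@organCenter, spec@organAxes,
               spec@organAngle), numeric(1))
  if (any(q > 1))
    stop("lesion ellipse extends outside the organ ellipse")
  invisible(TRUE)
}

#' Generate a synthetic kidney-CT-like phantom
#'
#' Builds a piecewise-smooth test image with exact ground truth: a dark
#' background, a bright elliptical "parenchyma" organ, and an embedded
#' "lesion" ellipse, optionally overlaid with a faint smooth texture field
#' (seeded Gaussian noise blurred to be band-limited, rescaled to standard
#' deviation `textureAmp` and clipped with the image to [0, L]). Sharp
#' ellipse edges make the phantom a deliberate stress test for how well a
#' denoiser preserves edge contours. Deterministic given the spec's seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{GrayImage}.
#' @examples
#' img <- generatePhantom(PhantomSpec(seed = 42))
#' dim(img)
#' @export
generatePhantom <- function(spec = PhantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  .check_lesion_inside_organ(spec)
  A <- spec@shape[1]; B <- spec@shape[2]
  rows <- seq_len(A); cols <- seq_len(B)
  img <- matrix(spec@backgroundLevel, A, B)
  organ <- .ellipse_q(rows, cols, spec@organCenter, spec@organAxes,
                      spec@organAngle) <= 1
  lesion <- .ellipse_q(rows, cols, spec@lesionCenter, spec@lesionAxes,
                       spec@lesionAngle) <= 1
  img[organ] <- spec@parenchymaLevel
  img[lesion] <- spec@lesionLevel
  if (spec@textureAmp > 0) {
    tex <- with_seed(spec@seed, matrix(stats::rnorm(A * B), A, B))
    tex <- .gaussian_blur(tex, sd = 2.5)
    tex <- tex / stats::sd(as.vector(tex)) * spec@textureAmp
    img <- img + tex
  }
  img <- pmin(pmax(img, 0), spec@grayRange)
  GrayImage(img, grayRange = spec@grayRange,
            origin = sprintf("phantom(seed=%d)", spec@seed))
}

## Separable Gaussian blur with reflect padding (band-limits the texture).
.gaussian_blur <- function(m, sd) {
  r <- max(1L, ceiling(3 * sd))
  kern <- stats::dnorm(-r:r, sd = sd)
  kern <- kern / sum(kern)
  A <- nrow(m); B <- ncol(m)
  pp <- pad_reflect(m, r)
  tmp <- matrix(0, A, B + 2L * r)
  for (j in seq_along(kern))
    tmp <- tmp + kern[j] * pp[(j):(A + j - 1L), , drop = FALSE]
  out <- matrix(0, A, B)
  for (j in seq_along(kern))
    out <- out + kern[j] * tmp[, (j):(B + j - 1L), drop = FALSE]
  out
}

#' Build a clean/noisy fixture set over a sigma grid
#'
#' One clean phantom plus one additive-Gaussian degraded copy per noise
#' level; the default grid is sigma = 10, 20, 30, 40. All noise seeds derive
#' deterministically from `seed`.
#'
#' @param sigmas noise standard deviations (default c(10, 20, 30, 40)).
#' @param base a \linkS4class{PhantomSpec}.
#' @param seed integer seed for the noise fields.
#' @return A list: `clean` (\linkS4class{GrayImage}), `noisy` (list of
#'   GrayImages named by sigma), `sigmas`.
#' @export
makeFixtureSet <- function(sigmas = c(10, 20, 30, 40), base = PhantomSpec(),
                           seed = 1L) {
  if (length(sigmas) < 1L) stop("'sigmas' must be non-empty")
  clean <- generatePhantom(base)
  noisy <- lapply(seq_along(sigmas), function(i) {
    degradeImage(clean, NoiseSpec(kind = "additive_gaussian", mu = 0,
                                  sigma = sigmas[i],
                                  seed = child_seed(seed, i)))
  })
  names(noisy) <- as.character(sigmas)
  list(clean = clean, noisy = noisy, sigmas = sigmas)
}
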