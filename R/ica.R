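#' Contrast functions for negentropy-based ICA
#'
#' Evaluates the smooth non-quadratic contrast G, its derivative g (the
#' nonlinearity of the fixed-point iteration) and g' at the given points.
#' Two families are provided:
#' \describe{
#'   \item{G1 (log-cosh)}{G1(u) = (1/a1) log cosh(a1 u); g1 = tanh(a1 u);
#'     g1' = a1 (1 - tanh^2(a1 u)). The robust general-purpose choice.}
#'   \item{G2 (Gaussian kernel)}{G2(u) = -(1/a2) exp(-a2 u^2 / 2);
#'     g2 = u exp(-a2 u^2 / 2); g2' = (1 - a2 u^2) exp(-a2 u^2 / 2).}
#' }
#'
#' @param u numeric vector of evaluation points.
#' @param kind "G1" (default) or "G2".
#' @param a1 slope parameter of G1, in [1, 2].
#' @param a2 width parameter of G2, > 0.
#' @return A list with numeric vectors `G`, `g`, `gprime`.
#' @examples
#' contrastEval(1, "G1")$g   # tanh(1)
#' @export
contrastEval <- function(u, kind = c("G1", "G2"), a1 = 1, a2 = 1) {
  kind <- match.arg(kind)
  if (kind == "G1") {
    if (a1 < 1 || a1 > 2) stop("'a1' must lie in [1, 2]")
    th <- tanh(a1 * u)
    ## log(cosh(x)) overflows for |x| > ~350; use |x| - log 2 asymptote there
    ax <- abs(a1 * u)
    lc <- ifelse(ax > 30, ax - log(2), log(cosh(a1 * u)))
    list(G = lc / a1, g = th, gprime = a1 * (1 - th^2))
  } else {
    if (a2 <= 0) stop("'a2' must be > 0")
    e <- exp(-a2 * u^2 / 2)
    list(G = -e / a2, g = u * e, gprime = (1 - a2 * u^2) * e)
  }
}

#' Center and whiten multivariate data
#'
#' Removes the per-dimension mean and applies an eigen-decomposition-based
#' linear transform so the output has zero mean and identity (population)
#' covariance — the preprocessing the FastICA fixed point requires.
#' Dimensions whose covariance eigenvalue falls below 1e-10 times the
#' largest are dropped.
#'
#' @param data numeric matrix, one observation per row.
#' @return A list: `Z` whitened data (n x k), `whitening` K (k x d) with
#'   Z = (X - mean) K', `dewhitening` (d x k) right-inverse of K, and
#'   `mean` (length d).
#' @export
centerWhiten <- function(data) {
  X <- as.matrix(data)
  n <- nrow(X); d <- ncol(X)
  if (n <= d)
    stop("need more observations than dimensions (", n, " x ", d, ")")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > 1e-10 * eg$values[1]
  if (!any(keep)) stop("covariance is numerically rank zero")
  lam <- eg$values[keep]
  E <- eg$vectors[, keep, drop = FALSE]
  K <- diag(1 / sqrt(lam), nrow = length(lam)) %*% t(E)
  Kinv <- E %*% diag(sqrt(lam), nrow = length(lam))
  list(Z = Xc %*% t(K), whitening = K, dewhitening = Kinv, mean = mu)
}

#' Negentropy approximation of a projection
#'
#' |E[G(y)] - E[G(v)]|^p, where v is a standard Gaussian variable and the
#' Gaussian reference expectation is computed by high-accuracy quadrature.
#' Zero (in expectation) for Gaussian y; larger the further y is from
#' Gaussian. The exponent p only rescales the objective monotonically;
#' default p = 2.
#'
#' @param y numeric vector, approximately zero-mean unit-variance.
#' @inheritParams contrastEval
#' @param p positive exponent (default 2).
#' @return A non-negative scalar.
#' @export
negentropyObjective <- function(y, kind = c("G1", "G2"), a1 = 1, a2 = 1, p = 2) {
  kind <- match.arg(kind)
  EGv <- .gaussian_contrast_expectation(kind, a1, a2)
  abs(mean(contrastEval(y, kind, a1, a2)$G) - EGv)^p
}

## E[G(v)] for standard Gaussian v, by adaptive quadrature (cached).
.gauss_EG_cache <- new.env(parent = emptyenv())
.gaussian_contrast_expectation <- function(kind, a1, a2) {
  key <- paste(kind, a1, a2, sep = "_")
  if (!is.null(.gauss_EG_cache[[key]])) return(.gauss_EG_cache[[key]])
  f <- function(v) contrastEval(v, kind, a1, a2)$G * stats::dnorm(v)
  val <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-12)$value
  .gauss_EG_cache[[key]] <- val
  val
}

#' Fit a FastICA model by deflation
#'
#' Fixed-point negentropy maximisation: after centering/whitening, each
#' component vector w is initialised randomly (seeded, unit norm) and
#' iterated as
#' \deqn{w \leftarrow E[z\, g(w^T z)] - E[g'(w^T z)]\, w,}
#' then orthogonalised against previously extracted components
#' (Gram-Schmidt) and renormalised to unit length. Convergence is declared
#' when |<w_k, w_{k-1}>| > 1 - tol. The sign of each component is fixed so
#' its largest-magnitude entry is positive. Non-convergence is reported via
#' the model's `converged` flags, not an error.
#'
#' @param data numeric matrix, one observation per row (raw; whitening is
#'   applied internally unless `whiten = FALSE`, in which case the data must
#'   already be white).
#' @param nComponents number of components to extract (<= whitened
#'   dimension).
#' @inheritParams contrastEval
#' @param tol convergence tolerance on |<w_k, w_{k-1}>| - 1 (default 1e-6).
#' @param maxIter maximum fixed-point iterations per component (default 200).
#' @param seed integer seed for the random initial vectors.
#' @param whiten apply [centerWhiten()] internally (default TRUE).
#' @return An \linkS4class{ICAModel}.
#' @examples
#' s <- cbind(rexp(2000) * sample(c(-1, 1), 2000, TRUE),
#'            rexp(2000) * sample(c(-1, 1), 2000, TRUE))
#' x <- s %*% t(matrix(c(2, 1, 1, 1), 2, 2))
#' fasticaFit(x, 2, seed = 1)
#' @export
fasticaFit <- function(data, nComponents, kind = c("G1", "G2"), a1 = 1, a2 = 1,
                       tol = 1e-6, maxIter = 200L, seed = NULL,
                       whiten = TRUE) {
  kind <- match.arg(kind)
  X <- as.matrix(data)
  if (whiten) {
    w <- centerWhiten(X)
    Z <- w$Z; K <- w$whitening; Kinv <- w$dewhitening; mu <- w$mean
  } else {
    Z <- X
    K <- diag(ncol(Z)); Kinv <- diag(ncol(Z)); mu <- rep(0, ncol(Z))
  }
  k <- ncol(Z); n <- nrow(Z)
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L || nComponents > k)
    stop("'nComponents' must be between 1 and the whitened dimension (", k, ")")
  W <- matrix(0, nComponents, k)
  nIter <- integer(nComponents)
  conv <- logical(nComponents)
  with_seed(seed, {
    for (comp in seq_len(nComponents)) {
      w <- stats::rnorm(k)
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(maxIter)) {
        wOld <- w
        y <- Z %*% w
        ce <- contrastEval(y, kind, a1, a2)
        w <- crossprod(Z, ce$g)[, 1] / n - mean(ce$gprime) * w
        if (comp > 1L) {
          prev <- W[seq_len(comp - 1L), , drop = FALSE]
          w <- w - crossprod(prev, prev %*% w)[, 1]
        }
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) {  # degenerate direction; restart randomly
          w <- stats::rnorm(k)
          if (comp > 1L) {
            prev <- W[seq_len(comp - 1L), , drop = FALSE]
            w <- w - crossprod(prev, prev %*% w)[, 1]
          }
          nw <- sqrt(sum(w^2))
        }
        w <- w / nw
        if (abs(sum(w * wOld)) > 1 - tol) {
          conv[comp] <- TRUE
          nIter[comp] <- it
          break
        }
        nIter[comp] <- it
      }
      if (max(abs(w)) > 0 && w[which.max(abs(w))] < 0) w <- -w
      W[comp, ] <- w
    }
  })
  new("ICAModel", dataMean = mu, whitening = K, dewhitening = Kinv, W = W,
      contrast = kind, a1 = a1, a2 = a2, nIter = nIter, converged = conv)
}

#' Extract sliding patches from an image
#'
#' Cuts square patches of side `patchSize` at the configured stride,
#' flattening each patch row-major into one column of the returned matrix.
#' The right and bottom edges are always covered: the final patch origin on
#' each axis is clamped to the border. With `removeDC` each patch's mean is
#' subtracted and returned separately.
#'
#' @param img a \linkS4class{GrayImage} or numeric matrix.
#' @param cfg a \linkS4class{PatchConfig}.
#' @return A list: `patches` (patchSize^2 x nPatches), `means` (per-patch DC,
#'   zeros when `removeDC` is off), `geometry` (dims, origins, config) for
#'   [reconstructPatches()].
#' @export
extractPatches <- function(img, cfg = PatchConfig()) {
  p <- as_pixel_matrix(img)
  validObject(cfg)
  ps <- cfg@patchSize; st <- cfg@stride
  A <- nrow(p); B <- ncol(p)
  if (ps > A || ps > B)
    stop("patch size ", ps, " exceeds image size ", A, "x", B)
  rowStarts <- unique(c(seq(1L, A - ps + 1L, by = st), A - ps + 1L))
  colStarts <- unique(c(seq(1L, B - ps + 1L, by = st), B - ps + 1L))
  nP <- length(rowStarts) * length(colStarts)
  patches <- matrix(0, ps * ps, nP)
  idx <- 1L
  for (rs in rowStarts) for (cs in colStarts) {
    ## row-major flattening of the ps x ps patch
    patches[, idx] <- as.vector(t(p[rs:(rs + ps - 1L), cs:(cs + ps - 1L)]))
    idx <- idx + 1L
  }
  means <- if (cfg@removeDC) colMeans(patches) else numeric(nP)
  if (cfg@removeDC) patches <- sweep(patches, 2L, means)
  list(patches = patches, means = means,
       geometry = list(dim = c(A, B), patchSize = ps, stride = st,
                       rowStarts = rowStarts, colStarts = colStarts,
                       removeDC = cfg@removeDC))
}

#' Reassemble an image from (processed) patches
#'
#' Overlap-add inverse of [extractPatches()]: per-patch DC means are
#' re-added, every patch is placed back at its origin, and each pixel is
#' averaged over the number of patches covering it. With unprocessed patches
#' the round trip is exact.
#'
#' @param patches matrix as returned by [extractPatches()].
#' @param means per-patch DC means.
#' @param geometry the geometry list from [extractPatches()].
#' @return A numeric matrix of the original image dimensions.
#' @export
reconstructPatches <- function(patches, means, geometry) {
  ps <- geometry$patchSize
  if (nrow(patches) != ps * ps)
    stop("patch matrix rows (", nrow(patches), ") inconsistent with patch size ",
         ps)
  nP <- length(geometry$rowStarts) * length(geometry$colStarts)
  if (ncol(patches) != nP || length(means) != nP)
    stop("patch count inconsistent with geometry")
  acc <- matrix(0, geometry$dim[1], geometry$dim[2])
  cnt <- matrix(0, geometry$dim[1], geometry$dim[2])
  idx <- 1L
  for (rs in geometry$rowStarts) for (cs in geometry$colStarts) {
    patch <- matrix(patches[, idx] + means[idx], ps, ps, byrow = TRUE)
    ri <- rs:(rs + ps - 1L); ci <- cs:(cs + ps - 1L)
    acc[ri, ci] <- acc[ri, ci] + patch
    cnt[ri, ci] <- cnt[ri, ci] + 1
    idx <- idx + 1L
  }
  acc / cnt
}

#' Soft-threshold shrinkage of component responses
#'
#' Sparse-code shrinkage: s(c) = sign(c) max(0, |c| - t) with threshold
#' t = sigma^2 / componentScale, where `sigma` is the noise standard
#' deviation propagated to this component and `componentScale` the robust
#' scale (MAD / 0.6745) of the component's responses. With sigma = 0 the
#' code passes through unchanged.
#'
#' @param code numeric vector of responses of one component.
#' @param sigma noise standard deviation at this component, >= 0.
#' @param componentScale robust scale of the responses, > 0.
#' @return The shrunken code vector.
#' @examples
#' shrinkCode(c(-5, -1, 0, 1, 5), sigma = 2, componentScale = 2)  # t = 2
#' @export
shrinkCode <- function(code, sigma, componentScale) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(code)
  t <- sigma^2 / max(componentScale, .Machine$double.eps)
  sign(code) * pmax(0, abs(code) - t)
}

#' Denoise an image by patch-based ICA sparse-code shrinkage
#'
#' The polluted image is treated as a mixture of source structure and noise:
#' overlapping patches are extracted, an ICA basis is fitted to the (noisy)
#' patches themselves by [fasticaFit()], patch vectors are projected onto
#' the unit-norm components, the resulting sparse codes are soft-thresholded
#' per component ([shrinkCode()]), and the image is rebuilt by overlap-add
#' reconstruction. Per-patch DC means bypass the shrinkage.
#'
#' The per-component threshold is sigma_i^2 / scale_i, where sigma_i is the
#' pixel noise level propagated through component i's analysis filter and
#' scale_i the robust (MAD-based) scale of the *signal* part of its
#' responses — the response scale with the propagated noise variance
#' subtracted in quadrature. Components carrying no signal beyond the noise
#' floor therefore receive an unbounded threshold and are removed outright,
#' which is what makes the method competitive on noise-dominated bands.
#'
#' The fit needs many more patches than patch dimensions (patchSize^2):
#' with too few patches the whitening eigenvalues are underestimated, the
#' propagated noise level is overstated, and the shrinkage over-suppresses
#' real structure. At the default 8 px / stride 4 configuration an image of
#' roughly 128 x 128 or larger is advisable.
#'
#' @param img a \linkS4class{GrayImage}.
#' @param cfg a \linkS4class{PatchConfig} (default 8 px patches, stride 4).
#' @param sigma pixel noise standard deviation, or "auto" to estimate it
#'   with [estimateSigma()].
#' @param model a pre-fitted \linkS4class{ICAModel} to reuse, or "fit"
#'   (default) to fit on this image's patches.
#' @param nComponents components to extract; default the whitened patch
#'   dimension (patchSize^2, minus dropped dimensions).
#' @param seed integer seed for the ICA initialisation (fixes the output
#'   bit-for-bit).
#' @param ... further arguments passed to [fasticaFit()] (contrast kind,
#'   a1, a2, tol, maxIter).
#' @return A denoised \linkS4class{GrayImage} of the same shape.
#' @examples
#' clean <- generatePhantom(PhantomSpec(shape = c(96L, 96L)))
#' noisy <- degradeImage(clean, NoiseSpec(sigma = 20, seed = 3))
#' out <- icaDenoise(noisy, sigma = 20, seed = 3)
#' imagePSNR(clean, out) > imagePSNR(clean, noisy)
#' @export
icaDenoise <- function(img, cfg = PatchConfig(), sigma = "auto", model = "fit",
                       nComponents = NULL, seed = NULL, ...) {
  stopifnot(is(img, "GrayImage"))
  validObject(img)
  if (identical(sigma, "auto")) sigma <- estimateSigma(img)
  if (sigma < 0) stop("'sigma' must be >= 0")
  ex <- extractPatches(img, cfg)
  X <- t(ex$patches)                       # observations in rows
  if (identical(model, "fit")) {
    if (is.null(nComponents)) nComponents <- ncol(X)
    ## whitening may drop near-null dimensions; retry with the reduced count
    cw <- centerWhiten(X)
    nComponents <- min(nComponents, ncol(cw$Z))
    model <- fasticaFit(X, nComponents, seed = seed, ...)
  }
  stopifnot(is(model, "ICAModel"))
  Z <- sweep(X, 2L, model@dataMean) %*% t(model@whitening)
  S <- Z %*% t(model@W)                    # component responses (codes)
  ## pixel-domain analysis filters: rows of W K; noise std per component
  F <- model@W %*% model@whitening
  sigmaComp <- sigma * sqrt(rowSums(F^2))
  for (i in seq_len(ncol(S))) {
    ## robust scale of the *signal* part of the responses: the MAD-based
    ## scale of the noisy code, with the propagated noise variance removed.
    ## Components whose responses are pure noise get scale 0, i.e. an
    ## infinite threshold, and are suppressed entirely.
    sc <- sqrt(max(stats::mad(S[, i])^2 - sigmaComp[i]^2, 0))
    S[, i] <- shrinkCode(S[, i], sigmaComp[i], sc)
  }
  ## W rows orthonormal: synthesis is the transpose in whitened space
  Zhat <- S %*% model@W
  Xhat <- sweep(Zhat %*% t(model@dewhitening), 2L, model@dataMean, `+`)
  out <- reconstructPatches(t(Xhat), ex$means, ex$geometry)
  GrayImage(out, grayRange = img@grayRange,
            origin = sprintf("icaDenoise(%s, sigma=%.4g)",
                             ifelse(nzchar(img@origin), img@origin, "image"),
                             sigma))
}

#' Separate registered noisy copies into independent component images
#'
#' Secondary blind-separation entry point: given two or more registered
#' observations of the same scene (e.g. repeated noisy acquisitions), each
#' image is one mixture row and each pixel one sample; FastICA unmixes them
#' into maximally independent component images, typically splitting shared
#' structure from independent noise.
#'
#' @param imgs list of >= 2 \linkS4class{GrayImage}s with identical shape.
#' @param seed integer seed for the ICA initialisation.
#' @param ... passed to [fasticaFit()].
#' @return A list: `components` (list of component images, unit-variance
#'   scale), `model` the fitted \linkS4class{ICAModel}.
#' @export
icaSeparate <- function(imgs, seed = NULL, ...) {
  if (length(imgs) < 2L) stop("need at least two registered images")
  mats <- lapply(imgs, as_pixel_matrix)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("all images must have identical dimensions")
  X <- do.call(cbind, lapply(mats, as.vector))   # pixels x images
  model <- fasticaFit(X, nComponents = length(imgs), seed = seed, ...)
  Z <- sweep(X, 2L, model@dataMean) %*% t(model@whitening)
  S <- Z %*% t(model@W)
  comps <- lapply(seq_len(ncol(S)), function(i) {
    GrayImage(matrix(S[, i], d[1], d[2]),
              grayRange = grayRange(imgs[[1]]),
              origin = sprintf("icaSeparate component %d", i))
  })
  list(components = comps, model = model)
}
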