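test_that("contrast functions are odd, correct at anchors, with exact derivatives", {
  for (kind in c("G1", "G2")) {
    expect_equal(contrastEval(0, kind)$g, 0)
    # g' matches a centered finite difference of g on a grid in [-3, 3]
    u <- seq(-3, 3, length.out = 100)
    h <- 1e-5
    fd <- (contrastEval(u + h, kind)$g - contrastEval(u - h, kind)$g) / (2 * h)
    expect_equal(contrastEval(u, kind)$gprime, fd, tolerance = 1e-6)
  }
  expect_equal(contrastEval(1, "G1", a1 = 1)$g, tanh(1))
  expect_error(contrastEval(1, "G1", a1 = 3), "a1")
  expect_error(contrastEval(1, "G2", a2 = -1), "a2")
})

test_that("centerWhiten yields zero mean and identity covariance", {
  set.seed(2)
  X <- matrix(rnorm(5000 * 3), ncol = 3) %*%
    matrix(c(3, 1, 0, 1, 2, 0.5, 0, 0.5, 1), 3, 3)
  w <- centerWhiten(X)
  expect_lt(max(abs(colMeans(w$Z))), 1e-8)
  C <- crossprod(w$Z) / nrow(w$Z)
  expect_lt(max(abs(C - diag(ncol(w$Z)))), 1e-8)
  # dewhitening inverts whitening
  expect_equal(w$whitening %*% w$dewhitening, diag(ncol(w$Z)), tolerance = 1e-8)
  # 1-D data with population variance 4 -> whitening scalar 1/2
  x1 <- matrix(rep(c(-2, 2), 50), ncol = 1)
  expect_equal(abs(as.numeric(centerWhiten(x1)$whitening)), 0.5)
  expect_error(centerWhiten(matrix(1, 2, 3)), "observations")
})

test_that("FastICA separates Laplacian mixtures and flags Gaussian data", {
  mixing <- matrix(c(2, 1, 1, 1), 2, 2, byrow = TRUE)
  for (seed in 1:3) {
    set.seed(seed + 100)
    S <- cbind(rlaplace(20000), rlaplace(20000))
    X <- S %*% t(mixing)
    m <- fasticaFit(X, 2, seed = seed)
    expect_true(all(converged(m)))
    W <- icaComponents(m)
    expect_equal(rowSums(W^2), c(1, 1), tolerance = 1e-10)  # unit norm
    expect_lt(abs(sum(W[1, ] * W[2, ])), 1e-8)              # orthogonal
    expect_gt(matched_abs_cor(unmix_sources(X, m), S), 0.95)
  }
  # single source in 1-D: the only directions are +/- 1
  s1 <- matrix(rlaplace(5000), ncol = 1)
  m1 <- fasticaFit(s1, 1, seed = 2)
  expect_equal(abs(as.numeric(icaComponents(m1))), 1)
  # Gaussian sources are unidentifiable: non-convergence is flagged, not thrown
  set.seed(5)
  G <- matrix(rnorm(40000), ncol = 2) %*% t(mixing)
  mg <- fasticaFit(G, 2, seed = 1)
  expect_false(all(converged(mg)))
  expect_error(fasticaFit(G, 5, seed = 1), "nComponents")
})

test_that("negentropy objective separates Gaussian from Laplacian projections", {
  set.seed(9)
  g <- rnorm(1e5)
  g <- (g - mean(g)) / sd(g)
  l <- rlaplace(1e5)
  l <- (l - mean(l)) / sd(l)
  expect_lt(negentropyObjective(g), 1e-3)
  expect_gt(negentropyObjective(l), negentropyObjective(g))
  # p only rescales monotonically: ordering identical under p = 1 and p = 2
  dirs <- lapply(1:5, function(i) 0.2 * i * l + sqrt(1 - (0.2 * i)^2) * g)
  o1 <- vapply(dirs, negentropyObjective, numeric(1), p = 1)
  o2 <- vapply(dirs, negentropyObjective, numeric(1), p = 2)
  expect_identical(order(o1), order(o2))
})

test_that("patch extraction covers the image with the documented geometry", {
  m8 <- matrix(1:64, 8, 8)
  ex <- extractPatches(m8, PatchConfig(8, 8))
  expect_equal(ncol(ex$patches), 1)
  expect_equal(ex$patches[, 1] + ex$means[1], as.vector(t(m8)))  # row-major
  ex16 <- extractPatches(matrix(rnorm(256), 16, 16), PatchConfig(8, 8, FALSE))
  expect_equal(ncol(ex16$patches), 4)
  # 10x10 image, patch 8, stride 4: origins clamp to {1, 3} on each axis
  ex10 <- extractPatches(matrix(0, 10, 10), PatchConfig(8, 4))
  expect_equal(ex10$geometry$rowStarts, c(1L, 3L))
  expect_equal(ex10$geometry$colStarts, c(1L, 3L))
  expect_equal(ncol(ex10$patches), 4)
  expect_error(extractPatches(matrix(0, 4, 4), PatchConfig(8, 4)), "exceeds")
})

test_that("patch reconstruction is exact and averages overlaps", {
  img <- pixels(generatePhantom(tiny_phantom_spec()))
  for (cfg in list(PatchConfig(8, 4), PatchConfig(8, 8), PatchConfig(5, 3),
                   PatchConfig(8, 4, removeDC = FALSE))) {
    ex <- extractPatches(img, cfg)
    expect_equal(reconstructPatches(ex$patches, ex$means, ex$geometry), img)
  }
  # all-zero patches, removeDC off -> all-zero image
  ex0 <- extractPatches(matrix(0, 16, 16), PatchConfig(8, 8, removeDC = FALSE))
  expect_true(all(reconstructPatches(ex0$patches, ex0$means, ex0$geometry) == 0))
  # two overlapping patches disagreeing by 2 reconstruct to their mean
  ex2 <- extractPatches(matrix(5, 8, 12), PatchConfig(8, 4, removeDC = FALSE))
  expect_equal(ncol(ex2$patches), 2)
  pert <- ex2$patches
  pert[, 2] <- pert[, 2] + 2
  rec <- reconstructPatches(pert, ex2$means, ex2$geometry)
  expect_equal(rec[1, 1], 5)        # covered only by patch 1
  expect_equal(rec[1, 12], 7)       # covered only by patch 2 (5 + 2)
  expect_equal(rec[1, 6], 6)        # overlap: mean of 5 and 7
  expect_error(reconstructPatches(pert[, 1, drop = FALSE], ex2$means,
                                  ex2$geometry), "inconsistent")
})

test_that("shrinkCode implements soft thresholding with t = sigma^2/scale", {
  code <- c(-5, -1.5, 0, 1.5, 5)
  expect_identical(shrinkCode(code, 0, 1), code)          # sigma 0: identity
  expect_equal(shrinkCode(code, 2, 2), c(-3, 0, 0, 0, 3)) # t = 2
  expect_true(all(shrinkCode(c(0.5, -1.9), 2, 2) == 0))   # kill zone |c| < t
  expect_error(shrinkCode(code, -1, 1), "sigma")
})

test_that("ICA denoising is near-lossless at sigma 0 and deterministic", {
  img <- generatePhantom(tiny_phantom_spec())
  out0 <- icaDenoise(img, sigma = 0, seed = 1)
  expect_lt(imageRMSE(img, out0), 1.0)
  a <- icaDenoise(img, sigma = 5, seed = 7)
  b <- icaDenoise(img, sigma = 5, seed = 7)
  expect_identical(pixels(a), pixels(b))
})

test_that("ICA denoising improves a noisy phantom and never degrades it", {
  clean <- generatePhantom(tiny_phantom_spec())
  noisy <- degradeImage(clean, NoiseSpec(sigma = 20, seed = 3))
  out <- icaDenoise(noisy, sigma = 20, seed = 3)
  expect_gt(imagePSNR(clean, out), imagePSNR(clean, noisy) + 2)
  # with sigma correctly specified, MSE must not grow by more than 1%;
  # checked at the full phantom size, where the patch sample (~4000) is
  # large relative to the 64 patch dimensions as the method requires
  cleanFull <- generatePhantom(PhantomSpec())
  for (s in c(10, 30)) {
    ns <- degradeImage(cleanFull, NoiseSpec(sigma = s, seed = s))
    o <- icaDenoise(ns, sigma = s, seed = 1)
    expect_lt(imageMSE(cleanFull, o), 1.01 * imageMSE(cleanFull, ns))
  }
})

test_that("extracted components are more non-Gaussian than random directions", {
  clean <- generatePhantom(tiny_phantom_spec())
  noisy <- degradeImage(clean, NoiseSpec(sigma = 10, seed = 2))
  ex <- extractPatches(noisy, PatchConfig())
  X <- t(ex$patches)
  m <- fasticaFit(X, 12, seed = 4)
  Z <- sweep(X, 2, m@dataMean) %*% t(m@whitening)
  k <- ncol(Z)
  stdz <- function(y) (y - mean(y)) / sd(y)
  compObj <- apply(Z %*% t(icaComponents(m)), 2,
                   function(y) negentropyObjective(stdz(y)))
  set.seed(11)
  randObj <- replicate(20, {
    w <- rnorm(k); w <- w / sqrt(sum(w^2))
    negentropyObjective(stdz(Z %*% w))
  })
  expect_true(all(compObj >= median(randObj)))
})

test_that("blind separation splits structure from independent noise", {
  img <- pixels(generatePhantom(tiny_phantom_spec(textureAmp = 0)))
  set.seed(6)
  noise <- matrix(rlaplace(length(img)), nrow(img)) * 30
  obs <- list(GrayImage(img + 0.6 * noise), GrayImage(0.8 * img - 0.5 * noise))
  sep <- icaSeparate(obs, seed = 3)
  cors <- vapply(sep$components, function(cmp)
    abs(cor(as.vector(pixels(cmp)), as.vector(img))), numeric(1))
  expect_gt(max(cors), 0.95)   # one component recovers the image
  expect_lt(min(cors), 0.4)    # the other carries the noise
})
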