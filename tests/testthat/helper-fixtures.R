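# Shared fixtures: everything is generated in code, nothing read from disk.

# Small, fast phantom for unit tests (full-size 256x256 phantoms are used
# only where a property genuinely needs them).
tiny_phantom_spec <- function(seed = 1L, textureAmp = 4) {
  PhantomSpec(shape = c(96L, 96L), seed = seed, textureAmp = textureAmp)
}

# Unit-variance Laplacian sample.
rlaplace <- function(n) {
  (stats::rexp(n, rate = sqrt(2)) * sample(c(-1, 1), n, replace = TRUE))
}

# |correlation| between recovered and true sources after the best
# sign/permutation matching (2-source case).
matched_abs_cor <- function(Y, S) {
  C <- abs(stats::cor(Y, S))
  max(min(C[1, 1], C[2, 2]), min(C[1, 2], C[2, 1]))
}

# Unmix a 2-column mixture with a fitted model.
unmix_sources <- function(X, model) {
  Z <- sweep(X, 2, model@dataMean) %*% t(model@whitening)
  Z %*% t(icaComponents(model))
}
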