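.sweep_methods <- c("ica", "wavelet", "mean", "median", "wiener", "none")

## Apply one named method to a noisy image, given the true noise sigma.
.apply_method <- function(method, noisy, sigma, seed, k = 3L) {
  switch(method,
    none = noisy,
    ica = icaDenoise(noisy, sigma = sigma, seed = seed),
    wavelet = waveletDenoise(noisy, WaveletConfig(noiseSigma = sigma)),
    mean = meanFilter(noisy, k),
    median = medianFilter(noisy, k),
    wiener = wienerFilter(noisy, k, noiseVar = sigma^2),
    stop("unknown method '", method, "'; available: ",
         paste(.sweep_methods, collapse = ", ")))
}

#' Run a method x sigma x seed denoising sweep
#'
#' For every (sigma, seed) a fresh noisy copy of the phantom is drawn and
#' every requested method is scored against the clean reference. "none"
#' scores the raw noisy image. Methods run with the true sigma of each
#' condition; seeds make the sweep fully reproducible.
#'
#' @param methods subset of "ica", "wavelet", "mean", "median", "wiener",
#'   "none".
#' @param sigmas noise levels (default c(10, 20, 30, 40)). An empty grid
#'   yields an empty table.
#' @param nSeeds replicates per sigma (default 3).
#' @param base a \linkS4class{PhantomSpec} for the clean reference.
#' @param seed master seed; per-condition seeds derive from it.
#' @param k kernel size for the spatial filters (default 3).
#' @return A data.frame with columns method, sigma, seed, psnr, rmse, mse,
#'   runtime_s, sorted by (method, sigma, seed).
#' @examples
#' tab <- runSweep(c("none", "mean"), sigmas = 20, nSeeds = 2,
#'                 base = PhantomSpec(shape = c(96L, 96L)))
#' summarizeSweep(tab)
#' @export
runSweep <- function(methods = c("ica", "wavelet", "mean", "none"),
                     sigmas = c(10, 20, 30, 40), nSeeds = 3L,
                     base = PhantomSpec(), seed = 1L, k = 3L) {
  bad <- setdiff(methods, .sweep_methods)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (length(sigmas) == 0L)
    return(data.frame(method = character(), sigma = numeric(),
                      seed = integer(), psnr = numeric(), rmse = numeric(),
                      mse = numeric(), runtime_s = numeric()))
  clean <- generatePhantom(base)
  rows <- list()
  for (si in seq_along(sigmas)) {
    for (rep in seq_len(nSeeds)) {
      condSeed <- child_seed(seed, si, rep)
      noisy <- degradeImage(clean, NoiseSpec(sigma = sigmas[si],
                                             seed = condSeed))
      for (method in methods) {
        t0 <- proc.time()[["elapsed"]]
        out <- .apply_method(method, noisy, sigmas[si],
                             seed = child_seed(condSeed, match(method, .sweep_methods)),
                             k = k)
        dt <- proc.time()[["elapsed"]] - t0
        q <- qualityReport(clean, out)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, sigma = sigmas[si], seed = condSeed,
          psnr = q@psnr, rmse = q@rmse, mse = q@mse, runtime_s = dt)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$method, tab$sigma, tab$seed), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Aggregate a sweep table per method and sigma
#'
#' Mean and standard deviation of PSNR and RMSE within each
#' (method, sigma) cell.
#'
#' @param table a data.frame from [runSweep()].
#' @return A data.frame with columns method, sigma, n, psnr_mean, psnr_sd,
#'   rmse_mean, rmse_sd.
#' @export
summarizeSweep <- function(table) {
  if (is.null(table) || nrow(table) == 0L) stop("empty sweep table")
  agg <- function(f, col)
    stats::aggregate(table[[col]], by = list(method = table$method,
                                             sigma = table$sigma), FUN = f)$x
  base <- stats::aggregate(table$psnr,
                           by = list(method = table$method,
                                     sigma = table$sigma), FUN = length)
  out <- data.frame(method = base$method, sigma = base$sigma, n = base$x,
                    psnr_mean = agg(mean, "psnr"),
                    psnr_sd = agg(stats::sd, "psnr"),
                    rmse_mean = agg(mean, "rmse"),
                    rmse_sd = agg(stats::sd, "rmse"))
  out$psnr_sd[is.na(out$psnr_sd)] <- 0
  out$rmse_sd[is.na(out$rmse_sd)] <- 0
  out[order(out$method, out$sigma), , drop = FALSE]
}
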