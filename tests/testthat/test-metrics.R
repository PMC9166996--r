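test_that("MSE/RMSE/PSNR match their definitions on worked examples", {
  z <- matrix(0, 2, 2)
  t24 <- matrix(c(1, 3, 2, 4), 2, 2)         # [[1,2],[3,4]]
  expect_equal(imageMSE(z, z), 0)
  expect_equal(imageMSE(z, z + 3), 9)        # constant offset c -> c^2
  expect_equal(imageMSE(z, t24), 7.5)        # (1+4+9+16)/4
  expect_equal(imageRMSE(z, t24), sqrt(7.5))
  expect_equal(imageRMSE(z, z + 3), 3)
  expect_equal(imagePSNR(z, z, L = 255), Inf)
  expect_equal(imagePSNR(z, z + 255, L = 255), 0)          # worst case
  expect_equal(imagePSNR(z, z + 25.5, L = 255), 20)        # mse = 650.25
  expect_error(imageMSE(z, matrix(0, 3, 2)), "differ")
  expect_error(imagePSNR(z, t24, L = 0), "positive")
})

test_that("qualityReport is internally consistent and PSNR is monotone in MSE", {
  img <- generatePhantom(tiny_phantom_spec())
  q <- qualityReport(img, degradeImage(img, NoiseSpec(sigma = 10, seed = 1)))
  expect_s4_class(q, "QualityReport")
  expect_equal(q@rmse^2, q@mse)
  expect_equal(q@psnr, 10 * log10(255^2 / q@mse))
  psnrs <- vapply(c(5, 10, 20, 40), function(s) {
    imagePSNR(img, degradeImage(img, NoiseSpec(sigma = s, seed = 1)))
  }, numeric(1))
  expect_true(all(diff(psnrs) < 0))
  # any nonzero perturbation lowers psnr from +Inf
  expect_lt(psnrs[1], Inf)
})

test_that("diagnosticSummary reproduces the diagnostic-table arithmetic", {
  got <- diagnosticSummary(ConfusionTable(tp = 36, fn = 4, tn = 39, fp = 1))
  expect_equal(unname(got), c(90.0, 97.5, 93.8))   # 75/80 = 93.75 -> 93.8
  got2 <- diagnosticSummary(ConfusionTable(tp = 38, fn = 2, tn = 39, fp = 1))
  expect_equal(unname(got2), c(95.0, 97.5, 96.3))  # 77/80 = 96.25 -> 96.3
  perfect <- diagnosticSummary(ConfusionTable(40, 0, 40, 0))
  expect_equal(unname(perfect), c(100, 100, 100))
  expect_error(diagnosticSummary(ConfusionTable(0, 0, 5, 5)), "sensitivity")
  expect_error(diagnosticSummary(ConfusionTable(5, 5, 0, 0)), "specificity")
})

test_that("accuracy always lies between sensitivity and specificity", {
  set.seed(1)
  for (i in 1:25) {
    ct <- ConfusionTable(tp = sample(0:30, 1), fn = sample(1:30, 1),
                         tn = sample(0:30, 1), fp = sample(1:30, 1))
    d <- diagnosticSummary(ct)
    expect_gte(d[["accuracy"]], min(d[["sensitivity"]], d[["specificity"]]) - 0.05)
    expect_lte(d[["accuracy"]], max(d[["sensitivity"]], d[["specificity"]]) + 0.05)
  }
})

test_that("confusionFromRates inverts reported percentages into counts", {
  ct <- confusionFromRates(90, 97.5, 40, 40)
  expect_equal(c(ct@tp, ct@fn, ct@tn, ct@fp), c(36L, 4L, 39L, 1L))
  expect_error(confusionFromRates(91, 97.5, 40, 40), "inconsistent")
})

test_that("subjective grading levels map to their fixed labels", {
  expect_equal(subjectiveGrade(1)$label, "Poor")
  expect_equal(subjectiveGrade(2)$label, "General")
  expect_equal(subjectiveGrade(3)$label, "Good")
  expect_equal(subjectiveGrade(4)$label, "Excellent")
  expect_error(subjectiveGrade(5))
})
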