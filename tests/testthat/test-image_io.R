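test_that("PNG write/read round trip preserves integer images and metadata", {
  img <- generatePhantom(tiny_phantom_spec(textureAmp = 0))
  f <- withr::local_tempfile(fileext = ".png")
  writeGrayImage(img, f, bitDepth = 8L)
  back <- readGrayImage(f)
  expect_identical(dim(back), c(96L, 96L))
  expect_equal(grayRange(back), 255)
  # phantom levels are integers, so quantization is lossless
  expect_equal(pixels(back), pixels(img))
})

test_that("16-bit TIFF round trip reports L = 65535 and is lossless", {
  p <- matrix(round(seq(0, 65535, length.out = 64)), 8, 8)
  img <- GrayImage(p, grayRange = 65535)
  f <- withr::local_tempfile(fileext = ".tif")
  writeGrayImage(img, f, bitDepth = 16L)
  back <- readGrayImage(f)
  expect_equal(grayRange(back), 65535)
  expect_equal(pixels(back), p)
})

test_that("writing clips to the representable range and maps endpoints", {
  f <- withr::local_tempfile(fileext = ".png")
  writeGrayImage(GrayImage(matrix(0, 4, 4)), f)
  expect_true(all(pixels(readGrayImage(f)) == 0))
  img <- GrayImage(matrix(c(255, 265, -3, 128), 2, 2), grayRange = 255)
  writeGrayImage(img, f)
  got <- pixels(readGrayImage(f))
  expect_equal(got[1, 1], 255)   # value L -> max code
  expect_equal(got[2, 1], 255)   # L + 10 clipped to max code
  expect_equal(got[1, 2], 0)     # negative clipped to 0
})

test_that("16-bit PNG writing is refused, unknown formats and RGB are errors", {
  img <- GrayImage(matrix(1, 2, 2))
  expect_error(writeGrayImage(img, tempfile(fileext = ".png"), 16L), "TIFF")
  expect_error(writeGrayImage(img, tempfile(fileext = ".bmp")), "unsupported")
  expect_error(readGrayImage(tempfile(fileext = ".png")), "not found")
  # RGB png: rejected without forceGray, luminance-converted with it
  f <- withr::local_tempfile(fileext = ".png")
  rgb <- array(0, c(4, 4, 3)); rgb[, , 1] <- 1
  png::writePNG(rgb, f)
  expect_error(readGrayImage(f), "forceGray")
  lum <- readGrayImage(f, forceGray = TRUE)
  expect_equal(pixels(lum)[1, 1], 0.299 * 255, tolerance = 1e-6)
})

test_that("normalizeImage rescales linearly and is invertible", {
  img <- GrayImage(matrix(c(0, 51, 204, 255), 2, 2), grayRange = 255)
  same <- normalizeImage(img, 255)
  expect_equal(pixels(same), pixels(img))
  unit <- normalizeImage(img, 1)
  expect_equal(grayRange(unit), 1)
  expect_equal(pixels(unit)[2, 1], 0.2)      # 51/255
  expect_equal(pixels(unit)[2, 2], 1.0)      # endpoint
  # normalize(normalize(img, a), L) recovers img to relative 1e-9
  back <- normalizeImage(normalizeImage(img, 7.3), 255)
  expect_equal(pixels(back), pixels(img), tolerance = 1e-9)
  expect_error(normalizeImage(img, 0), "positive")
})

test_that("GrayImage validity rejects degenerate inputs", {
  expect_error(GrayImage(matrix(1, 2, 2), grayRange = -1))
  expect_error(new("GrayImage", pixels = matrix(numeric(0), 0, 0),
                   grayRange = 255, origin = ""))
})
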