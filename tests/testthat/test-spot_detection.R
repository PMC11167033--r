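test_that("default detection parameters are the published ones", {
  p <- default_detection_params()
  expect_equal(p$diameter_um, 8)
  expect_equal(p$quality_min, 1)
})

test_that("detection parameters validate and round-trip", {
  p <- detection_params(diameter_um = 5, quality_min = 0.3, subpixel = TRUE)
  q <- do.call(detection_params, lapply(unclass(p), identity))
  expect_equal(p, q)
  expect_error(detection_params(diameter_um = -1), "diameter_um")
})

test_that("LoG response of a constant image is numerically zero", {
  img <- matrix(7.3, 48, 48)
  r <- log_response(img, 8, 1)
  expect_lt(max(abs(r)), 1e-6 * max(img))
})

test_that("LoG response is invariant to an added constant", {
  set.seed(10)
  img <- matrix(runif(48 * 48), 48, 48)
  r1 <- log_response(img, 8, 1)
  r2 <- log_response(img + 5, 8, 1)
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("LoG peak of a matched blob sits at the blob center", {
  sigma <- 8 / (2 * sqrt(2))
  img <- make_blob_image(48, 48, cx = 23, cy = 25, sigma = sigma,
                         amplitude = 2)
  r <- log_response(img, 8, 1)
  peak <- which(r == max(r), arr.ind = TRUE)
  expect_lte(abs(peak[1, "row"] - 1 - 25), 1)
  expect_lte(abs(peak[1, "col"] - 1 - 23), 1)
  # dense-convolution oracle agrees everywhere
  expect_equal(r, oracle_log_response(img, 8), tolerance = 1e-6)
})

test_that("log_response rejects sub-pixel diameters", {
  expect_error(log_response(matrix(0, 8, 8), diameter_um = 0.5,
                            pixel_size_um = 1), "smaller than 1 pixel")
})

test_that("two well-separated blobs are both detected near their centers", {
  sigma <- 8 / (2 * sqrt(2))
  img <- make_blob_image(96, 96, cx = c(25, 70), cy = c(30, 65),
                         sigma = c(sigma, sigma), amplitude = c(3, 3))
  det <- detect_spots(img, detection_params(8, 0.5), 1)
  expect_equal(nrow(det), 2L)
  det <- det[order(det$x_px), ]
  expect_lte(max(abs(det$x_px - c(25, 70))), 1)
  expect_lte(max(abs(det$y_px - c(30, 65))), 1)
  # oracle: brute-force maxima of the dense-convolved response
  ro <- oracle_log_response(img, 8)
  top2 <- order(ro, decreasing = TRUE)[1:2]
  oy <- (top2 - 1) %% 96
  ox <- (top2 - 1) %/% 96
  expect_lte(max(abs(sort(ox) - sort(det$x_px))), 1)
})

test_that("a blob below the quality threshold is rejected", {
  sigma <- 8 / (2 * sqrt(2))
  img <- make_blob_image(48, 48, cx = 24, cy = 24, sigma = sigma,
                         amplitude = 2)
  peak <- max(oracle_log_response(img, 8))
  det <- detect_spots(img, detection_params(8, quality_min = peak * 1.1), 1)
  expect_equal(nrow(det), 0L)
  det <- detect_spots(img, detection_params(8, quality_min = peak * 0.9), 1)
  expect_equal(nrow(det), 1L)
})

test_that("an all-zero image yields no detections", {
  expect_equal(nrow(detect_spots(matrix(0, 32, 32),
                                 default_detection_params(), 1)), 0L)
})

test_that("lowering the quality threshold never removes a detection", {
  set.seed(11)
  img <- make_blob_image(96, 96, cx = c(20, 50, 75), cy = c(70, 25, 60),
                         sigma = rep(8 / (2 * sqrt(2)), 3),
                         amplitude = c(1, 2, 3)) +
    matrix(rnorm(96 * 96, 0, 0.02), 96, 96)
  hi <- detect_spots(img, detection_params(8, 0.8), 1)
  lo <- detect_spots(img, detection_params(8, 0.2), 1)
  key <- function(d) paste(d$x_px, d$y_px)
  expect_true(all(key(hi) %in% key(lo)))
  expect_gte(nrow(lo), nrow(hi))
})

test_that("detections shift with an integer translation of the image", {
  set.seed(12)
  sigma <- 8 / (2 * sqrt(2))
  base <- make_blob_image(120, 120, cx = c(40, 60), cy = c(45, 80),
                          sigma = c(sigma, sigma), amplitude = c(2, 2))
  shifted <- make_blob_image(120, 120, cx = c(40, 60) + 7, cy = c(45, 80) + 3,
                             sigma = c(sigma, sigma), amplitude = c(2, 2))
  d0 <- detect_spots(base, detection_params(8, 0.5), 1)
  d1 <- detect_spots(shifted, detection_params(8, 0.5), 1)
  expect_equal(nrow(d0), nrow(d1))
  expect_equal(sort(d1$x_px), sort(d0$x_px) + 7)
  expect_equal(sort(d1$y_px), sort(d0$y_px) + 3)
})

test_that("subpixel refinement localizes an off-grid blob to < 0.3 px", {
  sigma <- 8 / (2 * sqrt(2))
  img <- make_blob_image(48, 48, cx = 23.4, cy = 24.6, sigma = sigma,
                         amplitude = 2)
  det <- detect_spots(img, detection_params(8, 0.5, subpixel = TRUE), 1)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_px - 23.4), 0.3)
  expect_lt(abs(det$y_px - 24.6), 0.3)
})

test_that("detect_movie indexes frames from zero in acquisition order", {
  sigma <- 8 / (2 * sqrt(2))
  frames <- lapply(c(20, 40), function(cx) {
    make_blob_image(64, 64, cx = cx, cy = 32, sigma = sigma, amplitude = 3)
  })
  mov <- movie(list(treg = frames), 1, 5)
  det <- detect_movie(mov, "treg", detection_params(8, 0.5))
  expect_equal(det$frame, c(0L, 1L))
  expect_equal(det$x_px, c(20, 40), tolerance = 1)
})
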