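# Contrast-enhancement chain: each stage against its contract.

mk <- function(v, h = 20, w = 30) matrix(v, h, w)
full_mask <- function(h = 20, w = 30) matrix(1, h, w)

test_that("histogram centering shifts dark foregrounds onto the target", {
  m <- full_mask()
  expect_equal(center_histogram(mk(100), m), mk(100))
  out <- center_histogram(mk(40), m)
  expect_true(all(out == 100))
  # bimodal foreground already centered
  img <- mk(0); img[, 16:30] <- 200
  expect_equal(center_histogram(img, m), img)
  # achieved mean within rounding of the target for a mixed dark image
  set.seed(1)
  img2 <- matrix(sample(10:60, 600, replace = TRUE), 20, 30)
  out2 <- center_histogram(img2, m)
  expect_lt(abs(mean(out2) - 100), 1)
  # brighter-than-target images pass through by default but not when forced
  expect_equal(center_histogram(mk(180), m), mk(180))
  expect_true(all(center_histogram(mk(180), m, darker_only = FALSE) == 100))
  expect_error(center_histogram(mk(40), mk(0)), "foreground")
})

test_that("reflection detection finds 8-connected saturated components", {
  img <- mk(80, 40, 40)
  expect_length(detect_reflections(img), 0)
  img[10:14, 10:14] <- 255
  comps <- detect_reflections(img)
  expect_length(comps, 1)
  expect_equal(nrow(comps[[1]]), 25)
  img[30:33, 25:29] <- 255
  comps <- detect_reflections(img)
  expect_length(comps, 2)
  # diagonal contact joins components (8-connectivity)
  img2 <- mk(80, 40, 40)
  img2[10, 10] <- 255; img2[11, 11] <- 255
  expect_length(detect_reflections(img2), 1)
})

test_that("reflection filling uses the contour mean and touches nothing else", {
  img <- mk(80, 30, 30)
  expect_equal(fill_reflections(img, list()), img)
  img[10:12, 10:12] <- 255
  comp <- which(img == 255, arr.ind = TRUE)
  out <- fill_reflections(img, list(comp))
  expect_true(all(out[10:12, 10:12] == 80))
  expect_equal(out[-(9:13), ], img[-(9:13), ])
  # half-60 / half-100 ring around a single pixel fills with 80
  img2 <- mk(0, 9, 9)
  img2[4, 4:6] <- 60; img2[6, 4:6] <- 100
  img2[5, 4] <- 60; img2[5, 6] <- 100
  img2[5, 5] <- 255
  out2 <- fill_reflections(img2, list(cbind(5L, 5L)))
  expect_equal(out2[5, 5], 80)
})

test_that("dark suppression is a strict-below threshold", {
  expect_equal(black_out_dark(mk(49)), mk(0))
  expect_equal(black_out_dark(mk(50)), mk(50))
  img <- matrix(c(30, 200), 20, 30)
  out <- black_out_dark(img)
  expect_equal(sort(unique(as.vector(out))), c(0, 200))
})

test_that("CLAHE respects range, dimensions, and enhances low-contrast tiles", {
  # a flat field stays flat (the mapped level may shift, contrast cannot)
  flat <- enhance_local_contrast(mk(120, 100, 120))
  expect_equal(stats::sd(flat), 0)
  set.seed(2)
  img <- matrix(round(runif(120 * 100, 0, 255)), 100, 120)
  out <- enhance_local_contrast(img)
  expect_equal(dim(out), dim(img))
  expect_true(min(out) >= 0 && max(out) <= 255)
  # a gentle ramp with faint texture gains local contrast
  ramp <- outer(rep(1, 100), seq(60, 120, length.out = 120))
  set.seed(3)
  ramp <- pmin(pmax(ramp + matrix(rnorm(12000, 0, 3), 100, 120), 0), 255)
  out2 <- enhance_local_contrast(ramp)
  tile <- function(m) sd(m[30:60, 30:60])
  expect_gt(tile(out2), tile(ramp))
  expect_message(enhance_local_contrast(mk(50, 10, 10)), "minimal")
})

test_that("gray closing fills dark holes, is extensive and idempotent", {
  expect_equal(close_gray(mk(77)), mk(77))
  img <- mk(0, 40, 40)
  img[10:29, 10:29] <- 200
  img[20, 20] <- 0
  out <- close_gray(img)
  expect_equal(out[20, 20], 200)
  expect_true(all(out >= img))
  expect_equal(close_gray(out), out)
})

test_that("global equalization stretches to the endpoints and keeps order", {
  expect_message(out <- equalize_global(mk(128)), "constant")
  expect_equal(out, mk(128))
  two <- matrix(c(10, 20), 20, 30)
  out2 <- equalize_global(two)
  expect_setequal(unique(as.vector(out2)), c(0, 255))
  expect_true(all(out2[two == 10] == 0) && all(out2[two == 20] == 255))
  set.seed(4)
  img <- matrix(round(runif(600, 0, 255)), 20, 30)
  out3 <- equalize_global(img)
  ord <- order(img)
  expect_true(all(diff(out3[ord]) >= 0))
})

test_that("the pipeline preserves dimensions, is deterministic, and removes
           saturated blobs", {
  tr <- synth_truth(seed = 11, n_glands = 6,
                    reflections = list(list(y = 320, x = 640, r = 6)))
  sc <- synth_render(tr)
  cfg <- mg_config()
  w1 <- preprocess_pipeline(sc$image, sc$mask, cfg)
  w2 <- preprocess_pipeline(sc$image, sc$mask, cfg)
  expect_equal(dim(w1), dim(sc$image))
  expect_identical(unclass(w1), unclass(w2))
  expect_true(min(w1) >= 0 && max(w1) <= 255)
  # after the reflection stage alone, no blob pixel remains saturated
  cen <- center_histogram(sc$image, sc$mask)
  comps <- detect_reflections(cen)
  expect_gt(length(comps), 0)
  filled <- fill_reflections(cen, comps, sc$mask)
  expect_length(detect_reflections(filled), 0)
})

test_that("disabled centering/reflection stages are no-ops on an already
           clean image", {
  tr <- synth_truth(seed = 12, n_glands = 6, noise_sd = 0)
  sc <- synth_render(tr)
  img <- center_histogram(sc$image, sc$mask)   # pre-center so stage no-ops
  on_cfg <- mg_config()
  off_cfg <- mg_config(preprocess = list(do_center = FALSE,
                                         do_reflections = FALSE))
  expect_equal(as.vector(preprocess_pipeline(img, sc$mask, on_cfg)),
               as.vector(preprocess_pipeline(img, sc$mask, off_cfg)))
})
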