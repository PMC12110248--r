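# Smoothing, peak detection, fusion and width filtering.

test_that("linear Savitzky-Golay smoothing reproduces constants and ramps", {
  const <- as_profile(rep(120, 50), normalized = FALSE)
  sm <- smooth_profile(const)
  expect_true(isTRUE(sm$normalized))
  expect_equal(sm$values, rep(120 / 255, 50))
  ramp <- as_profile(seq(0, 245, by = 5), normalized = FALSE)
  smr <- smooth_profile(ramp)
  interior <- 6:44
  expect_equal(smr$values[interior], (ramp$values / 255)[interior],
               tolerance = 1e-10)
  # an impulse is scaled by the window's central coefficient (1/11)
  imp <- as_profile(c(rep(0, 25), 255, rep(0, 25)), normalized = FALSE)
  smi <- smooth_profile(imp)
  expect_equal(smi$values[26], (255 / 11) / 255, tolerance = 1e-10)
  expect_error(smooth_profile(as_profile(rep(1, 5), normalized = FALSE)),
               "at least 11")
})

test_that("peak detection matches the geometry of simple shapes", {
  expect_equal(nrow(detect_peaks(as_profile(rep(0.5, 100)))), 0)
  # triangle 0 -> 1 -> 0 over 21 samples: apex center, width = half the base
  tri <- c(rep(0, 20), seq(0, 1, length.out = 11), seq(0.9, 0, by = -0.1),
           rep(0, 20))
  pk <- detect_peaks(as_profile(tri))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$index, 31)
  expect_equal(pk$width, 10, tolerance = 0.01)
  # two Gaussian bumps, amplitude 0.8 on baseline 0.1, 100 px apart
  xs <- 1:300
  v <- 0.1 + 0.8 * (exp(-(xs - 100)^2 / (2 * 6^2)) +
                    exp(-(xs - 200)^2 / (2 * 6^2)))
  pk2 <- detect_peaks(as_profile(v))
  expect_equal(nrow(pk2), 2)
  expect_lte(max(abs(pk2$index - c(100, 200))), 1)
  expect_equal(pk2$width, rep(2 * sqrt(2 * log(2)) * 6, 2), tolerance = 0.05)
})

test_that("peak detection agrees with the brute-force oracle", {
  set.seed(99)
  for (rep_i in 1:25) {
    n <- sample(60:500, 1)
    v <- stats::filter(rnorm(n), rep(1 / 7, 7), circular = TRUE)
    v <- (v - min(v)) / (max(v) - min(v))
    got <- detect_peaks(as_profile(as.numeric(v)), prominence = 0.1,
                        min_width = 2)
    want <- bf_peaks(as.numeric(v), prominence = 0.1, min_width = 2)
    expect_equal(got$index, want$index)
    expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
    expect_equal(got$width, want$width, tolerance = 1e-9)
  }
})

test_that("close peaks fuse at the midpoint with summed widths", {
  mk_peaks <- function(xs, widths) data.frame(
    layer = 1L, x = xs, y = 100, index = xs, height = 0.9,
    prominence = 0.5, width = widths)
  fused <- fuse_close_peaks(mk_peaks(c(100, 108), c(6, 8)))
  expect_equal(nrow(fused), 1)
  expect_equal(fused$x, 104)
  expect_equal(fused$width, 14)
  # exactly at the separation: untouched (strictly-closer rule)
  kept <- fuse_close_peaks(mk_peaks(c(100, 110), c(6, 8)))
  expect_equal(kept$x, c(100, 110))
  expect_equal(nrow(fuse_close_peaks(mk_peaks(1, 5)[0, ])), 0)
  # a chain of three mutually close peaks collapses with accumulated width
  chain <- fuse_close_peaks(mk_peaks(c(100, 106, 112), c(4, 5, 6)))
  expect_equal(nrow(chain), 1)
  expect_equal(chain$width, 15)
  # property: no output pair closer than the separation; count never grows
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:15, 1)
    p <- mk_peaks(sort(sample(1:200, n)), runif(n, 2, 20))
    f <- fuse_close_peaks(p)
    expect_lte(nrow(f), n)
    if (nrow(f) > 1) expect_true(all(diff(f$x) >= 10))
    expect_equal(sum(f$width), sum(p$width))
  }
})

test_that("implausibly wide peaks are dropped, boundary kept", {
  p <- data.frame(layer = 1L, x = c(10, 60, 120), y = 1, index = c(10, 60, 120),
                  height = 1, prominence = 0.5, width = c(12, 95, 30))
  expect_equal(drop_wide_peaks(p)$width, c(12, 30))
  p$width <- c(12, 90, 30)
  expect_equal(drop_wide_peaks(p)$width, c(12, 90, 30))
  expect_equal(nrow(drop_wide_peaks(p[0, ])), 0)
})

test_that("widths measured on the raw profile recover the Gaussian FWHM", {
  xs <- 1:400
  for (sg in c(5, 10, 15)) {
    raw <- 60 + 90 * exp(-(xs - 200)^2 / (2 * sg^2))   # tarsus baseline 60
    prof <- as_profile(raw, normalized = FALSE)
    sm <- smooth_profile(prof)
    pk <- detect_peaks(sm, raw = prof)
    expect_equal(nrow(pk), 1)
    expect_lt(abs(pk$width / (2 * sqrt(2 * log(2)) * sg) - 1), 0.15)
  }
})
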