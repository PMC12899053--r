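test_that("notch filter removes the line frequency and passes the band", {
  fs <- 2000
  t <- seq(0, 6, by = 1 / fs)
  s50 <- sin(2 * pi * 50 * t)
  s200 <- sin(2 * pi * 200 * t)
  # the Q = 35 notch is narrow, so its transients decay over ~1 s; judge the
  # steady state in the middle of the signal
  mid <- 5000:7000
  expect_lt(sqrt(mean(notch_filter(s50, fs)[mid]^2)) /
              sqrt(mean(s50[mid]^2)), 0.01)
  expect_lt(abs(sqrt(mean(notch_filter(s200, fs)[mid]^2)) /
                  sqrt(mean(s200[mid]^2)) - 1), 0.02)
  expect_equal(notch_filter(numeric(1000), fs), numeric(1000))
  expect_error(notch_filter(s50, fs, f0 = 1500))
})

test_that("zero-padding matches the longest segment and preserves aligned bins", {
  out <- pad_to_reference(list(1:5, 1:5))
  expect_equal(out$n_fft, 5)
  expect_identical(out$segments, list(1:5, 1:5))

  out2 <- pad_to_reference(list(rnorm(100), rnorm(80)))
  expect_equal(lengths(out2$segments), c(100, 100))
  expect_equal(out2$segments[[2]][81:100], numeric(20))
  expect_error(pad_to_reference(list()))

  # doubling N by padding keeps the DFT values at the original bins
  fs <- 100
  x <- sin(2 * pi * 10 * (0:49) / fs)
  X1 <- fft(x)
  X2 <- fft(c(x, numeric(50)))
  expect_equal(X2[seq(1, 100, by = 2)], X1, tolerance = 1e-9)
})

test_that("Hann taper has the closed-form shape and energy", {
  n <- 256
  w <- apply_window(rep(1, n))
  expect_equal(w[1], 0)
  expect_equal(w[n], 0)
  expect_equal(w, 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))))
  expect_lt(abs(sum(w^2) - 3 * n / 8), 1)
})

test_that("power spectrum follows the DFT magnitude-squared definition", {
  fs <- 1000
  expect_equal(power_spectrum(numeric(100), fs)$p, numeric(51))

  # un-windowed sinusoid at an exact bin: P = (N A / 2)^2
  N <- 1000; A <- 3; m0 <- 80
  x <- A * sin(2 * pi * m0 * (0:(N - 1)) / N)
  sp <- power_spectrum(x, fs, c(0, fs / 2))
  expect_equal(sp$p[m0 + 1], (N * A / 2)^2, tolerance = 1e-6)

  # Parseval: reconstruct the two-sided energy from the one-sided spectrum
  set.seed(9)
  x <- rnorm(256)
  sp <- power_spectrum(x, fs, c(0, fs / 2))
  two_sided <- sp$p[1] + sp$p[length(sp$p)] + 2 * sum(sp$p[2:(length(sp$p) - 1)])
  expect_equal(two_sided, length(x) * sum(x^2), tolerance = 1e-8)
})

test_that("moving trend filter reproduces cubics and matches the naive oracle", {
  f <- seq_len(400) / 400
  y <- 2 + 3 * f - 5 * f^2 + 4 * f^3
  out <- mtf_filter(y, span = 40, p = 3, clip = FALSE)
  expect_lt(max(abs(out - y) / abs(y)), 1e-8)

  expect_equal(mtf_filter(rep(7, 300), 40, 3), rep(7, 300), tolerance = 1e-10)

  set.seed(10)
  yr <- runif(250)
  expect_lt(max(abs(mtf_filter(yr, 30, 3, clip = FALSE) -
                      naive_mtf(yr, 30, 3))), 1e-9)

  expect_error(mtf_filter(runif(100), span = 120, p = 3))
})

test_that("moving trend filter is linear and strongly low-pass", {
  set.seed(11)
  x <- runif(300); y <- runif(300)
  lhs <- mtf_filter(2 * x + 3 * y, 40, 3, clip = FALSE)
  rhs <- 2 * mtf_filter(x, 40, 3, clip = FALSE) +
    3 * mtf_filter(y, 40, 3, clip = FALSE)
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  wn <- rnorm(2000)
  expect_lt(var(mtf_filter(wn, 180, 3, clip = FALSE)) / var(wn), 0.2)
})

test_that("normalization yields unit peak or unit energy and rejects zeros", {
  sp <- new_spectrum(c(0, 1, 2), c(1, 4, 2), n_fft = 6, fs = 6)
  expect_equal(normalize_spectrum(sp, "max")$p, c(0.25, 1, 0.5))
  expect_equal(normalize_spectrum(sp, "energy")$p, c(1, 4, 2) / 7)
  z <- new_spectrum(c(0, 1, 2), c(0, 0, 0), n_fft = 6, fs = 6)
  expect_error(normalize_spectrum(z, "max"), "all-zero")
})

test_that("regridding interpolates linearly and re-applies normalization", {
  f <- seq(0, 100, by = 1)
  sp <- new_spectrum(f, 2 * f + 5, n_fft = 200, fs = 200)
  # identity on the source grid
  rg <- regrid_spectrum(sp, df = 1, band = c(0, 100))
  expect_equal(rg$p, sp$p, tolerance = 1e-12)
  # linear ramp is reproduced exactly at half-bin points
  rg2 <- regrid_spectrum(sp, df = 0.5, band = c(0, 100))
  expect_equal(rg2$p, 2 * rg2$f + 5, tolerance = 1e-12)

  # random spectrum against a pointwise piecewise-linear oracle
  set.seed(12)
  pv <- runif(101)
  sp3 <- new_spectrum(f, pv, n_fft = 200, fs = 200)
  target <- seq(0, 100, by = 2)
  rg3 <- regrid_spectrum(sp3, df = 2, band = c(0, 100))
  oracle <- sapply(target, function(ft) {
    i <- findInterval(ft, f)
    if (f[i] == ft) pv[i]
    else pv[i] + (pv[i + 1] - pv[i]) * (ft - f[i]) / (f[i + 1] - f[i])
  })
  expect_lt(max(abs(rg3$p - oracle)), 1e-12)

  expect_error(regrid_spectrum(sp, df = 1, band = c(0, 150)), "beyond")

  # normalization survives the regrid
  spn <- normalize_spectrum(sp, "energy")
  rgn <- regrid_spectrum(spn, df = 0.5, band = c(0, 100))
  expect_equal(sum(rgn$p), 1, tolerance = 1e-12)
})

test_that("synthetic segment spectra are dominated by low-frequency energy", {
  p <- small_params(n_repetitions = 3)
  res <- generate_recording(p, task = "SP", seed = 13)
  segs <- segment_recording(res$recording)
  cfg <- spectral_config()
  for (norm in c("max", "energy")) {
    sp <- segment_spectra(segs, p$fs, cfg, norm)
    for (muscle in names(sp)) {
      cents <- sapply(sp[[muscle]], spectral_centroid)
      expect_true(all(cents < 250))
      # container invariants hold on the common grid
      for (s in sp[[muscle]]) {
        expect_equal(s$f, seq(0, 500, by = 0.5))
        if (norm == "max") expect_equal(max(s$p), 1, tolerance = 1e-12)
        else expect_equal(sum(s$p), 1, tolerance = 1e-12)
      }
    }
  }
})
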