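test_that("reference trace is the elementwise channel sum", {
  mk <- function(x) structure(list(t = seq_len(nrow(x)) / 100, x = x,
                                   fs = 100, participant_id = 1, task = "SP",
                                   channel_muscles = colnames(x)),
                              class = "emg_recording")
  a <- rnorm(50)
  rec <- mk(cbind(BB = a, BR = -a))
  expect_equal(build_reference_trace(rec), rep(0, 50))
  rec2 <- mk(cbind(BB = a, BR = a))
  expect_equal(build_reference_trace(rec2), 2 * a)

  b <- rnorm(50)
  rec3 <- mk(cbind(BB = a, BR = b))
  loop <- sapply(seq_along(a), function(i) a[i] + b[i])
  expect_equal(build_reference_trace(rec3), loop)

  expect_error(build_reference_trace(mk(cbind(BB = a))))
})

test_that("peak detection enforces spacing with tall-wins and prominence", {
  cfg <- segmenter_config(min_prominence_uv = 500, min_peak_distance_s = 0.35,
                          neighbor_delta_uv = 250, rms_window_s = 0.05)
  fs <- 1000
  expect_identical(detect_peaks(rep(3, 1000), fs, cfg), integer(0))
  expect_error(detect_peaks(numeric(1), fs, cfg))

  # two prominent impulse-like bumps 0.2 s apart: only the taller survives
  tr <- numeric(2000)
  tr[500 + -10:10] <- 900 * (1 - abs(-10:10) / 11)
  tr[700 + -10:10] <- 1200 * (1 - abs(-10:10) / 11)
  pk <- detect_peaks(tr, fs, segmenter_config(rms_window_s = 0.05))
  expect_identical(pk, 700L)
})

test_that("peak detection recovers the protocol repetition count", {
  p <- small_params(n_repetitions = 6)
  res <- generate_recording(p, task = "SP", seed = 2)
  trace <- build_reference_trace(res$recording)
  pk <- detect_peaks(trace, p$fs, segmenter_config())
  expect_length(pk, nrow(res$ground_truth$burst_intervals))
})

test_that("RMS envelope matches the per-sample loop oracle", {
  fs <- 200
  expect_equal(rms_envelope(rep(-4, 100), fs, 0.1), rep(4, 100))
  expect_equal(rms_envelope(numeric(100), fs, 0.1), numeric(100))
  set.seed(3)
  x <- rnorm(400)
  expect_lt(max(abs(rms_envelope(x, fs, 0.1) -
                      naive_rms_envelope(x, fs, 0.1))), 1e-9)
  expect_error(rms_envelope(x, fs, 0.001))
})

test_that("boundary refinement partitions the recording at envelope minima", {
  fs <- 1000
  set.seed(4)
  # two noise bursts with a silent gap
  burst <- function(n, amp) amp * rnorm(n)
  tr <- c(burst(800, 300), numeric(600), burst(800, 300))
  cfg <- segmenter_config(rms_window_s = 0.1)
  env <- rms_envelope(tr, fs, 0.1)
  pk <- c(which.max(abs(tr[1:800])), 1400 + which.max(abs(tr[1401:2200])))
  win <- refine_boundaries(tr, fs, pk, cfg)
  expect_equal(nrow(win), 2)
  # partition property
  expect_equal(win$start[1], 1)
  expect_equal(win$end[2], length(tr))
  expect_equal(win$start[2], win$end[1] + 1)
  # boundary falls inside the silent gap, where the envelope is tiny
  b <- win$end[1]
  expect_gt(b, 800)
  expect_lt(b, 1401)
  expect_lt(env[b], 0.1 * max(env))

  # single peak spans the whole recording
  win1 <- refine_boundaries(tr, fs, pk[1], cfg)
  expect_equal(unlist(win1), c(start = 1, end = length(tr)))
  expect_error(refine_boundaries(tr, fs, integer(0), cfg))
})

test_that("segmentation recovers ground-truth bursts with identical channel cuts", {
  p <- small_params(n_repetitions = 5)
  res <- generate_recording(p, task = "NT", seed = 6)
  segs <- segment_recording(res$recording, segmenter_config(expected_count = 5))
  expect_length(segs, 5)

  # partition of all samples, in order
  starts <- sapply(segs, `[[`, "start")
  ends <- sapply(segs, `[[`, "end")
  expect_equal(starts[1], 1)
  expect_equal(ends[5], nrow(res$recording$x))
  expect_equal(starts[-1], ends[-5] + 1)

  # each segment overlaps exactly one ground-truth burst with Jaccard > 0.5
  gt <- res$ground_truth$burst_intervals
  fs <- p$fs
  for (k in seq_along(segs)) {
    jac <- sapply(seq_len(nrow(gt)), function(j) {
      a <- c(segs[[k]]$start, segs[[k]]$end) / fs
      b <- c(gt$start_s[j], gt$end_s[j])
      inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
      inter / (diff(a) + diff(b) - inter)
    })
    expect_equal(sum(jac > 0.5), 1)
    expect_equal(which.max(jac), k)
  }

  # a flat recording yields an empty list with a warning
  flat <- res$recording
  flat$x <- matrix(0, 2000, 2, dimnames = list(NULL, c("BB", "BR")))
  flat$t <- seq_len(2000) / fs
  expect_warning(out <- segment_recording(flat), "no contractions")
  expect_length(out, 0)

  # count mismatch warns
  expect_warning(segment_recording(res$recording,
                                   segmenter_config(expected_count = 7)),
                 "expected 7")
})

test_that("segmentation is invariant to a small constant offset", {
  p <- small_params(n_repetitions = 4)
  res <- generate_recording(p, task = "SP", seed = 8)
  rec <- res$recording
  segs0 <- segment_recording(rec)
  rec_off <- rec
  rec_off$x <- rec$x + 25           # well below min_prominence / 10 per channel
  segs1 <- segment_recording(rec_off)
  expect_equal(length(segs0), length(segs1))
  # boundaries may drift within a rest interval but never across one
  drift <- abs(sapply(segs0, `[[`, "start") - sapply(segs1, `[[`, "start"))
  expect_lt(max(drift), p$rest_duration_s * p$fs)
})
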