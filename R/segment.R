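#' Segmentation configuration
#'
#' Parameters of the deterministic contraction-isolation procedure: candidate
#' peaks on the summed-channel trace must have a topographic prominence of at
#' least `min_prominence_uv`, be separated by at least `min_peak_distance_s`,
#' and exceed the RMS-envelope minima towards both neighbouring peaks by at
#' least `neighbor_delta_uv`; repetition boundaries are then placed at the
#' envelope minima between consecutive retained peaks.
#'
#' @param min_prominence_uv minimum topographic peak prominence (uV).
#' @param min_peak_distance_s minimum inter-peak distance (seconds).
#' @param neighbor_delta_uv minimum difference (uV) between a peak's RMS
#'   envelope value and the envelope minima towards both adjacent peaks.
#' @param rms_window_s RMS-envelope window length (seconds). The default of
#'   0.5 s is long relative to the correlation time of band-limited EMG noise
#'   (so plateau envelope fluctuations do not mimic inter-contraction gaps)
#'   yet short relative to the rest intervals that define the boundaries.
#' @param expected_count optional expected number of contractions; a mismatch
#'   triggers a warning in [segment_recording()].
#' @return Object of class `segmenter_config`.
#' @export
segmenter_config <- function(min_prominence_uv = 500,
                             min_peak_distance_s = 0.35,
                             neighbor_delta_uv = 250,
                             rms_window_s = 0.5,
                             expected_count = NULL) {
  stopifnot(min_prominence_uv > 0, min_peak_distance_s > 0,
            neighbor_delta_uv > 0, rms_window_s > 0)
  structure(list(min_prominence_uv = min_prominence_uv,
                 min_peak_distance_s = min_peak_distance_s,
                 neighbor_delta_uv = neighbor_delta_uv,
                 rms_window_s = rms_window_s,
                 expected_count = expected_count),
            class = "segmenter_config")
}

#' Summed-channel reference trace
#'
#' Elementwise sum of the two EMG channels; approximate phase synchrony of
#' simultaneous contractions enhances the amplitude contrast.
#'
#' @param rec an `emg_recording` with exactly two channels.
#' @return Numeric vector, same length as the recording.
#' @export
build_reference_trace <- function(rec) {
  if (ncol(rec$x) != 2) stop("recording must have exactly 2 channels")
  rec$x[, 1] + rec$x[, 2]
}

# Topographic prominence of peak index i on trace x: walk out to the nearest
# strictly higher sample on each side; the base is the higher of the two
# interval minima.
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- if (i > 1) x[seq_len(i - 1)] else numeric(0)
  hi_l <- which(left > h)
  min_l <- if (length(left)) min(left[seq(if (length(hi_l)) max(hi_l) else 1,
                                          length(left))]) else h
  right <- if (i < length(x)) x[(i + 1):length(x)] else numeric(0)
  hi_r <- which(right > h)
  min_r <- if (length(right)) min(right[seq_len(if (length(hi_r)) min(hi_r)
                                               else length(right))]) else h
  h - max(min_l, min_r)
}

#' Detect contraction peaks on a reference trace
#'
#' Local maxima are filtered by three constraints: a minimum inter-peak
#' distance (when candidates conflict on spacing the higher peak wins), a
#' minimum topographic prominence, and a minimum difference between each
#' peak's RMS-envelope value and the envelope minima towards both adjacent
#' retained peaks (recording ends count as neighbours for the outermost
#' peaks). The last rule is applied iteratively, discarding the lowest
#' failing peak and re-evaluating, so that minor oscillations within one
#' contraction collapse onto its dominant peak.
#'
#' @param trace numeric reference trace (uV).
#' @param fs sampling rate in Hz.
#' @param cfg a [segmenter_config()].
#' @return Sorted integer vector of peak sample indices (possibly empty).
#' @export
detect_peaks <- function(trace, fs, cfg = segmenter_config()) {
  if (length(trace) < 2) stop("trace must have at least 2 samples")
  min_dist <- max(1L, round(cfg$min_peak_distance_s * fs))
  d <- diff(trace)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L   # local maxima
  if (!length(cand)) return(integer(0))

  # spacing: greedy acceptance in descending height order; an accepted peak
  # blocks its neighbourhood, so lower peaks within min_dist are discarded
  cand <- cand[order(trace[cand], decreasing = TRUE)]
  blocked <- logical(length(trace))
  accepted <- integer(0)
  for (i in cand) {
    if (blocked[i]) next
    accepted <- c(accepted, i)
    blocked[max(1L, i - min_dist + 1L):min(length(trace), i + min_dist - 1L)] <- TRUE
  }
  accepted <- sort(accepted)

  # prominence on the raw trace
  prom <- vapply(accepted, function(i) peak_prominence(trace, i), numeric(1))
  peaks <- accepted[prom >= cfg$min_prominence_uv]
  if (!length(peaks)) return(integer(0))

  # neighbour rule on the RMS envelope, dropping the lowest offender first;
  # inter-peak envelope minima are maintained incrementally (removing a peak
  # merges its two flanking intervals)
  env <- rms_envelope(trace, fs, cfg$rms_window_s)
  bounds <- c(1L, peaks, length(trace))
  mins <- vapply(seq_len(length(peaks) + 1), function(k)
    env_min_between(env, bounds[k], bounds[k + 1]), numeric(1))
  repeat {
    if (!length(peaks)) break
    pe <- env[peaks]
    ok <- pe - mins[-length(mins)] >= cfg$neighbor_delta_uv &
      pe - mins[-1] >= cfg$neighbor_delta_uv
    if (all(ok)) break
    bad <- which(!ok)
    j <- bad[which.min(pe[bad])]
    mins[j] <- min(mins[j], mins[j + 1], env[peaks[j]])
    mins <- mins[-(j + 1)]
    peaks <- peaks[-j]
  }
  peaks
}

# Minimum of env strictly between indices a and b (falls back to the
# endpoint values when the open interval is empty).
env_min_between <- function(env, a, b) {
  if (b - a > 1) min(env[(a + 1):(b - 1)]) else min(env[c(a, b)])
}

#' Centered moving RMS envelope
#'
#' Root of the moving mean of squared samples over a centered window of
#' half-width `round(window_s * fs / 2)` samples, shrunk at the trace
#' boundaries.
#'
#' @param trace numeric vector (uV).
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (`window_s * fs >= 1`).
#' @return Nonnegative numeric vector, same length as `trace`.
#' @export
rms_envelope <- function(trace, fs, window_s) {
  if (window_s * fs < 1) stop("window shorter than one sample")
  n <- length(trace)
  h <- max(1L, round(window_s * fs / 2))
  cs <- c(0, cumsum(trace^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

#' Refine segment boundaries between detected peaks
#'
#' For each pair of consecutive peaks the boundary is the first index of the
#' minimum of the RMS envelope strictly between them — the phase of minimal
#' muscular activity. The first segment starts at the beginning of the
#' recording and the last one ends at its end, so the returned windows
#' partition the whole recording into `length(peaks)` contiguous segments.
#'
#' @param trace numeric reference trace.
#' @param fs sampling rate in Hz.
#' @param peaks sorted peak indices (at least one).
#' @param cfg a [segmenter_config()] (supplies the envelope window).
#' @return Data frame with columns `start`, `end` (1-based, inclusive).
#' @export
refine_boundaries <- function(trace, fs, peaks, cfg = segmenter_config()) {
  if (!length(peaks)) stop("at least one peak is required")
  n <- length(trace)
  env <- rms_envelope(trace, fs, cfg$rms_window_s)
  cuts <- integer(0)
  if (length(peaks) > 1) {
    cuts <- vapply(seq_len(length(peaks) - 1), function(k) {
      idx <- (peaks[k] + 1):(peaks[k + 1] - 1)
      idx[which.min(env[idx])]                 # first index on ties
    }, integer(1))
  }
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, n)
  data.frame(start = starts, end = ends)
}

#' Segment a two-channel recording into contractions
#'
#' Composes [build_reference_trace()], [detect_peaks()] and
#' [refine_boundaries()]; both channels are cut with the identical boundaries
#' derived from the summed trace. If `cfg$expected_count` is set and the
#' number of detected segments differs, a warning is emitted.
#'
#' @param rec an `emg_recording`.
#' @param cfg a [segmenter_config()].
#' @return List of segments, each a list with `participant_id`, `task`,
#'   `repetition`, `start`, `end` (1-based inclusive sample indices) and `x`
#'   (samples x channels matrix, uV). Empty list when no peak qualifies.
#' @export
segment_recording <- function(rec, cfg = segmenter_config()) {
  trace <- build_reference_trace(rec)
  peaks <- detect_peaks(trace, rec$fs, cfg)
  if (!length(peaks)) {
    warning("no contractions detected in recording")
    return(list())
  }
  win <- refine_boundaries(trace, rec$fs, peaks, cfg)
  if (!is.null(cfg$expected_count) && nrow(win) != cfg$expected_count)
    warning(sprintf("detected %d segments, expected %d (participant %s, task %s)",
                    nrow(win), cfg$expected_count,
                    as.character(rec$participant_id), rec$task))
  lapply(seq_len(nrow(win)), function(k) {
    list(participant_id = rec$participant_id, task = rec$task,
         repetition = k, start = win$start[k], end = win$end[k],
         x = rec$x[win$start[k]:win$end[k], , drop = FALSE])
  })
}
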