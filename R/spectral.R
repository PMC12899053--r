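#' Spectral-analysis configuration
#'
#' @param notch_freq_hz line-interference notch frequency (Hz).
#' @param notch_q notch quality factor (bandwidth is `notch_freq_hz / notch_q`).
#' @param mtf_order polynomial order of the moving trend filter.
#' @param mtf_span_bins sweep span of the moving trend filter in frequency
#'   bins (see [mtf_filter()]).
#' @param analysis_band_hz two-element vector, the analyzed frequency range.
#' @param common_grid_df_hz bin width of the common frequency grid that all
#'   spectra are interpolated onto before distances are computed.
#' @return Object of class `spectral_config`.
#' @export
spectral_config <- function(notch_freq_hz = 50,
                            notch_q = 35,
                            mtf_order = 3,
                            mtf_span_bins = 180,
                            analysis_band_hz = c(0, 500),
                            common_grid_df_hz = 0.5) {
  stopifnot(notch_freq_hz > 0, notch_q > 0, mtf_order >= 1,
            mtf_span_bins >= 2 * mtf_order + 2,
            length(analysis_band_hz) == 2,
            analysis_band_hz[1] < analysis_band_hz[2],
            common_grid_df_hz > 0)
  structure(list(notch_freq_hz = notch_freq_hz, notch_q = notch_q,
                 mtf_order = mtf_order, mtf_span_bins = mtf_span_bins,
                 analysis_band_hz = analysis_band_hz,
                 common_grid_df_hz = common_grid_df_hz),
            class = "spectral_config")
}

#' Power spectrum container
#'
#' @param f strictly increasing, uniformly spaced frequency grid (Hz).
#' @param p nonnegative power values, same length as `f`.
#' @param n_fft transform length the spectrum was computed with.
#' @param fs sampling rate of the originating signal (Hz).
#' @param normalization `"none"`, `"max"` (peak equals 1) or `"energy"`
#'   (values sum to 1).
#' @param smoothing `"raw"` or `"mtf"`.
#' @return Object of class `emg_spectrum`.
#' @export
new_spectrum <- function(f, p, n_fft, fs,
                         normalization = "none", smoothing = "raw") {
  s <- structure(list(f = f, p = p, n_fft = n_fft, fs = fs,
                      normalization = normalization, smoothing = smoothing),
                 class = "emg_spectrum")
  validate_spectrum(s)
  s
}

validate_spectrum <- function(s) {
  stopifnot(length(s$f) == length(s$p), length(s$f) >= 2)
  df <- diff(s$f)
  if (any(df <= 0)) stop("frequency grid must be strictly increasing")
  if (max(df) - min(df) > 1e-9 * max(df))
    stop("frequency grid must be uniformly spaced")
  if (any(s$p < 0)) stop("power values must be nonnegative")
  if (s$normalization == "max" && abs(max(s$p) - 1) > 1e-12)
    stop("max-normalized spectrum must peak at 1")
  if (s$normalization == "energy" && abs(sum(s$p) - 1) > 1e-12)
    stop("energy-normalized spectrum must sum to 1")
  invisible(s)
}

#' @export
print.emg_spectrum <- function(x, ...) {
  cat(sprintf("<emg_spectrum> %d bins, %.3g-%.4g Hz (df = %.4g), N = %d, normalization = %s, smoothing = %s\n",
              length(x$f), min(x$f), max(x$f), x$f[2] - x$f[1],
              x$n_fft, x$normalization, x$smoothing))
  invisible(x)
}

#' Zero-phase IIR notch filter
#'
#' Second-order notch (bandwidth `f0 / Q`) applied forward and backward via
#' [signal::filtfilt()], so the filter has zero phase and doubled stop-band
#' attenuation.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param f0 notch frequency in Hz (`0 < f0 < fs / 2`).
#' @param Q quality factor.
#' @return Filtered signal, same length as `x`.
#' @export
notch_filter <- function(x, fs, f0 = 50, Q = 35) {
  if (!(f0 > 0 && f0 < fs / 2)) stop("notch frequency must lie in (0, fs/2)")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::filtfilt(b / a[1], a / a[1], x)
}

#' Zero-pad segments to a common reference length
#'
#' The longest segment within a recording defines the reference length;
#' shorter segments receive trailing zeros. Padding increases frequency
#' resolution without altering the original samples, and yields an identical
#' frequency grid across repetitions.
#'
#' @param segments list of numeric vectors (one channel of each segment).
#' @return List with `segments` (all of equal length) and `n_fft`.
#' @export
pad_to_reference <- function(segments) {
  if (!length(segments)) stop("no segments to pad")
  n <- max(lengths(segments))
  list(segments = lapply(segments, function(x)
         if (length(x) == n) x else c(x, numeric(n - length(x)))),
       n_fft = n)
}

#' Apply a Hann taper
#'
#' Multiplies the segment by the symmetric length-`N` Hann window
#' (`0.5 * (1 - cos(2*pi*k/(N-1)))`), attenuating boundary discontinuities
#' and thus spectral leakage.
#'
#' @param x numeric vector of length at least 2.
#' @return Tapered vector; its endpoints are exactly zero.
#' @export
apply_window <- function(x) {
  n <- length(x)
  if (n < 2) stop("segment must have at least 2 samples")
  k <- 0:(n - 1)
  x * (0.5 * (1 - cos(2 * pi * k / (n - 1))))
}

#' One-sided FFT power spectrum
#'
#' `P[f_m] = |X[m]|^2` for `m = 0 .. floor(N/2)`, `f_m = m * fs / N`,
#' truncated to the analysis band. One guard bin above the upper band edge is
#' retained (when available) so the band edge itself stays interpolable when
#' spectra are later moved onto a common grid.
#'
#' @param x numeric segment (already padded/tapered as required).
#' @param fs sampling rate in Hz.
#' @param band two-element analysis band in Hz.
#' @return An `emg_spectrum` (raw, unnormalized).
#' @export
power_spectrum <- function(x, fs, band = c(0, 500)) {
  n <- length(x)
  if (n < 2) stop("segment must have at least 2 samples")
  X <- stats::fft(x)
  m <- 0:floor(n / 2)
  f <- m * fs / n
  pw <- Mod(X[m + 1])^2
  keep <- f >= band[1] & m <= ceiling(band[2] * n / fs)
  new_spectrum(f[keep], pw[keep], n_fft = n, fs = fs)
}

#' Smooth a power spectrum with the moving trend filter
#'
#' @param spec an `emg_spectrum`.
#' @param cfg a [spectral_config()] supplying the span and polynomial order.
#' @return The smoothed `emg_spectrum` (`smoothing = "mtf"`).
#' @export
mtf_smooth <- function(spec, cfg = spectral_config()) {
  if (length(spec$p) <= cfg$mtf_span_bins)
    stop("spectrum not longer than the smoothing span")
  new_spectrum(spec$f, mtf_filter(spec$p, cfg$mtf_span_bins, cfg$mtf_order),
               n_fft = spec$n_fft, fs = spec$fs,
               normalization = spec$normalization, smoothing = "mtf")
}

#' Normalize a power spectrum
#'
#' `"max"` scales the spectrum by its peak value within the analysis band so
#' the dominant component equals one; `"energy"` scales it so the discrete
#' energy (bin sum) equals one, a probability-like representation.
#'
#' @param spec an `emg_spectrum` with at least one positive value.
#' @param mode `"max"` or `"energy"`.
#' @return Normalized `emg_spectrum`.
#' @export
normalize_spectrum <- function(spec, mode = c("max", "energy")) {
  mode <- match.arg(mode)
  denom <- if (mode == "max") max(spec$p) else sum(spec$p)
  if (denom <= 0) stop("cannot normalize an all-zero spectrum")
  new_spectrum(spec$f, spec$p / denom, n_fft = spec$n_fft, fs = spec$fs,
               normalization = mode, smoothing = spec$smoothing)
}

#' Interpolate a spectrum onto a uniform common grid
#'
#' Linear interpolation of the power values onto `seq(band[1], band[2], df)`,
#' after which the spectrum's normalization mode is re-applied so its
#' invariants hold on the new grid. Different recordings generally have
#' different FFT lengths and hence incompatible native grids; the common grid
#' makes bin-wise spectral comparison possible.
#'
#' @param spec an `emg_spectrum`.
#' @param df target bin width in Hz.
#' @param band two-element target band in Hz; must lie within the source grid.
#' @return An `emg_spectrum` on the common grid.
#' @export
regrid_spectrum <- function(spec, df = 0.5, band = c(0, 500)) {
  target <- seq(band[1], band[2], by = df)
  if (min(target) < min(spec$f) || max(target) > max(spec$f))
    stop("target grid extends beyond the source grid")
  pw <- stats::approx(spec$f, spec$p, xout = target)$y
  out <- new_spectrum(target, pw, n_fft = spec$n_fft, fs = spec$fs,
                      normalization = "none", smoothing = spec$smoothing)
  if (spec$normalization != "none")
    out <- normalize_spectrum(out, spec$normalization)
  out
}

#' Spectral centroid
#'
#' Power-weighted mean frequency, `sum(f * p) / sum(p)`.
#'
#' @param spec an `emg_spectrum`.
#' @return Centroid frequency in Hz.
#' @export
spectral_centroid <- function(spec) {
  sum(spec$f * spec$p) / sum(spec$p)
}

#' Per-repetition normalized spectra of one segmented recording
#'
#' Runs the fixed processing chain for every segment and channel: 50 Hz
#' notch, zero-padding to the recording's longest segment, Hann taper, FFT
#' power spectrum on the analysis band, moving-trend-filter smoothing,
#' normalization of the smoothed spectrum, and interpolation onto the common
#' frequency grid.
#'
#' @param segments output of [segment_recording()] (non-empty).
#' @param fs sampling rate in Hz.
#' @param cfg a [spectral_config()].
#' @param normalization `"max"` or `"energy"`.
#' @return Nested list `spectra[[muscle]][[repetition]]`, each an
#'   `emg_spectrum` on the common grid.
#' @export
segment_spectra <- function(segments, fs, cfg = spectral_config(),
                            normalization = c("max", "energy")) {
  normalization <- match.arg(normalization)
  raw <- smoothed_spectra(segments, fs, cfg)
  lapply(raw, function(reps) lapply(reps, finalize_spectrum,
                                    cfg = cfg, normalization = normalization))
}

# Smoothed (but unnormalized, native-grid) spectra per muscle and repetition;
# shared by both normalization modes.
smoothed_spectra <- function(segments, fs, cfg) {
  if (!length(segments)) stop("no segments supplied")
  muscles <- colnames(segments[[1]]$x)
  out <- lapply(muscles, function(m) {
    filtered <- lapply(segments, function(s)
      notch_filter(s$x[, m], fs, cfg$notch_freq_hz, cfg$notch_q))
    padded <- pad_to_reference(filtered)
    lapply(padded$segments, function(x) {
      sp <- power_spectrum(apply_window(x), fs, cfg$analysis_band_hz)
      mtf_smooth(sp, cfg)
    })
  })
  names(out) <- muscles
  out
}

finalize_spectrum <- function(sp, cfg, normalization) {
  regrid_spectrum(normalize_spectrum(sp, normalization),
                  cfg$common_grid_df_hz, cfg$analysis_band_hz)
}
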