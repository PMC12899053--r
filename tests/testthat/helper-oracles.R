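# Small cohort parameters used throughout the unit tests: same statistical
# structure as the defaults, shorter bursts/rests so tests stay fast.
small_params <- function(n_participants = 2, burst_duration_s = 1.5,
                         rest_duration_s = 0.6, ...) {
  cohort_params(n_participants = n_participants,
                burst_duration_s = burst_duration_s,
                rest_duration_s = rest_duration_s, ...)
}

# Naive per-bin double-loop implementation of the moving trend filter:
# for every window position covering bin i, fit an order-p polynomial by
# least squares on u in [-1, 1] and evaluate it at i; average.
naive_mtf <- function(y, span, p) {
  n <- length(y)
  K <- floor(span / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    vals <- c()
    for (s in (i - K + 1):i) {
      a <- max(1, s); b <- min(n, s + K - 1); len <- b - a + 1
      if (len < p + 2) next
      u <- seq(-1, 1, length.out = len)
      fitv <- lm.fit(outer(u, 0:p, `^`), y[a:b])$fitted.values
      vals <- c(vals, fitv[i - a + 1])
    }
    out[i] <- mean(vals)
  }
  out
}

# Per-sample loop oracle for the centered moving RMS with shrinking windows.
naive_rms_envelope <- function(x, fs, window_s) {
  n <- length(x)
  h <- max(1, round(window_s * fs / 2))
  sapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    sqrt(mean(x[idx]^2))
  })
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
# (assumes no zero differences and no tied absolute differences).
enumerate_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Relative bandwidth-weighted spectral centroid of the shape model on a band,
# by dense numeric integration.
shape_centroid <- function(f_l, f_h, band = c(1, 500)) {
  f <- seq(band[1], band[2], by = 0.01)
  g <- shape_psd(f, f_l, f_h)
  sum(f * g) / sum(g)
}
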