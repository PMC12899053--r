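#' Subject-specific reference spectrum
#'
#' Bin-wise arithmetic mean of a participant's repetition spectra for one
#' muscle/posture condition — the compact descriptor of that participant's
#' characteristic spectral pattern.
#'
#' @param spectra list of `emg_spectrum` objects on an identical grid with
#'   identical normalization.
#' @return An `emg_spectrum` with attribute `n_reps`.
#' @export
reference_spectrum <- function(spectra) {
  if (!length(spectra)) stop("no spectra supplied")
  f <- spectra[[1]]$f
  norm <- spectra[[1]]$normalization
  for (s in spectra) {
    if (length(s$f) != length(f) || max(abs(s$f - f)) > 1e-9)
      stop("spectra must share an identical frequency grid")
    if (s$normalization != norm)
      stop("spectra must share the same normalization")
  }
  pw <- rowMeans(vapply(spectra, function(s) s$p, numeric(length(f))))
  ref <- structure(list(f = f, p = pw, n_fft = spectra[[1]]$n_fft,
                        fs = spectra[[1]]$fs, normalization = norm,
                        smoothing = spectra[[1]]$smoothing),
                   class = "emg_spectrum")
  attr(ref, "n_reps") <- length(spectra)
  ref
}

#' Minkowski distance between two spectra
#'
#' `D(x, y) = (sum |x_k - y_k|^l)^(1/l)`: order 1 is the Manhattan distance,
#' 2 the Euclidean distance, and `Inf` the Chebyshev distance (maximum
#' absolute difference).
#'
#' @param x,y numeric vectors of equal length, or `emg_spectrum` objects.
#' @param order 1, 2 or `Inf`.
#' @return Nonnegative scalar.
#' @export
minkowski_distance <- function(x, y, order = 2) {
  if (inherits(x, "emg_spectrum")) x <- x$p
  if (inherits(y, "emg_spectrum")) y <- y$p
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (!order %in% c(1, 2, Inf)) stop("order must be 1, 2 or Inf")
  d <- abs(x - y)
  switch(as.character(order),
         "1" = sum(d),
         "2" = sqrt(sum(d^2)),
         "Inf" = max(d))
}

#' Intra-subject repetition distances
#'
#' Distance of each repetition spectrum to the subject-specific reference
#' spectrum, one value per repetition.
#'
#' @param spectra list of repetition `emg_spectrum` objects.
#' @param reference the [reference_spectrum()] built from them.
#' @param order Minkowski order (1, 2 or `Inf`).
#' @return Data frame with columns `repetition`, `distance`.
#' @export
intra_distances <- function(spectra, reference, order = 2) {
  data.frame(
    repetition = seq_along(spectra),
    distance = vapply(spectra, minkowski_distance, numeric(1),
                      y = reference, order = order))
}

#' Inter-subject pairwise distances
#'
#' Minkowski distance between the reference spectra of every unordered pair
#' of participants under one condition; `n` participants yield
#' `n * (n - 1) / 2` rows.
#'
#' @param references named list of `emg_spectrum` reference spectra on a
#'   shared grid (names identify participants).
#' @param order Minkowski order (1, 2 or `Inf`).
#' @return Data frame with columns `s1`, `s2`, `distance`.
#' @export
inter_distances <- function(references, order = 2) {
  n <- length(references)
  if (n < 2) stop("at least two participants are required")
  ids <- names(references)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  pairs <- utils::combn(n, 2)
  data.frame(
    s1 = ids[pairs[1, ]],
    s2 = ids[pairs[2, ]],
    distance = apply(pairs, 2, function(pr)
      minkowski_distance(references[[pr[1]]], references[[pr[2]]], order)))
}

#' Descriptive statistics of a distance sample
#'
#' Mean, sample standard deviation (n - 1 divisor), coefficient of variation
#' (`sd / mean`, `NA` when the mean is zero), minimum and maximum — the
#' summary layout used for the variability tables.
#'
#' @param values numeric vector of at least two distances.
#' @return One-row data frame with columns `mean`, `std`, `cv`, `min`, `max`.
#' @export
summarize_distances <- function(values) {
  if (length(values) < 2) stop("at least two values are required")
  m <- mean(values)
  s <- stats::sd(values)
  data.frame(mean = m, std = s,
             cv = if (m > 0) s / m else if (s == 0) 0 else NA_real_,
             min = min(values), max = max(values))
}
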