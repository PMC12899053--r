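#' Parameters for a synthetic sEMG cohort
#'
#' Bundles every knob of the synthetic two-channel sEMG generator. The
#' defaults emulate the acquisition protocol the analysis assumes: repeated
#' near-maximal isometric elbow-flexion bursts of roughly 5 s, 10 repetitions
#' per task, sampled at 2 kHz, with rest-interval amplitudes below 5 uV,
#' two muscles (biceps brachii BB, brachioradialis BR) with distinct
#' band-limited spectral shapes, a small 50 Hz line component, repetition-level
#' spectral jitter (larger in the neutral-grip task NT than in the supinated
#' task SP) and participant-level random effects on spectral shape.
#'
#' @param n_participants number of participants in the cohort.
#' @param n_repetitions contractions per task recording.
#' @param fs sampling rate in Hz.
#' @param burst_duration_s nominal contraction duration in seconds.
#' @param rest_duration_s rest interval between contractions in seconds.
#' @param duration_jitter_frac relative jitter of individual burst durations
#'   (uniform on +/- this fraction); contractions only last *approximately*
#'   the nominal duration, which is what makes downstream zero-padding
#'   meaningful.
#' @param shape_means nested list `muscle -> posture -> c(f_l, f_h)` of
#'   low/high corner frequencies (Hz) of the spectral shape model.
#' @param subject_sd between-participant SD (Hz) of corner-frequency offsets.
#' @param rep_jitter_sd named vector `c(SP = , NT = )`: within-participant
#'   repetition SD (Hz) of the corner frequencies, one value per posture.
#' @param burst_rms_uv target plateau RMS of each contraction, per channel (uV).
#' @param baseline_amp_uv bound on the rest-interval amplitude (uV); the
#'   composite rest signal (noise + line interference) never exceeds it.
#' @param line_amp_uv amplitude of the 50 Hz line-interference sinusoid (uV).
#' @param seed integer seed controlling the whole cohort.
#'
#' @return An object of class `cohort_params` (a validated list).
#' @seealso [generate_cohort()], [generate_recording()], [shape_psd()]
#' @export
cohort_params <- function(n_participants = 33,
                          n_repetitions = 10,
                          fs = 2000,
                          burst_duration_s = 5,
                          rest_duration_s = 2,
                          duration_jitter_frac = 0.05,
                          shape_means = list(
                            BB = list(SP = c(f_l = 60, f_h = 120),
                                      NT = c(f_l = 65, f_h = 125)),
                            BR = list(SP = c(f_l = 70, f_h = 140),
                                      NT = c(f_l = 75, f_h = 145))),
                          subject_sd = 8,
                          rep_jitter_sd = c(SP = 5, NT = 10),
                          burst_rms_uv = 400,
                          baseline_amp_uv = 5,
                          line_amp_uv = 2,
                          seed = 1L) {
  p <- list(n_participants = as.integer(n_participants),
            n_repetitions = as.integer(n_repetitions),
            fs = fs,
            burst_duration_s = burst_duration_s,
            rest_duration_s = rest_duration_s,
            duration_jitter_frac = duration_jitter_frac,
            shape_means = shape_means,
            subject_sd = subject_sd,
            rep_jitter_sd = rep_jitter_sd,
            burst_rms_uv = burst_rms_uv,
            baseline_amp_uv = baseline_amp_uv,
            line_amp_uv = line_amp_uv,
            seed = as.integer(seed))
  validate_cohort_params(p)
  class(p) <- "cohort_params"
  p
}

validate_cohort_params <- function(p) {
  stopifnot(p$fs > 0, p$n_participants >= 1, p$n_repetitions >= 1,
            p$burst_duration_s > 0, p$rest_duration_s > 0,
            p$duration_jitter_frac >= 0, p$duration_jitter_frac < 1,
            p$subject_sd >= 0, p$baseline_amp_uv >= 0,
            p$burst_rms_uv >= 0, p$line_amp_uv >= 0)
  if (!all(c("SP", "NT") %in% names(p$rep_jitter_sd)))
    stop("rep_jitter_sd must be named with postures SP and NT")
  if (any(p$rep_jitter_sd < 0)) stop("rep_jitter_sd must be nonnegative")
  for (muscle in names(p$shape_means)) {
    for (posture in names(p$shape_means[[muscle]])) {
      fc <- p$shape_means[[muscle]][[posture]]
      if (!(fc[1] > 0 && fc[1] < fc[2] && fc[2] < p$fs / 2))
        stop("shape_means must satisfy 0 < f_l < f_h < fs/2 (",
             muscle, "/", posture, ")")
    }
  }
  invisible(p)
}

#' Band-limited sEMG spectral shape model
#'
#' Relative power spectral density of the rational band-pass form
#' `G(f) = f_h^2 f^2 / ((f^2 + f_l^2) (f^2 + f_h^2)^2)`, the standard
#' synthetic-sEMG spectrum model: zero at DC, a single broad peak between the
#' corner frequencies, and a gradual high-frequency decline.
#'
#' @param f frequencies in Hz (nonnegative, vectorized).
#' @param f_l,f_h low and high corner frequencies in Hz, `0 < f_l < f_h`.
#' @return Relative power density values, same length as `f`.
#' @export
shape_psd <- function(f, f_l, f_h) {
  if (!(is.numeric(f_l) && is.numeric(f_h) && f_l > 0 && f_h > f_l))
    stop("corner frequencies must satisfy 0 < f_l < f_h")
  if (any(f < 0)) stop("frequencies must be nonnegative")
  (f_h^2 * f^2) / ((f^2 + f_l^2) * (f^2 + f_h^2)^2)
}

# Evaluate code under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-recording substream so adding participants never
# perturbs existing recordings. Kept well below 2^31.
derive_seed <- function(base, participant, task_index) {
  (as.integer(base) %% 100000L) * 20011L + participant * 2L + task_index
}

#' Generate one synthetic contraction burst
#'
#' Colored zero-mean Gaussian noise whose periodogram expectation follows
#' [shape_psd()], shaped by a trapezoidal amplitude envelope and scaled so the
#' plateau RMS equals `target_rms_uv`. Coloring is done in the frequency
#' domain: the transform of white Gaussian noise is multiplied by
#' `sqrt(shape_psd)` and inverse-transformed.
#'
#' @param duration_s burst duration in seconds (at least 10 samples).
#' @param fs sampling rate in Hz.
#' @param f_l,f_h spectral corner frequencies in Hz.
#' @param target_rms_uv plateau RMS in uV; 0 yields an all-zero burst.
#' @param seed optional integer seed (identical seeds give identical bursts).
#' @param rise_frac,fall_frac envelope rise/fall fractions (plateau is the rest).
#' @return Numeric vector of samples in uV.
#' @export
generate_burst <- function(duration_s, fs, f_l, f_h, target_rms_uv,
                           seed = NULL, rise_frac = 0.1, fall_frac = 0.1) {
  n <- round(duration_s * fs)
  if (n < 10) stop("burst shorter than 10 samples")
  if (target_rms_uv == 0) return(numeric(n))
  with_seed(seed, {
    w <- stats::rnorm(n)
    f <- (seq_len(n) - 1) * fs / n
    f_fold <- pmin(f, fs - f)                       # two-sided frequency grid
    h <- sqrt(shape_psd(f_fold, f_l, f_h))
    x <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n
    n_rise <- max(1L, floor(rise_frac * n))
    n_fall <- max(1L, floor(fall_frac * n))
    env <- c(seq(0, 1, length.out = n_rise),
             rep(1, n - n_rise - n_fall),
             seq(1, 0, length.out = n_fall))
    x <- x * env
    plateau <- (n_rise + 1):(n - n_fall)
    rms <- sqrt(mean(x[plateau]^2))
    x * (target_rms_uv / rms)
  })
}

#' Generate one synthetic two-channel task recording
#'
#' Concatenates `n_repetitions` contraction bursts separated by rest intervals
#' of bounded uniform noise, then adds a common 50 Hz sinusoid to both
#' channels. The per-repetition spectral corners are the posture mean plus the
#' participant effect plus repetition jitter; realized values are recorded in
#' the ground truth together with the burst intervals. The rest-interval
#' noise amplitude is `baseline_amp_uv - line_amp_uv`, so the composite rest
#' signal respects the baseline amplitude bound.
#'
#' @param params a [cohort_params()] object.
#' @param participant_effects 2x2 numeric matrix of corner-frequency offsets
#'   (rows: muscles BB/BR, columns: `f_l`, `f_h`); defaults to zeros.
#' @param task `"SP"` or `"NT"`.
#' @param participant_id identifier stored in the recording.
#' @param seed optional integer seed.
#' @return A list with elements `recording` (class `emg_recording`: fields
#'   `t`, `x` (n x 2 matrix, uV), `fs`, `participant_id`, `task`,
#'   `channel_muscles`) and `ground_truth` (burst intervals in seconds and the
#'   realized corner frequencies per repetition and muscle).
#' @export
generate_recording <- function(params, participant_effects = NULL,
                               task = c("SP", "NT"), participant_id = 1L,
                               seed = NULL) {
  task <- match.arg(task)
  validate_cohort_params(params)
  muscles <- names(params$shape_means)
  if (is.null(participant_effects))
    participant_effects <- matrix(0, length(muscles), 2,
                                  dimnames = list(muscles, c("f_l", "f_h")))
  with_seed(seed, {
    fs <- params$fs
    n_rest <- round(params$rest_duration_s * fs)
    noise_amp <- max(params$baseline_amp_uv - params$line_amp_uv, 0)
    jit_sd <- params$rep_jitter_sd[[task]]
    djf <- params$duration_jitter_frac
    line_phase <- stats::runif(1, 0, 2 * pi)

    chunks <- vector("list", 2 * params$n_repetitions + 1)
    chunks[[1]] <- matrix(stats::runif(n_rest * length(muscles), -1, 1) * noise_amp,
                          ncol = length(muscles))
    intervals <- matrix(NA_real_, params$n_repetitions, 2)
    corners <- vector("list", params$n_repetitions)
    pos <- n_rest                                   # samples so far
    for (i in seq_len(params$n_repetitions)) {
      dur <- params$burst_duration_s *
        (1 + if (djf > 0) stats::runif(1, -djf, djf) else 0)
      n_burst <- round(dur * fs)
      burst <- matrix(0, n_burst, length(muscles))
      cc <- matrix(NA_real_, length(muscles), 2,
                   dimnames = list(muscles, c("f_l", "f_h")))
      for (m in seq_along(muscles)) {
        base <- params$shape_means[[muscles[m]]][[task]] +
          participant_effects[muscles[m], ] +
          stats::rnorm(2, 0, jit_sd)
        f_l <- max(base[1], 1)
        f_h <- max(base[2], f_l + 1)
        cc[m, ] <- c(f_l, f_h)
        burst[, m] <- generate_burst(n_burst / fs, fs, f_l, f_h,
                                     params$burst_rms_uv)
      }
      corners[[i]] <- cc
      intervals[i, ] <- c(pos, pos + n_burst) / fs
      chunks[[2 * i]] <- burst
      chunks[[2 * i + 1]] <-
        matrix(stats::runif(n_rest * length(muscles), -1, 1) * noise_amp,
               ncol = length(muscles))
      pos <- pos + n_burst + n_rest
    }
    x <- do.call(rbind, chunks)
    t <- (seq_len(nrow(x)) - 1) / fs
    x <- x + params$line_amp_uv * sin(2 * pi * 50 * t + line_phase)
    colnames(x) <- muscles
    rec <- structure(list(t = t, x = x, fs = fs,
                          participant_id = participant_id, task = task,
                          channel_muscles = muscles),
                     class = "emg_recording")
    gt <- list(
      burst_intervals = data.frame(start_s = intervals[, 1],
                                   end_s = intervals[, 2]),
      corners = do.call(rbind, lapply(seq_along(corners), function(i) {
        cc <- corners[[i]]
        data.frame(rep = i, muscle = rownames(cc),
                   f_l = cc[, 1], f_h = cc[, 2], row.names = NULL)
      })))
    list(recording = rec, ground_truth = gt)
  })
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> participant %s, task %s: %d samples x %d channels (%s) @ %g Hz, %.1f s\n",
              as.character(x$participant_id), x$task, nrow(x$x), ncol(x$x),
              paste(x$channel_muscles, collapse = ", "), x$fs,
              nrow(x$x) / x$fs))
  invisible(x)
}

#' Generate a synthetic sEMG cohort
#'
#' Produces one recording per participant and task (SP and NT). Participant
#' effects on the spectral corner frequencies are drawn once per participant
#' from `Normal(0, subject_sd)` (independently for each muscle and corner,
#' i.e. a multivariate subject effect) and reused across both tasks. Each
#' recording is generated from a derived substream, so the cohort is fully
#' reproducible from `params$seed` and adding participants does not perturb
#' existing recordings.
#'
#' @param params a [cohort_params()] object.
#' @return An object of class `emg_cohort`: list with `params`, `recordings`
#'   (named `P<id>_<task>`), `ground_truth` (parallel list) and
#'   `participant_effects`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  validate_cohort_params(params)
  muscles <- names(params$shape_means)
  effects <- with_seed(params$seed, {
    lapply(seq_len(params$n_participants), function(p)
      matrix(stats::rnorm(2 * length(muscles), 0, params$subject_sd),
             length(muscles), 2, dimnames = list(muscles, c("f_l", "f_h"))))
  })
  recordings <- list()
  ground_truth <- list()
  for (p in seq_len(params$n_participants)) {
    for (ti in 1:2) {
      task <- c("SP", "NT")[ti]
      res <- generate_recording(params, effects[[p]], task,
                                participant_id = p,
                                seed = derive_seed(params$seed, p, ti))
      key <- sprintf("P%02d_%s", p, task)
      recordings[[key]] <- res$recording
      ground_truth[[key]] <- res$ground_truth
    }
  }
  structure(list(params = params, recordings = recordings,
                 ground_truth = ground_truth,
                 participant_effects = effects),
            class = "emg_cohort")
}

#' @export
print.emg_cohort <- function(x, ...) {
  cat(sprintf("<emg_cohort> %d participants x 2 tasks = %d recordings (%d repetitions each, fs = %g Hz)\n",
              x$params$n_participants, length(x$recordings),
              x$params$n_repetitions, x$params$fs))
  invisible(x)
}

#' Rest intervals implied by ground-truth burst intervals
#'
#' Complement of the burst intervals within the recording duration.
#'
#' @param ground_truth one ground-truth entry from [generate_cohort()].
#' @param duration_s total recording duration in seconds.
#' @return Data frame with columns `start_s`, `end_s`.
#' @export
rest_intervals <- function(ground_truth, duration_s) {
  bi <- ground_truth$burst_intervals
  starts <- c(0, bi$end_s)
  ends <- c(bi$start_s, duration_s)
  keep <- ends > starts
  data.frame(start_s = starts[keep], end_s = ends[keep])
}
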