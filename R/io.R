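#' Write a recording as delimited text
#'
#' CSV with header `time_s,<muscle1>_uv,<muscle2>_uv`. Values are written
#' with 17 significant digits so a write/read cycle reproduces the samples
#' exactly.
#'
#' @param rec an `emg_recording`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_recording <- function(rec, path) {
  header <- paste(c("time_s", paste0(rec$channel_muscles, "_uv")),
                  collapse = ",")
  cols <- cbind(rec$t, rec$x)
  lines <- apply(cols, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Expects the dialect written by [write_recording()]: a `time_s` column and
#' one `<muscle>_uv` column per channel. Validates that exactly two channels
#' are present and that the time stamps are uniformly spaced (any stamp
#' deviating by more than 1e-6 s from the uniform grid is an error).
#'
#' @param path CSV file path.
#' @param participant_id,task metadata; defaults are parsed from a file name
#'   of the form `P<id>_<task>.csv` when possible.
#' @return An `emg_recording`.
#' @export
read_recording <- function(path, participant_id = NULL, task = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("malformed header: missing column 'time_s' in ", path)
  ch <- grep("_uv$", names(df), value = TRUE)
  if (length(ch) != 2)
    stop("expected exactly 2 channel columns ('*_uv'), found ",
         length(ch), " in ", path)
  t <- df$time_s
  if (length(t) < 2) stop("recording too short in ", path)
  dt <- (t[length(t)] - t[1]) / (length(t) - 1)
  grid <- t[1] + (seq_along(t) - 1) * dt
  if (max(abs(t - grid)) > 1e-6)
    stop("non-uniform sampling detected in ", path)
  base <- sub("\\.csv$", "", basename(path))
  m <- regmatches(base, regexec("^P([0-9]+)_([A-Za-z]+)$", base))[[1]]
  if (is.null(participant_id))
    participant_id <- if (length(m)) as.integer(m[2]) else base
  if (is.null(task)) task <- if (length(m)) m[3] else "SP"
  x <- as.matrix(df[ch])
  colnames(x) <- sub("_uv$", "", ch)
  structure(list(t = t, x = x, fs = 1 / dt,
                 participant_id = participant_id, task = task,
                 channel_muscles = colnames(x)),
            class = "emg_recording")
}

#' Write a synthetic cohort to a directory
#'
#' One CSV per participant x task (`P<id>_<task>.csv`) plus a ground-truth
#' JSON sidecar (`P<id>_<task>_truth.json`) with the burst intervals in
#' seconds and the realized corner frequencies.
#'
#' @param cohort an `emg_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$recordings)) {
    write_recording(cohort$recordings[[key]],
                    file.path(dir, paste0(key, ".csv")))
    jsonlite::write_json(cohort$ground_truth[[key]],
                         file.path(dir, paste0(key, "_truth.json")),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read all recordings in a directory
#'
#' @param dir directory containing `*.csv` recordings (ground-truth sidecars
#'   are ignored).
#' @return Named list of `emg_recording` objects.
#' @export
read_recordings <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no recordings found in ", dir)
  recs <- lapply(files, read_recording)
  names(recs) <- sub("\\.csv$", "", basename(files))
  recs
}
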