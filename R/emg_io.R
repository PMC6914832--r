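#' Multichannel EMG recordings
#'
#' An `emg_recording` bundles a raw multichannel surface-EMG signal
#' (samples x channels, arbitrary amplitude units; raw EMG is bipolar so
#' negative samples are expected), the sampling rate in Hz, and optional
#' posture-label spans. Label spans use 0-based sample indexing with an
#' inclusive start and exclusive end, must lie within the recording and
#' must not overlap.
#'
#' @param samples Numeric matrix, one row per sample, one column per
#'   channel.
#' @param fs Sampling rate in Hz (the acquisition hardware digitized at
#'   2000 Hz; any positive rate is accepted).
#' @param labels Optional `data.frame` with columns `start_sample`,
#'   `end_sample`, `posture_code` (see [all_postures()] for codes).
#' @return An object of class `emg_recording`.
#' @seealso [read_emg()], [rms_envelope()]
#' @export
emg_recording <- function(samples, fs, labels = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || anyNA(samples))
    stop("'samples' must be a numeric matrix without missing values", call. = FALSE)
  if (ncol(samples) < 1L || nrow(samples) < 1L)
    stop("'samples' needs at least one sample and one channel", call. = FALSE)
  stop_if_not_scalar_pos(fs, "fs")
  if (!is.null(labels)) labels <- validate_label_spans(labels, nrow(samples))
  structure(
    list(samples = samples, fs = fs, labels = labels),
    class = "emg_recording"
  )
}

validate_label_spans <- function(labels, n_samples) {
  labels <- as.data.frame(labels)
  need <- c("start_sample", "end_sample", "posture_code")
  if (!all(need %in% names(labels)))
    stop("labels need columns start_sample, end_sample, posture_code", call. = FALSE)
  labels$start_sample <- as.integer(labels$start_sample)
  labels$end_sample <- as.integer(labels$end_sample)
  labels$posture_code <- as.character(labels$posture_code)
  for (code in unique(labels$posture_code)) parse_posture(code)
  bad <- labels$start_sample < 0L | labels$end_sample > n_samples |
    labels$start_sample >= labels$end_sample
  if (any(bad))
    stop(sprintf(
      "label span [%d, %d) outside recording of %d samples (0-based, end-exclusive)",
      labels$start_sample[which(bad)[1L]], labels$end_sample[which(bad)[1L]],
      n_samples), call. = FALSE)
  o <- order(labels$start_sample)
  labels <- labels[o, , drop = FALSE]
  if (nrow(labels) > 1L &&
      any(labels$start_sample[-1L] < labels$end_sample[-nrow(labels)]))
    stop("label spans overlap", call. = FALSE)
  rownames(labels) <- NULL
  labels
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("emg_recording: %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  if (!is.null(x$labels))
    cat(sprintf("  %d label span(s): %s\n", nrow(x$labels),
                paste(unique(x$labels$posture_code), collapse = " ")))
  invisible(x)
}

#' Read a multichannel EMG recording from delimited text
#'
#' The signal file holds one row per sample and one column per channel
#' (comma- or tab-separated; an optional single header row is detected
#' automatically). The optional label file has columns
#' `start_sample,end_sample,posture_code` with 0-based, end-exclusive
#' sample spans.
#'
#' @param path Path to the delimited signal file.
#' @param fs Sampling rate in Hz.
#' @param label_path Optional path to a posture-label file.
#' @return An [emg_recording()].
#' @export
read_emg <- function(path, fs, label_path = NULL) {
  if (!file.exists(path)) stop(sprintf("EMG file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  nf <- utils::count.fields(path, sep = sep)
  if (length(unique(nf)) > 1L)
    stop(sprintf("ragged rows in '%s': %d to %d fields", path, min(nf), max(nf)),
         call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, header = "auto", sep = sep, fill = FALSE,
                      data.table = FALSE),
    error = function(e) stop(sprintf("failed to parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (nrow(dt) == 0L) stop(sprintf("EMG file '%s' is empty", path), call. = FALSE)
  if (!all(vapply(dt, is.numeric, logical(1L))))
    stop(sprintf("EMG file '%s' contains non-numeric cells", path), call. = FALSE)
  labels <- NULL
  if (!is.null(label_path)) {
    if (!file.exists(label_path))
      stop(sprintf("label file not found: %s", label_path), call. = FALSE)
    labels <- data.table::fread(label_path, header = "auto", data.table = FALSE)
  }
  emg_recording(as.matrix(dt), fs = fs, labels = labels)
}

#' Write an EMG recording (and labels) to delimited text
#'
#' @param rec An [emg_recording()].
#' @param path Output CSV path for the signal.
#' @param label_path Optional output CSV path for the label spans.
#' @return `rec`, invisibly.
#' @export
write_emg <- function(rec, path, label_path = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  utils::write.csv(as.data.frame(rec$samples), path, row.names = FALSE)
  if (!is.null(label_path)) {
    if (is.null(rec$labels)) stop("recording has no labels to write", call. = FALSE)
    utils::write.csv(rec$labels, label_path, row.names = FALSE)
  }
  invisible(rec)
}

#' Envelope container
#'
#' An `emg_envelope` is the non-negative sliding-window RMS feature
#' matrix consumed by all downstream analyses: `frames` (frames x
#' channels), the center time of each frame in seconds, the effective
#' frame rate, and an optional posture label per frame.
#'
#' @param frames Non-negative numeric matrix, frames x channels.
#' @param fs_frames Effective frame rate in Hz.
#' @param frame_times Optional frame center times (seconds).
#' @param frame_labels Optional character vector of posture codes (or
#'   `NA` for unlabeled frames), one per frame.
#' @return An object of class `emg_envelope`.
#' @export
emg_envelope <- function(frames, fs_frames = NA_real_, frame_times = NULL,
                         frame_labels = NULL) {
  frames <- as.matrix(frames)
  if (!is.numeric(frames) || anyNA(frames) || any(frames < 0))
    stop("envelope frames must be non-negative and complete", call. = FALSE)
  if (is.null(frame_times)) frame_times <- seq_len(nrow(frames)) - 1
  if (length(frame_times) != nrow(frames))
    stop("frame_times length must match the number of frames", call. = FALSE)
  if (!is.null(frame_labels) && length(frame_labels) != nrow(frames))
    stop("frame_labels length must match the number of frames", call. = FALSE)
  structure(
    list(frames = frames, frame_times = as.numeric(frame_times),
         fs_frames = fs_frames, frame_labels = frame_labels),
    class = "emg_envelope"
  )
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("emg_envelope: %d frames x %d channels", nrow(x$frames),
              ncol(x$frames)))
  if (is.finite(x$fs_frames)) cat(sprintf(" @ %.3f frames/s", x$fs_frames))
  cat("\n")
  if (!is.null(x$frame_labels)) {
    tab <- table(x$frame_labels, useNA = "ifany")
    cat("  frames per posture:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Sliding-window RMS envelope of an EMG recording
#'
#' Computes, per channel, the root mean square over a sliding window —
#' the standard non-negative amplitude proxy for muscle activation.
#' Defaults follow the acquisition pipeline the package models: a
#' 250 ms window advanced in 70 ms steps (at 2000 Hz: 500-sample
#' windows, 140-sample hop, matching a 15 Hz control link). Only
#' complete windows produce frames; a recording shorter than one window
#' is an error. Window and step widths are converted to samples by
#' `floor(ms * fs / 1000)`.
#'
#' When the recording carries posture-label spans, each frame is labeled
#' by the span containing its center sample; frames whose center falls
#' in no span are `NA`.
#'
#' @param rec An [emg_recording()].
#' @param window_ms RMS window width in milliseconds.
#' @param step_ms Hop between window starts in milliseconds. A step
#'   larger than the window is allowed and simply yields disjoint
#'   windows.
#' @return An [emg_envelope()] with
#'   `floor((n_samples - window_samples) / step_samples) + 1` frames.
#' @examples
#' rec <- emg_recording(matrix(sin(2 * pi * 50 * (0:9999) / 2000), ncol = 1),
#'                      fs = 2000)
#' env <- rms_envelope(rec)
#' head(env$frames)  # ~ 1/sqrt(2) for a unit sine
#' @export
rms_envelope <- function(rec, window_ms = 250, step_ms = 70) {
  stopifnot(inherits(rec, "emg_recording"))
  stop_if_not_scalar_pos(window_ms, "window_ms")
  stop_if_not_scalar_pos(step_ms, "step_ms")
  w <- floor(window_ms * rec$fs / 1000)
  s <- floor(step_ms * rec$fs / 1000)
  if (w < 1L || s < 1L)
    stop("window and step must span at least one sample at this sampling rate",
         call. = FALSE)
  n <- nrow(rec$samples)
  if (n < w)
    stop(sprintf("recording (%d samples) is shorter than one %d-sample window",
                 n, w), call. = FALSE)
  n_frames <- (n - w) %/% s + 1L
  starts <- (seq_len(n_frames) - 1L) * s + 1L  # 1-based window start rows
  # cumulative sums of squares give O(n) window means
  css <- apply(rec$samples^2, 2L, cumsum)
  css <- rbind(0, css)
  frames <- sqrt((css[starts + w, , drop = FALSE] -
                    css[starts, , drop = FALSE]) / w)
  frames[frames < 0] <- 0  # guard tiny negative round-off
  centers0 <- (starts - 1L) + (w %/% 2L)           # 0-based center sample
  frame_times <- centers0 / rec$fs
  frame_labels <- NULL
  if (!is.null(rec$labels)) {
    frame_labels <- rep(NA_character_, n_frames)
    for (i in seq_len(nrow(rec$labels))) {
      hit <- centers0 >= rec$labels$start_sample[i] &
        centers0 < rec$labels$end_sample[i]
      frame_labels[hit] <- rec$labels$posture_code[i]
    }
  }
  emg_envelope(frames, fs_frames = rec$fs / s, frame_times = frame_times,
               frame_labels = frame_labels)
}

#' Split a labeled envelope into per-posture envelopes
#'
#' @param env An [emg_envelope()] with frame labels.
#' @param drop_na Drop unlabeled frames (default TRUE).
#' @return Named list mapping posture code to an [emg_envelope()].
#' @export
split_envelope <- function(env, drop_na = TRUE) {
  stopifnot(inherits(env, "emg_envelope"))
  if (is.null(env$frame_labels))
    stop("envelope carries no frame labels", call. = FALSE)
  labs <- env$frame_labels
  keep_levels <- unique(labs[!is.na(labs)])
  out <- lapply(keep_levels, function(p) {
    idx <- which(!is.na(labs) & labs == p)
    emg_envelope(env$frames[idx, , drop = FALSE], fs_frames = env$fs_frames,
                 frame_times = env$frame_times[idx],
                 frame_labels = rep(p, length(idx)))
  })
  names(out) <- keep_levels
  if (!drop_na && anyNA(labs)) {
    idx <- which(is.na(labs))
    out[["<unlabeled>"]] <- emg_envelope(env$frames[idx, , drop = FALSE],
                                         fs_frames = env$fs_frames,
                                         frame_times = env$frame_times[idx])
  }
  out
}
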