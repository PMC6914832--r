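#' Build a synthetic synergy bank
#'
#' Defines the ground truth for synthetic 5-channel biceps recordings:
#' a shared non-negative synergy basis `W_true` (channels x rank_true)
#' and one non-negative activation vector per posture. The per-posture
#' channel envelope pattern is `W_true %*% h_true(posture)`, so the
#' generated envelopes carry exactly the low-rank, posture-specific
#' structure the extraction pipeline assumes. Activation vectors are
#' redrawn until all pairwise Euclidean distances reach `separation`
#' (0 disables the constraint; postures with identical activations can
#' be constructed by passing `separation = 0` and copying patterns).
#'
#' @param n_postures Number of postures (>= 2).
#' @param rank_true True synergy rank (<= n_channels).
#' @param separation Minimum pairwise activation distance. Activations
#'   are drawn uniformly from `[0, 1]^rank_true`, so feasible
#'   separations are well below `sqrt(rank_true)`.
#' @param noise_sigma Scale of the Gaussian envelope perturbation
#'   applied at generation time (clipped at zero), in the same units as
#'   the channel patterns.
#' @param seed RNG seed; the bank is fully reproducible.
#' @param n_channels Number of EMG channels (5 electrode pairs across
#'   the biceps by default).
#' @param postures Posture codes; defaults to [all_postures()] for 8,
#'   [five_posture_subset()] for 5, otherwise the first `n_postures`
#'   codes.
#' @return An object of class `synergy_bank` with `W_true`, `H_true`
#'   (rank x postures), `patterns` (channels x postures), and the
#'   generation parameters.
#' @export
make_synergy_bank <- function(n_postures = 8L, rank_true = 3L,
                              separation = 0.35, noise_sigma = 0,
                              seed = 1L, n_channels = 5L, postures = NULL) {
  if (n_postures < 2L) stop("need at least two postures", call. = FALSE)
  if (rank_true > n_channels)
    stop("rank_true cannot exceed the channel count", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  if (is.null(postures)) {
    postures <- if (n_postures == 5L) five_posture_subset()
      else all_postures()[seq_len(min(n_postures, 8L))]
    if (n_postures > 8L) stop("at most 8 distinct postures exist", call. = FALSE)
  }
  if (length(postures) != n_postures || anyDuplicated(postures))
    stop("'postures' must supply n_postures distinct codes", call. = FALSE)
  for (p in postures) parse_posture(p)
  with_seed(seed, {
    W_true <- matrix(stats::runif(n_channels * rank_true, 0.2, 1),
                     n_channels, rank_true)
    H_true <- matrix(stats::runif(rank_true * n_postures), rank_true,
                     n_postures)
    ok <- function(H) {
      if (separation == 0) return(TRUE)
      d <- stats::dist(t(H))
      min(d) >= separation
    }
    tries <- 0L
    while (!ok(H_true)) {
      tries <- tries + 1L
      if (tries > 5000L)
        stop(sprintf("could not achieve pairwise activation separation %.3g",
                     separation), call. = FALSE)
      H_true <- matrix(stats::runif(rank_true * n_postures), rank_true,
                       n_postures)
    }
    colnames(H_true) <- postures
    patterns <- W_true %*% H_true
    colnames(patterns) <- postures
    structure(
      list(n_postures = as.integer(n_postures), postures = postures,
           rank_true = as.integer(rank_true), n_channels = as.integer(n_channels),
           W_true = W_true, H_true = H_true, patterns = patterns,
           separation = separation, noise_sigma = noise_sigma,
           seed = seed),
      class = "synergy_bank"
    )
  })
}

#' @export
print.synergy_bank <- function(x, ...) {
  cat(sprintf("synergy_bank: %d postures, %d channels, true rank %d, noise sigma %g\n",
              x$n_postures, x$n_channels, x$rank_true, x$noise_sigma))
  invisible(x)
}

#' Generate a synthetic multichannel EMG recording
#'
#' Produces, for a scripted schedule of posture holds, a zero-mean
#' broadband carrier amplitude-modulated so that the sliding RMS
#' envelope of each channel equals the bank's per-posture pattern plus
#' a Gaussian envelope perturbation of scale `noise_sigma` (clipped at
#' zero). The carrier is white Gaussian noise renormalized to exact
#' unit RMS in short 10 ms blocks, so at `noise_sigma = 0` interior
#' envelope frames reproduce the commanded pattern to floating-point
#' precision; the envelope perturbation itself varies on a 250 ms
#' scale. Samples outside any span are zero.
#'
#' @param bank A [make_synergy_bank()].
#' @param schedule `data.frame` with columns `start_s`, `end_s`,
#'   `posture` — non-overlapping posture holds in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed RNG seed for the carrier and envelope noise.
#' @return An [emg_recording()] with label spans attached.
#' @export
generate_emg <- function(bank, schedule, fs = 2000, seed = 1L) {
  stopifnot(inherits(bank, "synergy_bank"))
  schedule <- as.data.frame(schedule)
  if (!all(c("start_s", "end_s", "posture") %in% names(schedule)))
    stop("schedule needs columns start_s, end_s, posture", call. = FALSE)
  if (any(schedule$end_s <= schedule$start_s))
    stop("schedule spans must have positive duration", call. = FALSE)
  o <- order(schedule$start_s)
  schedule <- schedule[o, , drop = FALSE]
  if (nrow(schedule) > 1L &&
      any(schedule$start_s[-1L] < schedule$end_s[-nrow(schedule)]))
    stop("schedule spans overlap", call. = FALSE)
  unknown <- setdiff(schedule$posture, bank$postures)
  if (length(unknown) > 0L)
    stop(sprintf("posture(s) not in the bank: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  n <- round(max(schedule$end_s) * fs)
  n_ch <- bank$n_channels
  block <- max(1L, round(0.010 * fs))       # carrier normalization block
  noise_block <- max(block, round(0.250 * fs))  # envelope-noise time scale
  with_seed(seed, {
    samples <- matrix(0, n, n_ch)
    labels <- data.frame(start_sample = integer(0), end_sample = integer(0),
                         posture_code = character(0))
    for (i in seq_len(nrow(schedule))) {
      s0 <- round(schedule$start_s[i] * fs)
      s1 <- round(schedule$end_s[i] * fs)
      len <- s1 - s0
      pat <- bank$patterns[, schedule$posture[i]]
      # per-channel amplitude target, piecewise constant per noise block
      n_nb <- ceiling(len / noise_block)
      for (ch in seq_len(n_ch)) {
        amp_nb <- pmax(0, pat[ch] + stats::rnorm(n_nb, 0, bank$noise_sigma))
        amp <- rep(amp_nb, each = noise_block)[seq_len(len)]
        carrier <- stats::rnorm(len)
        # exact unit RMS per short block so the envelope is controlled
        nfull <- len %/% block
        if (nfull > 0L) {
          head_len <- nfull * block
          m <- matrix(carrier[seq_len(head_len)], nrow = block)
          r <- sqrt(colMeans(m * m))
          r[r == 0] <- 1
          carrier[seq_len(head_len)] <- as.numeric(m / rep(r, each = block))
        }
        if (len > nfull * block) {  # trailing partial block
          j0 <- nfull * block + 1L
          seg <- carrier[j0:len]
          r <- sqrt(mean(seg^2))
          if (r > 0) carrier[j0:len] <- seg / r
        }
        samples[(s0 + 1L):s1, ch] <- amp * carrier
      }
      labels <- rbind(labels, data.frame(start_sample = s0, end_sample = s1,
                                         posture_code = schedule$posture[i]))
    }
    emg_recording(samples, fs = fs, labels = labels)
  })
}

#' Standard training / evaluation schedules
#'
#' `training_schedule()` mirrors the study's training protocol: one
#' consecutive `hold_s`-second hold per posture (10 s in the study).
#' `evaluation_schedule()` mirrors the evaluation protocol: `reps`
#' repetitions of `hold_s`-second holds per posture (3 x 5 s in the
#' study), interleaved by repetition block.
#'
#' @param postures Character vector of posture codes.
#' @param hold_s Hold duration per span in seconds.
#' @param reps Repetitions per posture (evaluation only).
#' @return `data.frame` with columns `start_s`, `end_s`, `posture`.
#' @export
training_schedule <- function(postures, hold_s = 10) {
  n <- length(postures)
  data.frame(start_s = (seq_len(n) - 1) * hold_s,
             end_s = seq_len(n) * hold_s,
             posture = postures)
}

#' @rdname training_schedule
#' @export
evaluation_schedule <- function(postures, hold_s = 5, reps = 3L) {
  n <- length(postures)
  spans <- expand.grid(posture = postures, rep = seq_len(reps),
                       stringsAsFactors = FALSE)
  idx <- seq_len(nrow(spans)) - 1
  data.frame(start_s = idx * hold_s, end_s = (idx + 1) * hold_s,
             posture = spans$posture)
}

#' Generate per-posture envelopes straight from a bank
#'
#' Convenience wrappers running [generate_emg()] + [rms_envelope()]
#' for the standard protocols. Each posture hold is generated as its
#' own capture (as when a subject holds a posture while the system
#' records), so no envelope window straddles two postures; a single
#' continuous multi-posture recording can instead be built with
#' [generate_emg()] + [split_envelope()], in which case frames whose
#' window overlaps a posture transition carry mixed amplitudes.
#'
#' @param bank A [make_synergy_bank()].
#' @param hold_s,reps Schedule parameters (see [training_schedule()]).
#' @param fs Sampling rate in Hz.
#' @param seed Base RNG seed; hold `i` uses `seed + i - 1`.
#' @param window_ms,step_ms RMS envelope parameters.
#' @return Named list posture -> [emg_envelope()].
#' @export
training_envelopes <- function(bank, hold_s = 10, fs = 2000, seed = 1L,
                               window_ms = 250, step_ms = 70) {
  out <- vector("list", bank$n_postures)
  names(out) <- bank$postures
  for (i in seq_along(bank$postures)) {
    p <- bank$postures[i]
    rec <- generate_emg(bank,
                        data.frame(start_s = 0, end_s = hold_s, posture = p),
                        fs, seed + i - 1L)
    out[[p]] <- rms_envelope(rec, window_ms, step_ms)
  }
  out
}

#' @rdname training_envelopes
#' @export
evaluation_envelopes <- function(bank, hold_s = 5, reps = 3L, fs = 2000,
                                 seed = 2L, window_ms = 250, step_ms = 70) {
  out <- vector("list", bank$n_postures)
  names(out) <- bank$postures
  k <- 0L
  for (r in seq_len(reps)) {
    for (i in seq_along(bank$postures)) {
      p <- bank$postures[i]
      rec <- generate_emg(bank,
                          data.frame(start_s = 0, end_s = hold_s, posture = p),
                          fs, seed + k)
      k <- k + 1L
      env <- rms_envelope(rec, window_ms, step_ms)
      out[[p]] <- if (is.null(out[[p]])) env else
        emg_envelope(rbind(out[[p]]$frames, env$frames),
                     fs_frames = env$fs_frames,
                     frame_labels = rep(p, nrow(out[[p]]$frames) +
                                          nrow(env$frames)))
    }
  }
  out
}
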