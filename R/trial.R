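#' Configuration of a target-reaching trial
#'
#' A trial places the sphere at the cube center and asks the posture
#' stream to steer it into a target's capture ball. The sphere is a
#' point; the target counts as touched the instant the point enters the
#' ball of radius `capture_radius` (0.1 cube units — half the displayed
#' target diameter of 0.2). Trials run for at most `time_limit_s`
#' (120 s in the study) with posture events consumed at the
#' `control_rate_hz` link rate (15 Hz) and the dynamics integrated with
#' `substeps` RK4 sub-steps per control tick (dt = 1/150 s by default).
#'
#' @param target Numeric 3-vector, the target center inside the cube.
#' @param capture_radius Capture ball radius in cube units.
#' @param time_limit_s Trial time limit in seconds.
#' @param control_rate_hz Control/posture-event rate in Hz.
#' @param substeps RK4 sub-steps per control tick.
#' @param axis_signs Corner sign convention, see [posture_to_corner()].
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(target, capture_radius = 0.1, time_limit_s = 120,
                         control_rate_hz = 15, substeps = 10L,
                         axis_signs = c(1, 1, 1)) {
  target <- as.numeric(target)
  if (length(target) != 3L || anyNA(target))
    stop("'target' must be a numeric 3-vector", call. = FALSE)
  stop_if_not_scalar_pos(capture_radius, "capture_radius")
  stop_if_not_scalar_pos(time_limit_s, "time_limit_s")
  stop_if_not_scalar_pos(control_rate_hz, "control_rate_hz")
  if (substeps < 1L) stop("'substeps' must be >= 1", call. = FALSE)
  structure(
    list(target = target, capture_radius = capture_radius,
         time_limit_s = time_limit_s, control_rate_hz = control_rate_hz,
         substeps = as.integer(substeps), axis_signs = axis_signs),
    class = "trial_config"
  )
}

#' Read a posture stream from delimited text
#'
#' Columns `time_s,posture_code`, one row per posture event.
#'
#' @param path File path.
#' @return A `data.frame` with columns `time_s` and `posture`.
#' @export
read_posture_stream <- function(path) {
  if (!file.exists(path)) stop(sprintf("stream file not found: %s", path), call. = FALSE)
  d <- data.table::fread(path, header = "auto", data.table = FALSE)
  names(d) <- c("time_s", "posture")[seq_len(ncol(d))]
  d$posture <- as.character(d$posture)
  d
}

#' Run one target-reaching trial of the intermittent controller
#'
#' Simulates a scripted posture stream: the sphere starts at the cube
#' center; at each control tick, pending posture events update the
#' commanded corner and the joint-activation mask
#' ([joint_activation()]), and the active axes are advanced by RK4
#' integration of the second-order dynamics. Events repeating the
#' current posture change no joint and are ignored (not counted as
#' posture changes). Performance follows the study's four measures:
#' time to capture, trajectory length (cumulative Euclidean distance
#' along the numerical solution), number of posture changes, and — for
#' failed trials — the final distance to the target.
#'
#' @param stream `data.frame` with columns `time_s` (non-decreasing,
#'   within the time limit) and `posture`; `NULL` or zero rows is a
#'   valid trial in which the sphere never moves.
#' @param cfg A [trial_config()].
#' @param params A [dynamics_params()].
#' @param return_trajectory Keep the sampled trajectory (time, x, y, z
#'   at sub-step resolution)?
#' @return An object of class `cube_trial` with `reached`, `time_s`,
#'   `n_posture_changes`, `trajectory_length`, `final_distance`,
#'   `final_position` and (optionally) `trajectory`.
#' @examples
#' cfg <- trial_config(target = 0.5 * posture_to_corner("FFS") / sqrt(3))
#' tr <- run_trial(data.frame(time_s = 0, posture = "FFS"), cfg)
#' tr
#' @export
run_trial <- function(stream, cfg, params = dynamics_params(),
                      return_trajectory = FALSE) {
  stopifnot(inherits(cfg, "trial_config"))
  if (is.null(stream)) stream <- data.frame(time_s = numeric(0),
                                            posture = character(0))
  stream <- as.data.frame(stream)
  if (nrow(stream) > 0L) {
    if (!all(c("time_s", "posture") %in% names(stream)))
      stop("stream needs columns time_s and posture", call. = FALSE)
    if (is.unsorted(stream$time_s))
      stop("stream timestamps must be non-decreasing", call. = FALSE)
    if (any(stream$time_s < 0 | stream$time_s > cfg$time_limit_s))
      stop("stream timestamps must lie within [0, time_limit_s]", call. = FALSE)
    for (p in unique(stream$posture)) parse_posture(p)
  }
  tick <- 1 / cfg$control_rate_hz
  dt <- tick / cfg$substeps
  n_ticks <- ceiling(cfg$time_limit_s / tick)
  pos <- c(0, 0, 0)
  vel <- c(0, 0, 0)
  ref <- c(0, 0, 0)
  active <- rep(FALSE, 3L)
  lock <- FALSE
  last_posture <- NULL
  n_changes <- 0L
  next_event <- 1L
  traj_len <- 0
  r2 <- cfg$capture_radius^2
  reached <- sum((pos - cfg$target)^2) <= r2
  t_now <- 0
  keep <- isTRUE(return_trajectory)
  if (keep) {
    traj <- matrix(NA_real_, n_ticks * cfg$substeps + 1L, 4L)
    colnames(traj) <- c("time_s", "x", "y", "z")
    traj[1L, ] <- c(0, pos)
    ti <- 1L
  }
  w <- params$omega_n
  d2w <- 2 * params$delta * params$omega_n
  w2 <- params$omega_n^2
  if (!reached) {
    for (k in seq_len(n_ticks)) {
      t_now <- (k - 1L) * tick  # exact tick arithmetic, no accumulation drift
      # consume posture events due at this tick (half-step tolerance)
      while (next_event <= nrow(stream) &&
             stream$time_s[next_event] <= t_now + 1e-9) {
        p <- stream$posture[next_event]
        next_event <- next_event + 1L
        if (!is.null(last_posture) && p == last_posture) next
        act <- joint_activation(last_posture, p, lock)
        lock <- act$shoulder_lock
        mask <- unname(act$mask)
        vel[active & !mask] <- 0  # hard hold on deactivation
        corner <- unname(posture_to_corner(p, cfg$axis_signs))
        ref[mask] <- corner[mask]
        active <- mask
        last_posture <- p
        n_changes <- n_changes + 1L
      }
      for (s in seq_len(cfg$substeps)) {
        if (any(active)) {
          x <- pos[active]; v <- vel[active]; r <- ref[active]
          k1x <- v;                 k1v <- w2 * (r - x) - d2w * v
          x2 <- x + dt / 2 * k1x;   v2 <- v + dt / 2 * k1v
          k2x <- v2;                k2v <- w2 * (r - x2) - d2w * v2
          x3 <- x + dt / 2 * k2x;   v3 <- v + dt / 2 * k2v
          k3x <- v3;                k3v <- w2 * (r - x3) - d2w * v3
          x4 <- x + dt * k3x;       v4 <- v + dt * k3v
          k4x <- v4;                k4v <- w2 * (r - x4) - d2w * v4
          new_x <- x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
          new_v <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
          step_len2 <- sum((new_x - x)^2)
          pos[active] <- new_x
          vel[active] <- new_v
          traj_len <- traj_len + sqrt(step_len2)
        }
        t_now <- (k - 1L) * tick + s * dt
        if (keep) {
          ti <- ti + 1L
          traj[ti, ] <- c(t_now, pos)
        }
        if (sum((pos - cfg$target)^2) <= r2) {
          reached <- TRUE
          break
        }
      }
      if (reached) break
    }
  }
  final_distance <- vnorm(pos - cfg$target)
  out <- list(
    reached = reached,
    time_s = if (reached) t_now else cfg$time_limit_s,
    n_posture_changes = n_changes,
    trajectory_length = traj_len,
    final_distance = final_distance,
    final_position = pos,
    target = cfg$target
  )
  if (keep) out$trajectory <- traj[seq_len(ti), , drop = FALSE]
  structure(out, class = "cube_trial")
}

#' @export
print.cube_trial <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("cube_trial: target reached in %.2f s, %d posture change(s), trajectory length %.3f\n",
                x$time_s, x$n_posture_changes, x$trajectory_length))
  } else {
    cat(sprintf("cube_trial: failed; final distance %.3f after %.0f s, %d posture change(s), trajectory length %.3f\n",
                x$final_distance, x$time_s, x$n_posture_changes,
                x$trajectory_length))
  }
  invisible(x)
}

#' @export
as.data.frame.cube_trial <- function(x, ...) {
  data.frame(reached = x$reached, time_s = x$time_s,
             n_posture_changes = x$n_posture_changes,
             trajectory_length = x$trajectory_length,
             final_distance = x$final_distance)
}

#' @export
plot.cube_trial <- function(x, ...) {
  if (is.null(x$trajectory))
    stop("trial was run without return_trajectory = TRUE", call. = FALSE)
  tr <- x$trajectory
  graphics::matplot(tr[, "time_s"], tr[, c("x", "y", "z")], type = "l",
                    lty = 1, xlab = "time (s)", ylab = "cube position",
                    main = "sphere trajectory per axis", ...)
  graphics::abline(h = x$target, lty = 3, col = seq_len(3))
  graphics::legend("topright", legend = c("shoulder", "elbow", "wrist"),
                   col = seq_len(3), lty = 1, bty = "n")
  invisible(x)
}
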