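#' Second-order sphere dynamics parameters
#'
#' The red sphere moves along each cube axis as the step response of a
#' second-order system
#' \deqn{C(s)/R(s) = \omega_n^2 / (s^2 + 2\delta\omega_n s + \omega_n^2)}
#' where R is the per-axis commanded corner value and C the sphere
#' position. The study fixed \eqn{\omega_n = 0.39} (cube units) and
#' \eqn{\delta = 1} (critical damping: monotone approach, no overshoot)
#' for every subject.
#'
#' @param omega_n Natural frequency, > 0.
#' @param delta Damping ratio, > 0.
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(omega_n = 0.39, delta = 1) {
  stop_if_not_scalar_pos(omega_n, "omega_n")
  stop_if_not_scalar_pos(delta, "delta")
  structure(list(omega_n = omega_n, delta = delta), class = "dynamics_params")
}

#' Intermittent-controller joint activation rule
#'
#' The intermittent controller actuates, at each posture-change event,
#' only the joints where a change occurred:
#' * first posture of a trial (no previous): all three joints active;
#' * one or two joints changed: exactly those joints active;
#' * all three changed at once: only the shoulder is activated, and
#'   elbow/wrist stay inactive until a later posture change that does
#'   not involve the shoulder (tracked through `shoulder_lock`; while
#'   the lock holds, any change involving the shoulder re-applies the
#'   shoulder-only rule).
#'
#' An event whose posture equals the previous one changes no joint and
#' yields an all-off mask.
#'
#' @param prev Previous posture code, or `NULL` at trial start.
#' @param new New posture code.
#' @param shoulder_lock Logical: is the elbow/wrist lock from a prior
#'   three-joint change still pending?
#' @return List with `mask` (named logical 3-vector: shoulder, elbow,
#'   wrist) and the updated `shoulder_lock`.
#' @export
joint_activation <- function(prev, new, shoulder_lock = FALSE) {
  pn <- parse_posture(new)
  axes <- c("shoulder", "elbow", "wrist")
  if (is.null(prev)) {
    return(list(mask = stats::setNames(rep(TRUE, 3L), axes),
                shoulder_lock = FALSE))
  }
  pp <- parse_posture(prev)
  changed <- pn != pp
  names(changed) <- axes
  if (!any(changed)) {
    return(list(mask = stats::setNames(rep(FALSE, 3L), axes),
                shoulder_lock = shoulder_lock))
  }
  if (shoulder_lock) {
    if (changed[["shoulder"]]) {
      mask <- c(shoulder = TRUE, elbow = FALSE, wrist = FALSE)
      return(list(mask = mask, shoulder_lock = TRUE))
    }
    return(list(mask = changed, shoulder_lock = FALSE))
  }
  if (all(changed)) {
    mask <- c(shoulder = TRUE, elbow = FALSE, wrist = FALSE)
    return(list(mask = mask, shoulder_lock = TRUE))
  }
  list(mask = changed, shoulder_lock = FALSE)
}

#' One RK4 integration step of the sphere dynamics
#'
#' Advances each *active* axis of the controller state by one
#' Runge–Kutta 4 step of
#' \eqn{x'' = \omega_n^2 (r - x) - 2 \delta \omega_n x'};
#' inactive axes hold their position exactly (their velocity is zero
#' while deactivated). Position and velocity are continuous across
#' retargeting: commanding a new reference mid-flight simply bends the
#' trajectory.
#'
#' @param state List with numeric 3-vectors `position`, `velocity`,
#'   `reference` and logical 3-vector `active`.
#' @param params A [dynamics_params()].
#' @param dt Step size in seconds, > 0.
#' @return The updated state list.
#' @export
step_dynamics <- function(state, params = dynamics_params(), dt) {
  stop_if_not_scalar_pos(dt, "dt")
  a <- state$active
  if (!any(a)) return(state)
  w <- params$omega_n
  d <- params$delta
  x <- state$position[a]
  v <- state$velocity[a]
  r <- state$reference[a]
  acc <- function(x, v) w * w * (r - x) - 2 * d * w * v
  k1x <- v;                 k1v <- acc(x, v)
  k2x <- v + dt / 2 * k1v;  k2v <- acc(x + dt / 2 * k1x, v + dt / 2 * k1v)
  k3x <- v + dt / 2 * k2v;  k3v <- acc(x + dt / 2 * k2x, v + dt / 2 * k2v)
  k4x <- v + dt * k3v;      k4v <- acc(x + dt * k3x, v + dt * k3v)
  state$position[a] <- x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
  state$velocity[a] <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  state
}

#' Closed-form critically damped step response
#'
#' Analytic solution of \eqn{x'' = \omega^2 (r - x) - 2 \omega x'}
#' (damping ratio exactly 1) from initial position `x0` and velocity
#' `v0`:
#' \deqn{x(t) = r + (A + B t) e^{-\omega t}, \quad A = x_0 - r,\;
#'       B = v_0 + \omega A.}
#' Serves as the independent oracle for the RK4 integrator and as the
#' fast per-segment simulator inside the reachability search.
#'
#' @param t Time(s) since the step, seconds (vectorized).
#' @param x0,v0 Initial position and velocity.
#' @param r Commanded reference.
#' @param omega Natural frequency.
#' @return List with vectors `x` and `v` evaluated at `t`.
#' @export
damped_step_response <- function(t, x0, v0, r, omega) {
  A <- x0 - r
  B <- v0 + omega * A
  e <- exp(-omega * t)
  list(x = r + (A + B * t) * e,
       v = (B - omega * (A + B * t)) * e)
}
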