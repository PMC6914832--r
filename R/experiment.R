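#' Greedy "oracle subject" posture policy
#'
#' A scripted stand-in for the human operator, used only to exercise
#' target-reaching trials end to end (it models no behavioral finding):
#' once per `decision_interval_s` it evaluates every candidate posture
#' under the intermittent activation rule, predicts the sphere position
#' a lookahead interval ahead with the closed-form critically damped
#' solution, and commands the posture that most reduces the distance to
#' the target (keeping the current posture when no change improves on
#' it). With `error_rate > 0`, each commanded posture is replaced, with
#' that probability, by a uniformly random different posture —
#' emulating classifier misclassifications driving the cursor in an
#' unexpected direction.
#'
#' Requires `delta = 1`.
#'
#' @param target Numeric 3-vector.
#' @param postures Candidate posture codes.
#' @param params A [dynamics_params()] with `delta = 1`.
#' @param time_limit_s,capture_radius Trial limits.
#' @param decision_interval_s Seconds between policy decisions.
#' @param error_rate Per-command misclassification probability.
#' @param seed RNG seed for the misclassification draws.
#' @param axis_signs Corner sign convention.
#' @return A posture stream `data.frame(time_s, posture)` suitable for
#'   [run_trial()].
#' @export
greedy_posture_stream <- function(target, postures = all_postures(),
                                  params = dynamics_params(),
                                  time_limit_s = 120, capture_radius = 0.1,
                                  decision_interval_s = 1,
                                  error_rate = 0, seed = NULL,
                                  axis_signs = c(1, 1, 1)) {
  if (params$delta != 1)
    stop("the greedy policy's lookahead assumes critical damping (delta = 1)",
         call. = FALSE)
  target <- as.numeric(target)
  omega <- params$omega_n
  corners <- vapply(postures, posture_to_corner, numeric(3L),
                    axis_signs = axis_signs)
  with_seed(seed, {
    pos <- c(0, 0, 0); vel <- c(0, 0, 0); ref <- c(0, 0, 0)
    active <- rep(FALSE, 3L)
    lock <- FALSE
    last <- NULL
    events <- list()
    t_now <- 0
    predict_pos <- function(mask, reference, horizon) {
      p <- pos
      resp <- damped_step_response(horizon, pos[mask], vel[mask],
                                   reference[mask], omega)
      p[mask] <- resp$x
      p
    }
    while (t_now < time_limit_s) {
      if (vnorm(pos - target) <= capture_radius) break
      # score keeping the current command
      best_p <- NA_character_
      best_d <- vnorm(predict_pos(active, ref, decision_interval_s) - target)
      for (j in seq_along(postures)) {
        cand <- postures[j]
        if (!is.null(last) && cand == last) next
        act <- joint_activation(last, cand, lock)
        cref <- ref
        cref[act$mask] <- corners[, j][act$mask]
        d <- vnorm(predict_pos(act$mask, cref, decision_interval_s) - target)
        if (d < best_d - 1e-9) {
          best_d <- d
          best_p <- cand
        }
      }
      if (!is.na(best_p)) {
        commanded <- best_p
        if (error_rate > 0 && stats::runif(1L) < error_rate) {
          others <- setdiff(postures, commanded)
          commanded <- sample(others, 1L)
        }
        if (is.null(last) || commanded != last) {
          act <- joint_activation(last, commanded, lock)
          lock <- act$shoulder_lock
          vel[active & !act$mask] <- 0
          ref[act$mask] <- corners[, match(commanded, postures)][act$mask]
          active <- act$mask
          last <- commanded
          events[[length(events) + 1L]] <- list(time_s = t_now,
                                                posture = commanded)
        }
      }
      # advance one decision interval, stopping early at capture
      tau <- seq(1 / 15, decision_interval_s, by = 1 / 15)
      if (any(active)) {
        resp <- damped_step_response(rep(tau, each = sum(active)),
                                     rep(pos[active], times = length(tau)),
                                     rep(vel[active], times = length(tau)),
                                     rep(ref[active], times = length(tau)),
                                     omega)
        xs <- matrix(NA_real_, length(tau), 3L)
        xs[, which(active)] <- matrix(resp$x, ncol = sum(active), byrow = TRUE)
        for (ax in which(!active)) xs[, ax] <- pos[ax]
        d <- sqrt(rowSums(sweep(xs, 2L, target)^2))
        hit <- which(d <= capture_radius)
        stop_i <- if (length(hit) > 0L) hit[1L] else length(tau)
        end <- damped_step_response(tau[stop_i], pos[active], vel[active],
                                    ref[active], omega)
        pos[active] <- end$x
        vel[active] <- end$v
        t_now <- t_now + tau[stop_i]
        if (length(hit) > 0L) break
      } else {
        t_now <- t_now + decision_interval_s
      }
    }
    if (length(events) == 0L)
      return(data.frame(time_s = numeric(0), posture = character(0)))
    data.frame(time_s = vapply(events, `[[`, numeric(1L), "time_s"),
               posture = vapply(events, `[[`, character(1L), "posture"))
  })
}

#' Run a simulated multi-subject experiment
#'
#' For every seed (a simulated subject): generate synthetic training
#' and evaluation EMG, train five- and eight-posture round-robin
#' classifiers on the same recordings, measure per-condition
#' classification accuracy, then run `trials_per_target` greedy-policy
#' reaching trials for each condition's four targets. The per-command
#' misclassification probability of the policy is coupled to the
#' measured accuracy of that seed's classifier, so noisier synthetic
#' subjects both classify and reach worse. Per-condition reach ratio
#' is reached-trials / (4 targets x `trials_per_target`).
#'
#' @param seeds Integer vector, one per simulated subject.
#' @param noise_sigma Envelope noise scale of the synthetic EMG.
#' @param rank,restarts Classifier training parameters.
#' @param train_hold_s,eval_hold_s,eval_reps Protocol hold durations
#'   (study protocol: 10 s training, 3 x 5 s evaluation).
#' @param n_iter Evaluation frames per posture.
#' @param postures_five Five-posture subset (condition "five").
#' @param targets Named list of target 3-vectors `t1..t5`; condition
#'   "five" reaches t1–t4, condition "eight" t1, t2, t3, t5.
#' @param trials_per_target Trials per target (3 in the study).
#' @param time_limit_s Trial time limit.
#' @param fs Sampling rate.
#' @param params A [dynamics_params()].
#' @return An object of class `experiment_summary` with `accuracy`
#'   (seed x condition), `trials` (one row per trial), and
#'   `reach_ratio` tables.
#' @export
run_experiment <- function(seeds = 1:12, noise_sigma = 0.15, rank = 3L,
                           restarts = 30L, train_hold_s = 10,
                           eval_hold_s = 5, eval_reps = 3L, n_iter = 30L,
                           postures_five = five_posture_subset(),
                           targets = default_targets(),
                           trials_per_target = 3L, time_limit_s = 120,
                           fs = 2000, params = dynamics_params()) {
  stopifnot(all(postures_five %in% all_postures()))
  need_t <- c("t1", "t2", "t3", "t4", "t5")
  if (!all(need_t %in% names(targets)))
    stop("targets must be a named list with t1..t5", call. = FALSE)
  cond_targets <- list(five = c("t1", "t2", "t3", "t4"),
                       eight = c("t1", "t2", "t3", "t5"))
  acc_rows <- list()
  trial_rows <- list()
  for (s in seeds) {
    bank <- make_synergy_bank(8L, rank_true = rank, noise_sigma = noise_sigma,
                              seed = s)
    train_env <- training_envelopes(bank, hold_s = train_hold_s, fs = fs,
                                    seed = s * 1000L + 1L)
    eval_env <- evaluation_envelopes(bank, hold_s = eval_hold_s,
                                     reps = eval_reps, fs = fs,
                                     seed = s * 1000L + 2L)
    clfs <- list(
      five = suppressWarnings(train_round_robin(train_env[postures_five],
                                                rank = rank,
                                                restarts = restarts, seed = s)),
      eight = suppressWarnings(train_round_robin(train_env, rank = rank,
                                                 restarts = restarts,
                                                 seed = s + 500L))
    )
    for (cond in names(clfs)) {
      test_env <- if (cond == "five") eval_env[postures_five] else eval_env
      acc <- evaluate_classifier(clfs[[cond]], test_env, n_iter = n_iter)
      acc_rows[[length(acc_rows) + 1L]] <-
        data.frame(seed = s, condition = cond, accuracy = acc$overall)
      err <- (100 - acc$overall) / 100
      avail <- if (cond == "five") postures_five else all_postures()
      for (tn in cond_targets[[cond]]) {
        for (tr in seq_len(trials_per_target)) {
          stream <- greedy_posture_stream(
            targets[[tn]], postures = avail, params = params,
            time_limit_s = time_limit_s, error_rate = err,
            seed = s * 100000L + match(cond, names(clfs)) * 10000L +
              match(tn, need_t) * 100L + tr)
          res <- run_trial(stream,
                           trial_config(targets[[tn]],
                                        time_limit_s = time_limit_s),
                           params = params)
          trial_rows[[length(trial_rows) + 1L]] <-
            cbind(data.frame(seed = s, condition = cond, target = tn,
                             trial = tr), as.data.frame(res))
        }
      }
    }
  }
  accuracy <- do.call(rbind, acc_rows)
  trials <- do.call(rbind, trial_rows)
  reach_ratio <- stats::aggregate(reached ~ seed + condition, trials, mean)
  names(reach_ratio)[3L] <- "reach_ratio"
  structure(list(accuracy = accuracy, trials = trials,
                 reach_ratio = reach_ratio, seeds = seeds,
                 noise_sigma = noise_sigma),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("experiment_summary: %d seed(s), envelope noise sigma %g\n",
              length(x$seeds), x$noise_sigma))
  m <- stats::aggregate(accuracy ~ condition, x$accuracy, mean)
  s <- stats::aggregate(accuracy ~ condition, x$accuracy, stats::sd)
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %s-posture accuracy: %.1f%% (sd %.1f)\n",
                ifelse(m$condition[i] == "five", "5", "8"),
                m$accuracy[i], s$accuracy[i]))
  r <- stats::aggregate(reach_ratio ~ condition, x$reach_ratio, mean)
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %s-posture mean reach ratio: %.2f\n",
                ifelse(r$condition[i] == "five", "5", "8"), r$reach_ratio[i]))
  invisible(x)
}

#' Compare conditions of an experiment summary
#'
#' Paired t-test of per-seed accuracy (and reach ratio) between the
#' five- and eight-posture conditions.
#'
#' @param summary An [run_experiment()] result.
#' @return List with `accuracy` and `reach_ratio` test results
#'   (each a list `t`, `df`, `p`).
#' @export
compare_conditions <- function(summary) {
  stopifnot(inherits(summary, "experiment_summary"))
  wide <- function(d, col) {
    five <- d[d$condition == "five", ]
    eight <- d[d$condition == "eight", ]
    five <- five[order(five$seed), ]
    eight <- eight[order(eight$seed), ]
    list(x = five[[col]], y = eight[[col]])
  }
  a <- wide(summary$accuracy, "accuracy")
  r <- wide(summary$reach_ratio, "reach_ratio")
  list(accuracy = paired_ttest(a$x, a$y),
       reach_ratio = paired_ttest(r$x, r$y))
}
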