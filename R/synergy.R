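#' Fit a pairwise-posture muscle-synergy model
#'
#' The core extraction step: envelopes of two static postures are
#' concatenated frame-wise into one non-negative matrix V (channels x
#' frames) and factorized by NMF. Because NMF solutions are not unique,
#' the factorization is repeated `restarts` times from different random
#' initializations (seeds `seed, seed + 1, ...`) and the run whose
#' activation columns best separate the two postures — highest mean
#' silhouette of the H columns labeled by their source posture — is
#' kept. The kept run's per-posture mean activation vectors become the
#' class references of the binary minimum-distance classifier.
#'
#' A model whose two class mean activations coincide is flagged
#' `degenerate` — it cannot distinguish its postures at all (identical
#' training envelopes produce this). A model whose mean silhouette
#' falls below `degenerate_tol` is flagged `low_silhouette`: its
#' posture clouds barely separate, so its votes are unreliable;
#' training warns but the model still votes.
#'
#' @param env_a,env_b [emg_envelope()] objects (or plain frames x
#'   channels matrices) for the two postures; channel counts must
#'   match.
#' @param posture_a,posture_b Posture codes naming the two classes.
#' @param rank Number of synergies extracted per pair (three synergies
#'   from the five biceps channels by default).
#' @param restarts Number of NMF restarts; the study protocol used 30.
#' @param seed Base seed; restart `k` uses `seed + k - 1`.
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @param degenerate_tol Mean-silhouette threshold below which the
#'   model is flagged degenerate.
#' @return An object of class `pairwise_synergy`: the winning
#'   [nmf_factorize()] fit, `mean_a`/`mean_b` cluster mean activations,
#'   `silhouette_mean`, and a `degenerate` flag.
#' @export
fit_pairwise_synergy <- function(env_a, env_b, posture_a = "A", posture_b = "B",
                                 rank = 3L, restarts = 30L, seed = 1L,
                                 max_iter = 500L, tol = 1e-6,
                                 degenerate_tol = 0.05) {
  fa <- if (inherits(env_a, "emg_envelope")) env_a$frames else as.matrix(env_a)
  fb <- if (inherits(env_b, "emg_envelope")) env_b$frames else as.matrix(env_b)
  if (nrow(fa) < 1L || nrow(fb) < 1L)
    stop("both postures need at least one envelope frame", call. = FALSE)
  if (ncol(fa) != ncol(fb))
    stop("channel counts differ between the two envelopes", call. = FALSE)
  n_ch <- ncol(fa)
  if (rank > n_ch)
    stop(sprintf("rank (%d) exceeds channel count (%d)", rank, n_ch),
         call. = FALSE)
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("'restarts' must be >= 1", call. = FALSE)
  V <- t(rbind(fa, fb))  # channels x frames
  src <- rep(c("a", "b"), c(nrow(fa), nrow(fb)))
  best <- NULL
  best_sil <- -Inf
  for (k in seq_len(restarts)) {
    fit <- nmf_factorize(V, rank = rank, seed = seed + k - 1L,
                         max_iter = max_iter, tol = tol)
    sil <- silhouette_index(t(fit$H), src)$mean
    if (sil > best_sil) {
      best_sil <- sil
      best <- fit
    }
  }
  mean_a <- rowMeans(best$H[, src == "a", drop = FALSE])
  mean_b <- rowMeans(best$H[, src == "b", drop = FALSE])
  # degenerate: the two class references coincide, so the model cannot
  # vote meaningfully. low_silhouette: usable but unreliable (warned).
  degenerate <- isTRUE(all.equal(mean_a, mean_b, tolerance = 1e-8))
  low_silhouette <- best_sil < degenerate_tol
  structure(
    list(posture_a = posture_a, posture_b = posture_b, nmf = best,
         mean_a = mean_a, mean_b = mean_b, silhouette_mean = best_sil,
         rank = as.integer(rank), restarts = restarts, seed = seed,
         degenerate = degenerate, low_silhouette = low_silhouette),
    class = "pairwise_synergy"
  )
}

#' @export
print.pairwise_synergy <- function(x, ...) {
  cat(sprintf("pairwise_synergy %s vs %s: rank %d, silhouette %.3f%s\n",
              x$posture_a, x$posture_b, x$rank, x$silhouette_mean,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Project an envelope frame into a model's synergy-activation space
#'
#' Online frames are mapped into a pairwise model's activation space by
#' non-negative least squares against the model's synergy basis W:
#' the returned h minimizes \eqn{\|frame - W h\|^2} subject to
#' \eqn{h \ge 0}.
#'
#' @param model A [fit_pairwise_synergy()] model.
#' @param frame Non-negative numeric vector, one entry per channel.
#' @return Non-negative activation vector of length `rank`.
#' @export
project_activation <- function(model, frame) {
  stopifnot(inherits(model, "pairwise_synergy"))
  frame <- as.numeric(frame)
  W <- model$nmf$W
  if (length(frame) != nrow(W))
    stop(sprintf("frame length (%d) must equal channel count (%d)",
                 length(frame), nrow(W)), call. = FALSE)
  if (any(frame < 0))
    stop("envelope frames are non-negative; got a negative entry", call. = FALSE)
  if (all(frame == 0)) return(numeric(ncol(W)))
  h <- tryCatch(pracma::lsqnonneg(W, frame)$x,
                error = function(e) nnls_mult(W, frame))
  pmax(h, 0)
}

# Multiplicative-update non-negative least squares: min ||f - W h||^2,
# h >= 0. Used when the active-set solver hits a rank-deficient basis
# (common when the NMF rank exceeds the numerical rank of the envelope
# block, e.g. on noiseless synthetic data).
nnls_mult <- function(W, f, max_iter = 5000L, tol = 1e-14) {
  WtW <- crossprod(W)
  Wtf <- crossprod(W, f)
  if (all(Wtf <= 0)) return(numeric(ncol(W)))
  h <- rep(max(mean(f) / max(mean(W), 1e-12), 1e-12), ncol(W))
  eps <- 1e-16
  prev <- Inf
  for (i in seq_len(max_iter)) {
    h <- h * as.numeric(Wtf) / (as.numeric(WtW %*% h) + eps)
    if (i %% 25L == 0L) {
      obj <- sum((f - W %*% h)^2)
      if (prev - obj < tol * max(prev, eps)) break
      prev <- obj
    }
  }
  h
}
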