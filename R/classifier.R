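#' Train a round-robin posture classifier
#'
#' Fits the n-posture classifier as an ensemble of all
#' `n * (n - 1) / 2` pairwise-posture synergy models (one per unordered
#' pair, via [fit_pairwise_synergy()]). At prediction time every
#' pairwise model votes for the posture whose cluster-mean activation
#' is nearer (minimum Euclidean distance in its own synergy space) and
#' the posture with most votes wins ("winner takes all"). With eight
#' static postures this yields 28 binary classifiers; with five, 10.
#'
#' @param envelopes Either a named list mapping posture code to an
#'   [emg_envelope()] (or frames matrix), or a single labeled
#'   [emg_envelope()] which is split by [split_envelope()]. Every
#'   posture needs at least two frames.
#' @param rank Synergies per pairwise model (default 3).
#' @param restarts NMF restarts per pairwise model (default 30).
#' @param seed Base seed. Every pairwise fit draws its restarts from
#'   the same seed family `seed, seed + 1, ...` — the pairs factorize
#'   different data, so no initialization diversity is lost, and
#'   training is exactly equivariant under relabeling or reordering of
#'   the postures.
#' @param ... Further arguments to [fit_pairwise_synergy()].
#' @return An object of class `posture_classifier` with components
#'   `postures` (the ordered code list — also the deterministic
#'   tie-break order), `models` (named `"A|B"`), and the training
#'   parameters.
#' @seealso [classify_frame()], [predict.posture_classifier()],
#'   [evaluate_classifier()]
#' @examples
#' bank <- make_synergy_bank(n_postures = 3, seed = 1,
#'                           postures = c("FFS", "FEP", "EES"))
#' env <- training_envelopes(bank, hold_s = 2, seed = 1)
#' clf <- train_round_robin(env, restarts = 2, seed = 1)
#' clf
#' @export
train_round_robin <- function(envelopes, rank = 3L, restarts = 30L, seed = 1L,
                              ...) {
  if (inherits(envelopes, "emg_envelope")) envelopes <- split_envelope(envelopes)
  if (!is.list(envelopes) || is.null(names(envelopes)) ||
      any(!nzchar(names(envelopes))))
    stop("'envelopes' must be a named list: posture code -> envelope", call. = FALSE)
  postures <- names(envelopes)
  if (length(postures) < 2L) stop("need at least two postures", call. = FALSE)
  if (anyDuplicated(postures)) stop("duplicated posture codes", call. = FALSE)
  frames_of <- function(e) if (inherits(e, "emg_envelope")) e$frames else as.matrix(e)
  n_frames <- vapply(envelopes, function(e) nrow(frames_of(e)), integer(1L))
  if (any(n_frames < 2L))
    stop(sprintf("posture '%s' has fewer than 2 envelope frames",
                 postures[which(n_frames < 2L)[1L]]), call. = FALSE)
  pairs <- utils::combn(length(postures), 2L)
  models <- vector("list", ncol(pairs))
  names(models) <- apply(pairs, 2L, function(ij)
    paste(postures[ij[1L]], postures[ij[2L]], sep = "|"))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    models[[j]] <- fit_pairwise_synergy(
      envelopes[[i1]], envelopes[[i2]],
      posture_a = postures[i1], posture_b = postures[i2],
      rank = rank, restarts = restarts, seed = seed, ...)
  }
  n_degen <- sum(vapply(models, function(m) m$degenerate, logical(1L)))
  n_low <- sum(vapply(models, function(m) isTRUE(m$low_silhouette), logical(1L)))
  if (n_degen > 0L)
    warning(sprintf("%d of %d pairwise models are degenerate (identical class means)",
                    n_degen, length(models)), call. = FALSE)
  if (n_low > 0L)
    warning(sprintf("%d of %d pairwise models have low silhouette (< 0.05); their votes are unreliable",
                    n_low, length(models)), call. = FALSE)
  structure(
    list(postures = postures, models = models, rank = as.integer(rank),
         restarts = as.integer(restarts), seed = seed,
         tie_rule = "lowest index in the classifier's posture ordering"),
    class = "posture_classifier"
  )
}

#' @export
print.posture_classifier <- function(x, ...) {
  n <- length(x$postures)
  cat(sprintf("posture_classifier: %d postures, %d pairwise synergy models (rank %d, %d restarts)\n",
              n, length(x$models), x$rank, x$restarts))
  cat("  postures:", paste(x$postures, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.posture_classifier <- function(object, ...) {
  sil <- vapply(object$models, function(m) m$silhouette_mean, numeric(1L))
  degen <- vapply(object$models, function(m) m$degenerate, logical(1L))
  out <- list(
    n_postures = length(object$postures),
    n_models = length(object$models),
    silhouette = data.frame(pair = names(object$models), silhouette = sil,
                            degenerate = degen, row.names = NULL),
    rank = object$rank, restarts = object$restarts
  )
  class(out) <- "summary.posture_classifier"
  out
}

#' @export
print.summary.posture_classifier <- function(x, ...) {
  cat(sprintf("Round-robin classifier: %d postures -> %d pairwise models\n",
              x$n_postures, x$n_models))
  cat(sprintf("Mean pairwise silhouette: %.3f (min %.3f, %d degenerate)\n",
              mean(x$silhouette$silhouette), min(x$silhouette$silhouette),
              sum(x$silhouette$degenerate)))
  print(x$silhouette, digits = 3)
  invisible(x)
}

#' Classify a single envelope frame
#'
#' Every pairwise model projects the frame into its own activation
#' space ([project_activation()]) and votes for the posture whose
#' cluster mean is nearer in Euclidean distance. Votes are combined
#' winner-takes-all; ties (between votes, or between the two distances
#' within one model) are broken toward the posture earlier in the
#' classifier's posture ordering and the result is flagged ambiguous.
#'
#' @param clf A [train_round_robin()] classifier.
#' @param frame Non-negative numeric vector, one entry per channel.
#' @return An object of class `posture_classification`: `winner`,
#'   named integer `votes` (summing to `n*(n-1)/2`), per-model decision
#'   table, and an `ambiguous` flag.
#' @export
classify_frame <- function(clf, frame) {
  stopifnot(inherits(clf, "posture_classifier"))
  usable <- !vapply(clf$models, function(m) m$degenerate, logical(1L))
  if (!any(usable))
    stop("all pairwise models are degenerate; classifier is unusable", call. = FALSE)
  votes <- stats::setNames(integer(length(clf$postures)), clf$postures)
  rows <- vector("list", length(clf$models))
  ambiguous <- FALSE
  ord <- stats::setNames(seq_along(clf$postures), clf$postures)
  for (j in seq_along(clf$models)) {
    m <- clf$models[[j]]
    h <- project_activation(m, frame)
    da <- vnorm(h - m$mean_a)
    db <- vnorm(h - m$mean_b)
    chosen <- if (da < db) m$posture_a
      else if (db < da) m$posture_b
      else {  # exact distance tie: earlier posture in the ordering
        ambiguous <- TRUE
        if (ord[[m$posture_a]] <= ord[[m$posture_b]]) m$posture_a else m$posture_b
      }
    votes[chosen] <- votes[chosen] + 1L
    rows[[j]] <- data.frame(pair = names(clf$models)[j], chosen = chosen,
                            dist_a = da, dist_b = db)
  }
  top <- max(votes)
  leaders <- names(votes)[votes == top]
  if (length(leaders) > 1L) ambiguous <- TRUE
  winner <- leaders[which.min(ord[leaders])]
  structure(
    list(winner = winner, votes = votes,
         per_model = do.call(rbind, rows), ambiguous = ambiguous),
    class = "posture_classification"
  )
}

#' @export
print.posture_classification <- function(x, ...) {
  cat(sprintf("posture: %s (%d/%d votes)%s\n", x$winner, x$votes[[x$winner]],
              sum(x$votes), if (x$ambiguous) " [ambiguous]" else ""))
  invisible(x)
}

#' Predict postures for envelope frames
#'
#' @param object A `posture_classifier`.
#' @param newdata An [emg_envelope()] or a frames x channels matrix.
#' @param type `"class"` for a character vector of winning postures,
#'   `"votes"` for the full vote matrix (frames x postures).
#' @param debounce Consume a classification only after the same winner
#'   on this many consecutive frames (1 = off, the study default);
#'   until a run of agreement occurs the previous consumed posture is
#'   carried forward (`NA` before the first).
#' @param ... Unused.
#' @return Character vector (or integer matrix for `type = "votes"`).
#' @export
predict.posture_classifier <- function(object, newdata,
                                       type = c("class", "votes"),
                                       debounce = 1L, ...) {
  type <- match.arg(type)
  frames <- if (inherits(newdata, "emg_envelope")) newdata$frames
    else as.matrix(newdata)
  res <- lapply(seq_len(nrow(frames)), function(i)
    classify_frame(object, frames[i, ]))
  if (type == "votes") {
    out <- do.call(rbind, lapply(res, function(r) r$votes))
    rownames(out) <- NULL
    return(out)
  }
  winners <- vapply(res, function(r) r$winner, character(1L))
  if (debounce > 1L) winners <- debounce_stream(winners, debounce)
  winners
}

# Keep a classification only when the same winner occurs on k consecutive
# frames; otherwise carry the last consumed value forward (NA before any).
debounce_stream <- function(winners, k) {
  out <- rep(NA_character_, length(winners))
  current <- NA_character_
  run <- 0L
  last <- NA_character_
  for (i in seq_along(winners)) {
    if (!is.na(last) && winners[i] == last) run <- run + 1L else run <- 1L
    last <- winners[i]
    if (run >= k) current <- winners[i]
    out[i] <- current
  }
  out
}

#' Evaluate classification accuracy per posture
#'
#' Mirrors the study's evaluation cadence: for each posture, `n_iter`
#' frames are drawn evenly spaced from the posture's test envelope (all
#' frames if fewer exist) and classified; accuracy is the percentage
#' classified as the true posture.
#'
#' @param clf A [train_round_robin()] classifier.
#' @param test Named list posture -> [emg_envelope()] (or matrix), or a
#'   labeled [emg_envelope()]. Every posture must be known to the
#'   classifier.
#' @param n_iter Frames evaluated per posture (default 30).
#' @return An object of class `classifier_evaluation`: a per-posture
#'   accuracy table and the overall percentage.
#' @export
evaluate_classifier <- function(clf, test, n_iter = 30L) {
  stopifnot(inherits(clf, "posture_classifier"))
  if (inherits(test, "emg_envelope")) test <- split_envelope(test)
  unknown <- setdiff(names(test), clf$postures)
  if (length(unknown) > 0L)
    stop(sprintf("posture(s) unknown to the classifier: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  per <- lapply(names(test), function(p) {
    frames <- if (inherits(test[[p]], "emg_envelope")) test[[p]]$frames
      else as.matrix(test[[p]])
    n <- nrow(frames)
    idx <- if (n <= n_iter) seq_len(n) else round(seq(1L, n, length.out = n_iter))
    pred <- vapply(idx, function(i) classify_frame(clf, frames[i, ])$winner,
                   character(1L))
    data.frame(posture = p, n_frames = length(idx),
               n_correct = sum(pred == p),
               accuracy = 100 * mean(pred == p))
  })
  tab <- do.call(rbind, per)
  overall <- 100 * sum(tab$n_correct) / sum(tab$n_frames)
  structure(list(per_posture = tab, overall = overall, n_iter = n_iter),
            class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("Classification accuracy over %d postures: %.1f%%\n",
              nrow(x$per_posture), x$overall))
  print(x$per_posture, digits = 4, row.names = FALSE)
  invisible(x)
}
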