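#' Save / load a trained posture classifier
#'
#' Classifiers are serialized to a single self-describing JSON file:
#' matrices are stored with their dimensions and full double precision,
#' so a write/read round trip reproduces the classifier to within
#' floating-point text conversion (lossless for IEEE doubles).
#'
#' @param clf A [train_round_robin()] classifier.
#' @param path Output / input file path.
#' @return `write_classifier` returns `clf` invisibly;
#'   `read_classifier` returns the reconstructed `posture_classifier`.
#' @export
write_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "posture_classifier"))
  mat <- function(m) list(dim = dim(m), data = as.numeric(m))
  payload <- list(
    format = "synergycube-classifier",
    version = 1L,
    postures = clf$postures,
    rank = clf$rank,
    restarts = clf$restarts,
    seed = clf$seed,
    tie_rule = clf$tie_rule,
    models = lapply(clf$models, function(m) list(
      posture_a = m$posture_a, posture_b = m$posture_b,
      W = mat(m$nmf$W), H = mat(m$nmf$H),
      recon_error = m$nmf$recon_error,
      iterations = m$nmf$iterations,
      converged = m$nmf$converged,
      rank = m$rank, restarts = m$restarts, seed = m$seed,
      mean_a = m$mean_a, mean_b = m$mean_b,
      silhouette_mean = m$silhouette_mean,
      degenerate = m$degenerate,
      low_silhouette = isTRUE(m$low_silhouette)
    ))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(clf)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path), call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "synergycube-classifier"))
    stop("not a synergycube classifier file", call. = FALSE)
  unmat <- function(m) matrix(m$data, nrow = m$dim[1L], ncol = m$dim[2L])
  models <- lapply(p$models, function(m) {
    nmf <- structure(
      list(W = unmat(m$W), H = unmat(m$H), recon_error = m$recon_error,
           objective = numeric(0), iterations = m$iterations,
           converged = m$converged, rank = m$rank),
      class = "nmf_fit")
    structure(
      list(posture_a = m$posture_a, posture_b = m$posture_b, nmf = nmf,
           mean_a = as.numeric(m$mean_a), mean_b = as.numeric(m$mean_b),
           silhouette_mean = m$silhouette_mean, rank = as.integer(m$rank),
           restarts = as.integer(m$restarts), seed = m$seed,
           degenerate = isTRUE(m$degenerate),
           low_silhouette = isTRUE(m$low_silhouette)),
      class = "pairwise_synergy")
  })
  structure(
    list(postures = as.character(p$postures), models = models,
         rank = as.integer(p$rank), restarts = as.integer(p$restarts),
         seed = p$seed, tie_rule = p$tie_rule),
    class = "posture_classifier"
  )
}
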