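#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `V` (channels x frames) into
#' `W %*% H` with `W` (channels x rank) holding the muscle-synergy
#' vectors and `H` (rank x frames) their per-frame activations, by the
#' Lee–Seung multiplicative update rules for the squared Frobenius
#' reconstruction error. The objective is non-increasing at every
#' iteration (up to floating-point round-off); iteration stops at
#' `max_iter` or when the relative improvement of the objective falls
#' below `tol`.
#'
#' @param V Non-negative numeric matrix, channels x frames.
#' @param rank Number of synergies; must satisfy
#'   `1 <= rank <= min(dim(V))`.
#' @param seed Integer seed for the random uniform initialization of
#'   `W`; `NULL` uses the current RNG state. The caller's RNG state is
#'   restored afterwards. `H` is initialized from the data as
#'   `t(W0) %*% V` (rescaled), which makes the whole factorization
#'   exactly equivariant to column permutations of `V`: permuting
#'   frames permutes the columns of `H` and leaves `W` untouched.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Relative-improvement stopping threshold on the objective.
#' @param W0,H0 Optional explicit non-negative initial factors
#'   (overriding the random initialization); useful for warm starts and
#'   for nested-rank comparisons.
#' @return An object of class `nmf_fit` with components `W`, `H`,
#'   `recon_error` (Frobenius norm of `V - W %*% H`), `objective`
#'   (the per-iteration trace of that norm), `iterations` and
#'   `converged`.
#' @references Lee, D. D. and Seung, H. S. (1999) Learning the parts of
#'   objects by non-negative matrix factorization. Nature 401, 788–791.
#' @export
nmf_factorize <- function(V, rank, seed = NULL, max_iter = 500L, tol = 1e-6,
                          W0 = NULL, H0 = NULL) {
  V <- as.matrix(V)
  if (!is.numeric(V) || anyNA(V)) stop("'V' must be numeric and complete", call. = FALSE)
  if (any(V < 0)) stop("'V' has negative entries; NMF requires V >= 0", call. = FALSE)
  m <- nrow(V); n <- ncol(V)
  if (!is.numeric(rank) || length(rank) != 1L || rank < 1L || rank > min(m, n))
    stop(sprintf("'rank' must lie in 1..min(dim(V)) = 1..%d", min(m, n)),
         call. = FALSE)
  rank <- as.integer(rank)
  eps <- 1e-12
  W <- if (is.null(W0)) {
    scale <- sqrt(mean(V) / rank + eps)
    with_seed(seed,
      matrix(stats::runif(m * rank, min = eps, max = 1), m, rank) * scale)
  } else {
    W0 <- as.matrix(W0)
    stopifnot(nrow(W0) == m, ncol(W0) == rank, all(W0 >= 0))
    W0 + eps
  }
  H <- if (is.null(H0)) {
    # data-driven: column j of H depends only on column j of V, so the
    # factorization is equivariant to frame permutations
    Hd <- crossprod(W, V) + eps
    Hd * (mean(V) / (mean(W %*% Hd) + eps))
  } else {
    H0 <- as.matrix(H0)
    stopifnot(nrow(H0) == rank, ncol(H0) == n, all(H0 >= 0))
    H0 + eps
  }
  obj <- numeric(max_iter)
  prev <- sqrt(sum((V - W %*% H)^2))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # H <- H * (W'V) / (W'W H);  W <- W * (VH') / (W H H')
    H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err <- sqrt(sum((V - W %*% H)^2))
    obj[it] <- err
    if (prev - err < tol * max(prev, eps)) {
      converged <- TRUE
      break
    }
    prev <- err
  }
  structure(
    list(W = W, H = H, recon_error = obj[it], objective = obj[seq_len(it)],
         iterations = it, converged = converged, rank = rank),
    class = "nmf_fit"
  )
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf(
    "nmf_fit: rank %d, %d x %d basis, recon error %.4g after %d iteration(s)%s\n",
    x$rank, nrow(x$W), ncol(x$H), x$recon_error, x$iterations,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}
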