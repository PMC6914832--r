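#' Paired and independent t-tests
#'
#' Thin wrappers around [stats::t.test()] returning the statistic and
#' two-sided p-value used for condition comparisons (e.g. five- vs
#' eight-posture accuracy). Degenerate inputs that the underlying test
#' rejects are resolved explicitly: all-zero differences (or two
#' identical constant samples) give `t = 0, p = 1`; constant non-zero
#' differences give an infinite statistic with `p = 0`.
#'
#' @param x,y Numeric sample vectors. For the paired test they must
#'   have equal length >= 2; for the independent test each needs >= 2
#'   observations.
#' @param var_equal For `independent_ttest`: pooled-variance test
#'   instead of the Welch default.
#' @return List with `t`, `df`, `p`.
#' @export
paired_ttest <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least two pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = length(d) - 1L, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' @rdname paired_ttest
#' @export
independent_ttest <- function(x, y, var_equal = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least two observations", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    df <- length(x) + length(y) - 2L
    if (mean(x) == mean(y)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
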