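#' Silhouette index of a clustering
#'
#' Per-point silhouette widths in Rousseeuw's formulation:
#' \deqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))}
#' where \eqn{a(i)} is the mean Euclidean distance from point *i* to the
#' other members of its own cluster and \eqn{b(i)} the smallest mean
#' distance to the points of any other cluster (for the two-cluster case
#' used to score pairwise-posture synergy activations, simply the mean
#' distance to the other cluster). Points in singleton clusters take
#' \eqn{s(i) = 0}, as do points with \eqn{a(i) = b(i) = 0}. Every score
#' lies in \eqn{[-1, 1]}; the mean over all points measures how well the
#' two postures' activation clouds separate.
#'
#' @param points Numeric matrix, one row per point (a vector is treated
#'   as one-dimensional points).
#' @param labels Cluster label per point; at least two distinct labels
#'   must be present.
#' @return A list with `scores` (per-point silhouette widths) and
#'   `mean` (their average).
#' @references Rousseeuw, P. J. (1987) Silhouettes: a graphical aid to
#'   the interpretation and validation of cluster analysis.
#'   J. Comput. Appl. Math. 20, 53–65.
#' @examples
#' s <- silhouette_index(c(0, 1, 10, 11), c("A", "A", "B", "B"))
#' s$mean  # 0.9048: tight, well-separated 1-D clusters
#' @export
silhouette_index <- function(points, labels) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1L)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("silhouette needs at least two points", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("'labels' must supply one label per point", call. = FALSE)
  lev <- unique(labels)
  if (length(lev) < 2L)
    stop("silhouette needs at least two clusters present", call. = FALSE)
  D <- as.matrix(stats::dist(points))
  sizes <- table(labels)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[own]] == 1L) {
      scores[i] <- 0
      next
    }
    a <- sum(D[i, labels == own]) / (sizes[[own]] - 1L)
    b <- min(vapply(lev[lev != own], function(l) mean(D[i, labels == l]),
                    numeric(1L)))
    m <- max(a, b)
    scores[i] <- if (m == 0) 0 else (b - a) / m
  }
  list(scores = scores, mean = mean(scores))
}
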