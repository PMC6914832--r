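# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Small noiseless 5-posture world: exact envelopes, fast training.
fix_bank5 <- function() fixture("bank5", function() {
  make_synergy_bank(n_postures = 5L, rank_true = 3L, noise_sigma = 0, seed = 1L)
})

fix_train5 <- function() fixture("train5", function() {
  training_envelopes(fix_bank5(), hold_s = 3, seed = 10L)
})

fix_clf5 <- function() fixture("clf5", function() {
  suppressWarnings(train_round_robin(fix_train5(), rank = 3L, restarts = 2L,
                                     seed = 1L))
})

fix_eval5 <- function() fixture("eval5", function() {
  evaluation_envelopes(fix_bank5(), hold_s = 2, reps = 2L, seed = 20L)
})

# Random non-negative envelope frames (frames x channels)
rand_frames <- function(n, ch = 5L, scale = 1, seed = NULL) {
  with_seed <- function(s, code) {
    if (!is.null(s)) set.seed(s)
    code
  }
  with_seed(seed, matrix(abs(stats::rnorm(n * ch)) * scale, n, ch))
}

# Brute-force silhouette oracle: direct double loop over the definition.
silhouette_bruteforce <- function(points, labels) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1L)
  n <- nrow(points)
  labels <- as.character(labels)
  ed <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) ed(i, j), numeric(1L)))
    bs <- vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(vapply(which(labels == l), function(j) ed(i, j), numeric(1L)))
    }, numeric(1L))
    b <- min(bs)
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(scores = s, mean = mean(s))
}
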