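test_that("NMF recovers exact low-rank structure and validates inputs", {
  set.seed(3)
  w <- abs(rnorm(5)); h <- abs(rnorm(40))
  V <- outer(w, h)
  fit <- nmf_factorize(V, rank = 1, seed = 1)
  expect_lt(fit$recon_error, 1e-6 * sqrt(sum(V^2)))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))

  expect_error(nmf_factorize(V - 1, rank = 1), "negative")
  expect_error(nmf_factorize(V, rank = 0), "rank")
  expect_error(nmf_factorize(V, rank = 6), "rank")
})

test_that("NMF objective is monotone non-increasing every iteration", {
  set.seed(7)
  for (s in 1:5) {
    V <- matrix(abs(rnorm(5 * 60)), 5, 60)
    fit <- nmf_factorize(V, rank = 3, seed = s, max_iter = 200, tol = 0)
    d <- diff(fit$objective)
    expect_true(all(d <= 1e-10 * fit$objective[1]))
  }
})

test_that("reconstruction error does not increase with rank on low-rank data", {
  set.seed(11)
  V <- matrix(abs(rnorm(5 * 3)), 5, 3) %*% matrix(abs(rnorm(3 * 200)), 3, 200)
  for (s in 1:3) {
    e2 <- nmf_factorize(V, rank = 2, seed = s, max_iter = 500)$recon_error
    e3 <- nmf_factorize(V, rank = 3, seed = s, max_iter = 500)$recon_error
    expect_lte(e3, e2 + 1e-8 * e2)
  }
  # nested-rank comparison with matched initialization: embed the rank-2
  # solution in a rank-3 start and confirm the objective cannot worsen
  f2 <- nmf_factorize(V, rank = 2, seed = 1, max_iter = 300)
  W0 <- cbind(f2$W, 1e-8)
  H0 <- rbind(f2$H, 1e-8)
  f3 <- nmf_factorize(V, rank = 3, W0 = W0, H0 = H0, max_iter = 300)
  expect_lte(f3$recon_error, f2$recon_error * (1 + 1e-8))
})

test_that("silhouette matches brute force, hand-computed and library oracles", {
  # hand-computed 4-point instance: A = {0, 1}, B = {10, 11}.
  # point 0: a = 1, b = (10 + 11)/2 = 10.5, s = 9.5/10.5 ~ 0.9048;
  # point 1: a = 1, b = (9 + 10)/2 = 9.5,  s = 8.5/9.5  ~ 0.8947;
  # outer/inner pairs are symmetric, so the mean is their average.
  s4 <- silhouette_index(c(0, 1, 10, 11), c("A", "A", "B", "B"))
  expect_equal(s4$scores[1], 9.5 / 10.5, tolerance = 1e-12)
  expect_equal(round(s4$scores[1], 4), 0.9048)
  expect_equal(s4$mean, (9.5 / 10.5 + 8.5 / 9.5) / 2, tolerance = 1e-12)

  # interleaved clusters on a line have almost no separation
  si <- silhouette_index(c(0, 1, 0.01, 1.01), c("A", "A", "B", "B"))
  expect_lt(si$mean, 0.2)

  # two repeated-point clusters far apart: a = 0, b > 0 -> s = 1
  sp <- silhouette_index(c(0, 0, 5, 5), c("A", "A", "B", "B"))
  expect_equal(sp$mean, 1)

  # all points identical in both clusters: defined as 0
  sz <- silhouette_index(rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(sz$mean, 0)

  expect_error(silhouette_index(1:4, rep("A", 4)), "two clusters")

  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:50, 1)
    d <- sample(1:4, 1)
    pts <- matrix(rnorm(n * d), n, d)
    labs <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(labs)) < 2) labs[1:2] <- c("A", "B")
    mine <- silhouette_index(pts, labs)
    oracle <- silhouette_bruteforce(pts, labs)
    expect_equal(mine$scores, oracle$scores, tolerance = 1e-12)
    expect_true(all(mine$scores >= -1 - 1e-12 & mine$scores <= 1 + 1e-12))
    # independent library cross-check (cluster's definition coincides
    # when both clusters have >= 2 points)
    if (requireNamespace("cluster", quietly = TRUE) &&
        min(table(labs)) >= 2) {
      cl <- cluster::silhouette(as.integer(factor(labs)), stats::dist(pts))
      expect_equal(sort(mine$scores), sort(as.numeric(cl[, "sil_width"])),
                   tolerance = 1e-10)
    }
  }
})

test_that("pairwise synergy fitting separates distinct postures and flags degenerate pairs", {
  set.seed(21)
  W_true <- matrix(runif(15, 0.2, 1), 5, 3)
  ha <- c(1, 0.1, 0.2); hb <- c(0.1, 1, 0.7)
  A <- matrix(rep(W_true %*% ha, each = 30), 30, 5) # zero-noise envelopes
  B <- matrix(rep(W_true %*% hb, each = 30), 30, 5)
  m <- fit_pairwise_synergy(A, B, "FFS", "EEP", rank = 3, restarts = 3, seed = 1)
  expect_gt(m$silhouette_mean, 0.9)
  expect_false(m$degenerate)
  expect_false(isTRUE(all.equal(m$mean_a, m$mean_b)))

  # identical envelopes: indistinguishable clusters
  md <- fit_pairwise_synergy(A, A, "FFS", "FFP", rank = 3, restarts = 2, seed = 1)
  expect_lt(abs(md$silhouette_mean), 0.05)
  expect_true(md$degenerate)

  expect_error(fit_pairwise_synergy(A, B, rank = 6), "rank")
  expect_error(fit_pairwise_synergy(A, B[, 1:4], rank = 3), "channel")
})

test_that("more restarts never lower the selected silhouette", {
  set.seed(8)
  A <- matrix(abs(rnorm(40 * 5, mean = 1)), 40, 5)
  B <- matrix(abs(rnorm(40 * 5, mean = 1.2)), 40, 5)
  s1 <- fit_pairwise_synergy(A, B, rank = 3, restarts = 1, seed = 5)$silhouette_mean
  s10 <- fit_pairwise_synergy(A, B, rank = 3, restarts = 10, seed = 5)$silhouette_mean
  expect_gte(s10, s1)
})

test_that("frame order within each posture does not affect the fitted model", {
  set.seed(13)
  A <- matrix(abs(rnorm(25 * 5)), 25, 5)
  B <- matrix(abs(rnorm(30 * 5)) * 1.4, 30, 5)
  m1 <- fit_pairwise_synergy(A, B, rank = 3, restarts = 2, seed = 2)
  m2 <- fit_pairwise_synergy(A[sample(25), ], B[sample(30), ],
                             rank = 3, restarts = 2, seed = 2)
  expect_equal(m1$mean_a, m2$mean_a, tolerance = 1e-10)
  expect_equal(m1$mean_b, m2$mean_b, tolerance = 1e-10)
  expect_equal(m1$silhouette_mean, m2$silhouette_mean, tolerance = 1e-10)
})
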