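test_that("round-robin ensembles have one model per unordered pair", {
  clf5 <- fix_clf5()
  expect_s3_class(clf5, "posture_classifier")
  expect_equal(length(clf5$models), 10L)   # 5*(5-1)/2
  expect_false(anyDuplicated(names(clf5$models)) > 0)
  # every unordered pair appears exactly once
  pair_sets <- lapply(clf5$models, function(m) sort(c(m$posture_a, m$posture_b)))
  expect_equal(length(unique(pair_sets)), 10L)

  # two postures: single model
  tr <- fix_train5()
  clf2 <- suppressWarnings(train_round_robin(tr[1:2], restarts = 1, seed = 1))
  expect_equal(length(clf2$models), 1L)

  expect_error(train_round_robin(tr[1]), "two postures")
  bad <- tr
  bad[[1]] <- bad[[1]]$frames[1, , drop = FALSE]
  expect_error(train_round_robin(bad, restarts = 1), "fewer than 2")
})

test_that("activation projection solves non-negative least squares", {
  set.seed(4)
  W <- matrix(runif(15, 0.3, 1), 5, 3)  # full column rank w.h.p.
  model <- structure(list(posture_a = "A", posture_b = "B",
                          nmf = structure(list(W = W), class = "nmf_fit"),
                          mean_a = rep(0, 3), mean_b = rep(1, 3),
                          rank = 3L, degenerate = FALSE),
                     class = "pairwise_synergy")
  h0 <- c(0.5, 0.2, 1.3)
  h <- project_activation(model, as.numeric(W %*% h0))
  expect_equal(h, h0, tolerance = 1e-6)

  expect_equal(project_activation(model, rep(0, 5)), rep(0, 3))
  expect_error(project_activation(model, c(-1, 1, 1, 1, 1)), "negative")
  expect_error(project_activation(model, rep(1, 4)), "length")

  # Monte-Carlo optimality: no random non-negative candidate beats it
  for (rep in 1:5) {
    f <- abs(rnorm(5))
    h <- project_activation(model, f)
    res <- sum((f - W %*% h)^2)
    cand <- matrix(abs(rnorm(3 * 1000)) * 2, 3, 1000)
    res_cand <- colSums((as.numeric(f) - W %*% cand)^2)
    expect_true(all(res <= res_cand + 1e-9))
  }
})

test_that("frames at a posture's training mean win all its pairwise votes", {
  clf <- fix_clf5()
  bank <- fix_bank5()
  n <- length(clf$postures)
  for (p in clf$postures) {
    res <- classify_frame(clf, bank$patterns[, p])
    expect_equal(res$winner, p)
    expect_equal(unname(res$votes[p]), n - 1L)       # every model with p votes p
    expect_equal(sum(res$votes), n * (n - 1L) / 2L)  # one vote per model
  }
})

test_that("duplicate-posture classifiers break ties deterministically and flag ambiguity", {
  tr <- fix_train5()
  # FFS and FFP share identical training envelopes; FES is distinct
  dup <- list(FFS = tr[["FFS"]], FFP = tr[["FFS"]], FES = tr[["FES"]])
  clf <- suppressWarnings(train_round_robin(dup, restarts = 1, seed = 1))
  expect_true(clf$models[["FFS|FFP"]]$degenerate)
  frame <- fix_bank5()$patterns[, "FFS"]
  r1 <- classify_frame(clf, frame)
  expect_true(r1$ambiguous)
  expect_equal(r1$winner, "FFS")  # tie broken toward the earlier posture
  for (i in 1:5) expect_identical(classify_frame(clf, frame)$winner, r1$winner)
})

test_that("noiseless synthetic evaluation is perfect and errors on unknown postures", {
  clf <- fix_clf5()
  ev <- fix_eval5()
  res <- evaluate_classifier(clf, ev, n_iter = 30)
  expect_equal(res$overall, 100)
  expect_true(all(res$per_posture$accuracy == 100))
  expect_true(all(res$per_posture$n_frames <= 30))

  names(ev)[1] <- "EES"  # not trained
  expect_error(evaluate_classifier(clf, ev), "unknown")
})

test_that("relabeling postures permutes predictions consistently", {
  tr <- fix_train5()
  perm <- c(FFS = "EEP", FFP = "EFS", FES = "FFS", EFS = "FES", EEP = "FFP")
  tr_perm <- tr
  names(tr_perm) <- unname(perm[names(tr)])
  clf <- fix_clf5()
  clf_perm <- suppressWarnings(train_round_robin(
    tr_perm[clf$postures], restarts = 2, seed = 1))
  set.seed(31)
  for (rep in 1:5) {
    f <- abs(rnorm(5)) + 0.05
    w1 <- classify_frame(clf, f)$winner
    w2 <- classify_frame(clf_perm, f)$winner
    expect_equal(w2, unname(perm[w1]))
  }
})

test_that("debounce holds the previous consumed posture until k consecutive agreements", {
  w <- c("A", "B", "B", "C", "B", "B", "B")
  expect_equal(synergycube:::debounce_stream(w, 2L),
               c(NA, NA, "B", "B", "B", "B", "B"))
  expect_equal(synergycube:::debounce_stream(w, 3L),
               c(NA, NA, NA, NA, NA, NA, "B"))
})

test_that("classifiers survive a JSON round trip without behavioral change", {
  clf <- fix_clf5()
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, path)
  back <- read_classifier(path)
  expect_equal(back$postures, clf$postures)
  expect_equal(length(back$models), length(clf$models))
  m1 <- clf$models[[3]]; m2 <- back$models[[3]]
  expect_equal(m2$nmf$W, m1$nmf$W, tolerance = 1e-14)
  expect_equal(m2$mean_a, m1$mean_a, tolerance = 1e-14)
  set.seed(77)
  for (rep in 1:5) {
    f <- abs(rnorm(5))
    expect_identical(classify_frame(back, f)$winner,
                     classify_frame(clf, f)$winner)
  }
})

test_that("predict returns per-frame winners and vote matrices", {
  clf <- fix_clf5()
  ev <- fix_eval5()
  env <- ev[[clf$postures[2]]]
  cls <- predict(clf, env)
  expect_type(cls, "character")
  expect_length(cls, nrow(env$frames))
  expect_true(all(cls == clf$postures[2]))
  votes <- predict(clf, env$frames[1:3, ], type = "votes")
  expect_equal(dim(votes), c(3L, 5L))
  expect_true(all(rowSums(votes) == 10))
})

test_that("an all-degenerate classifier refuses to classify", {
  tr <- fix_train5()
  dup <- list(FFS = tr[[1]], FFP = tr[[1]])
  clf <- suppressWarnings(train_round_robin(dup, restarts = 1, seed = 1))
  expect_true(all(vapply(clf$models, function(m) m$degenerate, logical(1))))
  expect_error(classify_frame(clf, rep(1, 5)), "degenerate")
})
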