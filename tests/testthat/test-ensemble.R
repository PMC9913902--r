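test_that("all three base models separate well-separated clusters", {
  d <- gaussian_clusters(20L, 2L, gap = 8)
  model <- train_ensemble(d$X, d$y)
  v <- predict_votes(model, d$X)
  for (col in c("svm", "nb", "knn"))
    expect_gte(mean(v[, col] == d$y), 0.95)
  expect_gte(mean(predict(model, d$X) == d$y), 0.95)
})

test_that("training validates inputs and degenerate cases", {
  d <- gaussian_clusters(10L, 2L)
  expect_error(train_ensemble(d$X, rep(0L, nrow(d$X))), "both classes")
  expect_error(train_ensemble(d$X, d$y[-1]), "mismatch")
  # duplicate of one sample in both classes is admissible
  Xd <- rbind(d$X, d$X[1, ], d$X[1, ])
  yd <- c(d$y, 0L, 1L)
  expect_s3_class(train_ensemble(Xd, yd), "ensemble_model")
  # single feature accepted by all models
  m1 <- train_ensemble(matrix(c(rnorm(10), rnorm(10, 10)), ncol = 1),
                       rep(c(0L, 1L), each = 10L))
  expect_equal(unname(predict(m1, matrix(c(-1, 11), ncol = 1))), c(0L, 1L))
})

test_that("base-vote semantics: NB ties to normal, KNN 2-of-3 majority", {
  # NB with symmetric likelihoods: exactly at the midpoint -> class 0
  m <- rigged_ensemble(svm_cut = 0, nb_cut = 0,
                       knn_X = c(-1, -2, 1), knn_y = c(0, 0, 1))
  v <- predict_votes(m, matrix(0, 1, 1))
  expect_equal(unname(v[1, "nb"]), 0L)
  # KNN query near a {0,0,1} neighbourhood votes 0
  expect_equal(unname(v[1, "knn"]), 0L)
})

test_that("majority vote and score agree over all 8 vote patterns", {
  patterns <- expand.grid(svm = 0:1, nb = 0:1, knn = 0:1)
  # rig base models so one query point realizes each pattern:
  # svm votes x > 0; nb votes x > 2 (midpoint 2); knn stores points so the
  # 3 nearest switch at x > 4. Query x in {-1, 1, 3, 5} realize (0,0,0),
  # (1,0,0), (1,1,0), (1,1,1); remaining patterns checked by symmetry of
  # the voting rule itself below.
  m <- rigged_ensemble(svm_cut = 0, nb_cut = 2,
                       knn_X = c(3.9, 3.9, 3.9, 4.1, 4.1, 4.1),
                       knn_y = c(0, 0, 0, 1, 1, 1))
  q <- matrix(c(-1, 1, 3, 5), ncol = 1)
  v <- predict_votes(m, q)
  expect_equal(unname(v[, "svm"]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(v[, "nb"]), c(0L, 0L, 1L, 1L))
  expect_equal(unname(v[, "knn"]), c(0L, 0L, 0L, 1L))
  expect_equal(unname(predict(m, q)), c(0L, 0L, 1L, 1L))
  expect_equal(unname(vote_score(m, q)), c(0, 1/3, 2/3, 1))
  # voting rule identities over all 8 patterns: majority, permutation
  # invariance, unanimity, and score-threshold equivalence
  maj <- as.integer(rowSums(patterns) >= 2L)
  expect_equal(maj, as.integer(rowSums(patterns[, c(3, 1, 2)]) >= 2L))
  expect_equal(maj[c(1, 8)], c(0L, 1L))            # unanimity
  expect_equal(as.integer(rowSums(patterns) / 3 > 0.5), maj)
  # a base model disagrees with the ensemble only when outvoted 2-to-1
  for (i in seq_len(8)) for (col in 1:3)
    if (patterns[i, col] != maj[i])
      expect_equal(sum(patterns[i, -col] == maj[i]), 2L)
})

test_that("feature width mismatches are rejected", {
  d <- gaussian_clusters(10L, 3L)
  model <- train_ensemble(d$X, d$y)
  expect_error(predict_votes(model, matrix(0, 2, 2)), "features")
})

test_that("standardization switch changes scaling, not the contract", {
  d <- gaussian_clusters(15L, 2L, gap = 6, seed = 3L)
  X <- d$X; X[, 2] <- X[, 2] * 1000  # wildly different scales
  m <- train_ensemble(X, d$y, standardize = TRUE)
  expect_gte(mean(predict(m, X) == d$y), 0.95)
})
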