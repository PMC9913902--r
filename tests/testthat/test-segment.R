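test_that("image_histogram counts every pixel including zeros", {
  h <- image_histogram(matrix(50L, 4, 4))
  expect_equal(h$probs[51], 1)
  expect_equal(sum(h$probs), 1)
  img <- matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4)
  h2 <- image_histogram(img)
  expect_equal(h2$probs[c(1, 256)], c(0.5, 0.5))
  h3 <- image_histogram(generate_phantom(small_spec(), "normal", seed = 1)$image)
  expect_lt(abs(sum(h3$probs) - 1), 1e-12)
})

test_that("tsallis_entropy matches closed forms and the Shannon limit", {
  degenerate <- c(rep(0, 10), 1)
  for (q in c(0.5, 0.8, 2, 4)) expect_equal(tsallis_entropy(degenerate, q), 0)
  expect_equal(tsallis_entropy(rep(0.25, 4), 2), 0.75)
  # uniform closed form (1 - K^(1-q)) / (q - 1)
  for (K in c(2, 8, 32)) {
    expect_equal(tsallis_entropy(rep(1 / K, K), 0.8),
                 (1 - K^0.2) / (0.8 - 1), tolerance = 1e-12)
  }
  expect_error(tsallis_entropy(rep(0.25, 4), 1), "Shannon")
  # q -> 1 limit against Shannon entropy, random distributions
  set.seed(3)
  for (i in 1:10) {
    p <- runif(20); p <- p / sum(p)
    sh <- shannon_entropy(p)
    expect_lt(abs(tsallis_entropy(p, 1 + 1e-4) - sh), 1e-3)
    expect_lt(abs(tsallis_entropy(p, 1 - 1e-4) - sh), 1e-3)
  }
})

test_that("fitness reduces to plain entropy at m = 0 and handles spikes", {
  h <- toy_histogram(16L, seed = 2)
  for (q in c(0.5, 0.8, 2)) {
    expect_equal(segmentation_fitness(h, integer(0), q),
                 tsallis_entropy(h$probs, q))
  }
  # two-spike histogram: separating threshold gives 0, non-separating > 0
  h2 <- spike_histogram(c(10L, 200L))
  for (q in c(0.5, 0.8, 2)) {
    expect_equal(segmentation_fitness(h2, 100L, q), 0)
    expect_gt(segmentation_fitness(h2, 5L, q), 0)
  }
})

test_that("fitness agrees with a direct per-region evaluation", {
  # independent oracle: split probs explicitly, renormalize, combine
  direct <- function(probs, thr, q) {
    edges <- c(0L, thr, 256L)
    S <- vapply(seq_len(length(thr) + 1L), function(j) {
      p <- probs[(edges[j] + 1L):edges[j + 1L]]
      P <- sum(p)
      if (P <= 0) return(0)
      pr <- p[p > 0] / P
      (1 - sum(pr^q)) / (q - 1)
    }, numeric(1))
    sum(S) + (1 - q) * prod(S)
  }
  set.seed(8)
  for (i in 1:20) {
    h <- toy_histogram(32L, seed = 100 + i)
    m <- sample(1:3, 1)
    thr <- sort(sample(1:40, m))
    q <- sample(c(0.5, 0.8, 2, 3), 1)
    expect_equal(segmentation_fitness(h, thr, q), direct(h$probs, thr, q),
                 tolerance = 1e-12)
  }
})

test_that("exhaustive search finds the symmetric optimum and honors ties", {
  # uniform over [0, 15], m = 1, q = 2: symmetric maximum at the midpoint
  h <- spike_histogram(0:15)
  ex <- exhaustive_thresholds(h, 1L, 2)
  expect_equal(ex$thresholds, 8L)
  # bimodal two-spike: any separating threshold ties; smallest returned
  h2 <- spike_histogram(c(3L, 12L))
  # maximizer must keep both spikes in one region (q = 2 penalizes splits
  # of degenerate spikes to zero entropy); global entropy is the optimum
  ex2 <- exhaustive_thresholds(h2, 1L, 2)
  expect_equal(ex2$fitness,
               max(sapply(1:15, function(t) segmentation_fitness(h2, t, 2))))
  expect_equal(exhaustive_thresholds(h, 0L, 2)$fitness,
               tsallis_entropy(h$probs, 2))
  expect_error(exhaustive_thresholds(image_histogram(matrix(200L, 2, 2)), 3L, 2),
               "SSO")
})

test_that("SSO matches the exhaustive oracle on a toy instance", {
  h <- toy_histogram(16L, seed = 5)
  ex <- exhaustive_thresholds(h, 2L, 0.8)
  cfg <- sso_config(bounds = matrix(rep(c(1, 17), each = 2), 2, 2), seed = 3L)
  res <- sso_optimize(function(x)
    segmentation_fitness(h, spidermri:::repair_thresholds(x), 0.8), cfg)
  expect_equal(res$best_fitness, ex$fitness, tolerance = 1e-12)
})

test_that("threshold convention converters invert each other", {
  expect_equal(upper_to_thresholds(c(20L, 80L)), c(21L, 81L))
  expect_equal(thresholds_to_upper(c(21L, 81L)), c(20L, 80L))
  expect_equal(upper_to_thresholds(thresholds_to_upper(c(5L, 99L, 200L))),
               c(5L, 99L, 200L))
})

test_that("apply_thresholds follows the inclusive region convention", {
  img <- matrix(c(0L, 20L, 21L, 80L, 81L, 255L), 2, 3)
  lab <- apply_thresholds(img, upper_to_thresholds(c(20L, 80L)))
  expect_equal(as.vector(lab), c(1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("segment_image labels are monotone in intensity, in [1, C]", {
  s <- generate_phantom(small_spec(), "tumor", seed = 6)
  pp <- preprocess_image(s$image)
  seg <- segment_image(pp$image, C = 5L, q = 0.8,
                       config = sso_config(bounds = matrix(rep(c(1, 254),
                                                               each = 4), 4, 2),
                                           max_iterations = 40L, seed = 2L))
  expect_true(all(seg$labels >= 1L & seg$labels <= 5L))
  # monotone: sort pixels by intensity, labels must be non-decreasing
  ord <- order(as.vector(pp$image))
  expect_true(all(diff(as.vector(seg$labels)[ord]) >= 0L))
  # C = 2 on a two-spike image: pixels of equal intensity share one label,
  # and the SSO fitness equals the exhaustive optimum for this histogram
  img2 <- matrix(rep(c(10L, 200L), 18), 6, 6)
  seg2 <- segment_image(img2, C = 2L, q = 0.8,
                        config = sso_config(bounds = matrix(c(1, 254), 1, 2),
                                            max_iterations = 30L, seed = 1L))
  per_level <- tapply(as.vector(seg2$labels), as.vector(img2),
                      function(v) length(unique(v)))
  expect_true(all(per_level == 1L))
  ex <- exhaustive_thresholds(image_histogram(img2), 1L, 0.8)
  expect_equal(seg2$fitness, ex$fitness, tolerance = 1e-12)
})
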