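test_that("confusion-matrix rates match the closed formulas", {
  cm <- spidermri:::as_confusion_matrix(TP = 345, FN = 1, TN = 365, FP = 9)
  expect_equal(sensitivity(cm), 100 * 345 / 346)
  expect_equal(specificity(cm), 100 * 365 / 374)
  expect_equal(accuracy(cm), 100 * 710 / 720)
  expect_equal(sensitivity(spidermri:::as_confusion_matrix(5, 0, 1, 1)), 100)
  expect_equal(sensitivity(spidermri:::as_confusion_matrix(0, 3, 1, 1)), 0)
  expect_equal(specificity(spidermri:::as_confusion_matrix(1, 1, 7, 0)), 100)
  expect_equal(specificity(spidermri:::as_confusion_matrix(1, 1, 0, 2)), 0)
  expect_error(sensitivity(spidermri:::as_confusion_matrix(0, 0, 1, 1)),
               "positive")
  expect_error(specificity(spidermri:::as_confusion_matrix(1, 1, 0, 0)),
               "negative")
})

test_that("rates agree with brute-force recounts on random predictions", {
  set.seed(11)
  for (i in 1:20) {
    truth <- sample(0:1, 50, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(truth)) < 2) next
    pred <- sample(0:1, 50, replace = TRUE)
    cm <- confusion_matrix(truth, pred)
    expect_equal(cm$TP + cm$FN, sum(truth == 1))
    expect_equal(cm$TN + cm$FP, sum(truth == 0))
    expect_equal(accuracy(cm), 100 * mean(truth == pred))
    expect_equal(sensitivity(cm), 100 * mean(pred[truth == 1] == 1))
    expect_equal(specificity(cm), 100 * mean(pred[truth == 0] == 0))
  }
})

test_that("roc_curve handles perfect, chance and vote-score inputs", {
  y <- c(0, 0, 0, 1, 1)
  perfect <- roc_curve(y, y)
  expect_equal(perfect$auc, 1.0)
  flat <- roc_curve(rep(0.7, 5), y)
  expect_equal(flat$auc, 0.5)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
  # vote scores take 4 levels -> at most 5 distinct ROC points
  set.seed(5)
  scores <- sample(c(0, 1/3, 2/3, 1), 40, replace = TRUE)
  labs <- as.integer(scores + rnorm(40, 0, 0.3) > 0.5)
  if (length(unique(labs)) == 2) {
    r <- roc_curve(scores, labs)
    expect_lte(nrow(r$points), 5L)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(r$points$tpr >= 0 & r$points$tpr <= 1))
  }
})

test_that("repeated holdout on separable features is perfect and exact", {
  d <- gaussian_clusters(12L, 4L, gap = 10, seed = 2L)
  rep1 <- repeated_holdout(d$X, d$y, reps = 3L, seed = 9L,
                           energy_fraction = 0.999)
  expect_equal(unname(rep1$mean_acc[["ensemble"]]), 100)
  expect_equal(unname(rep1$sd_acc[["ensemble"]]), 0)
  expect_equal(rep1$auc, 1.0)
  # reported mean equals the mean of per-repetition accuracies
  expect_equal(rep1$mean_acc, colMeans(rep1$per_rep_acc), tolerance = 1e-12)
  # single repetition reports sd 0 by definition
  rep2 <- repeated_holdout(d$X, d$y, reps = 1L, seed = 9L)
  expect_equal(nrow(rep2$per_rep_acc), 1L)
  expect_equal(unname(rep2$sd_acc[["ensemble"]]), 0)
})

test_that("kfold partitions every sample exactly once", {
  d <- gaussian_clusters(10L, 3L, gap = 10, seed = 4L)
  r <- kfold_cv(d$X, d$y, k = 5L, seed = 1L)
  cm <- r$pooled_cm
  expect_equal(cm$TP + cm$FN, sum(d$y == 1))
  expect_equal(cm$TN + cm$FP, sum(d$y == 0))
  expect_equal(r$accuracy, 100)
  # leave-one-out per class: k equal to the class size still partitions
  r2 <- kfold_cv(d$X, d$y, k = 10L, seed = 1L)
  expect_equal(r2$pooled_cm$TP + r2$pooled_cm$FN, 10)
  expect_error(kfold_cv(d$X, d$y, k = 11L), "class")
})

test_that("stratified splits always keep both classes in train and test", {
  set.seed(6)
  y <- rep(c(0L, 1L), c(30L, 10L))
  for (i in 1:25) {
    tr <- spidermri:::stratified_split(y, 0.7)
    te <- setdiff(seq_along(y), tr)
    expect_setequal(unique(y[tr]), c(0L, 1L))
    expect_setequal(unique(y[te]), c(0L, 1L))
  }
})
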