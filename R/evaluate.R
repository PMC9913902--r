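#' Confusion matrix for binary tumor screening
#'
#' Tumor is the positive class throughout: `TP` counts tumor samples called
#' tumor, `TN` normal samples called normal.
#'
#' @param truth 0/1 (or `normal`/`tumor`) true labels.
#' @param predicted 0/1 predicted labels.
#' @return object of class `confusion_matrix`: list with `TP`, `FN`, `TN`,
#'   `FP`.
#' @export
confusion_matrix <- function(truth, predicted) {
  t <- encode_labels(truth); p <- encode_labels(predicted)
  if (length(t) != length(p)) stop("length mismatch", call. = FALSE)
  structure(list(TP = sum(t == 1L & p == 1L), FN = sum(t == 1L & p == 0L),
                 TN = sum(t == 0L & p == 0L), FP = sum(t == 0L & p == 1L)),
            class = "confusion_matrix")
}

as_confusion_matrix <- function(TP, FN, TN, FP) {
  if (any(c(TP, FN, TN, FP) < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  # 2x2 layout, index 1 = normal, index 2 = tumor
  m <- matrix(c(x$TN, x$FN, x$FP, x$TP), 2, 2,
              dimnames = list(true = c("normal", "tumor"),
                              predicted = c("normal", "tumor")))
  print(m)
  invisible(x)
}

#' Sensitivity (true-positive rate), percent
#'
#' @param cm a [confusion_matrix()].
#' @return `100 * TP / (TP + FN)`.
#' @export
sensitivity <- function(cm) {
  if (cm$TP + cm$FN == 0) stop("no positive (tumor) samples", call. = FALSE)
  100 * cm$TP / (cm$TP + cm$FN)
}

#' Specificity (true-negative rate), percent
#'
#' @param cm a [confusion_matrix()].
#' @return `100 * TN / (TN + FP)`.
#' @export
specificity <- function(cm) {
  if (cm$TN + cm$FP == 0) stop("no negative (normal) samples", call. = FALSE)
  100 * cm$TN / (cm$TN + cm$FP)
}

#' Overall accuracy, percent
#'
#' @param cm a [confusion_matrix()].
#' @return `100 * (TP + TN) / total`.
#' @export
accuracy <- function(cm) {
  n <- cm$TP + cm$FN + cm$TN + cm$FP
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  100 * (cm$TP + cm$TN) / n
}

#' ROC curve and AUC from scores
#'
#' Standard threshold sweep over the unique score values (ties grouped at a
#' single threshold), trapezoidal AUC. Higher scores mean "more tumor-like".
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or `normal`/`tumor`) true labels; both classes
#'   required.
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- encode_labels(labels)
  if (length(unique(y)) < 2L)
    stop("ROC needs both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  np <- sum(y == 1L); nn <- sum(y == 0L)
  # last index of each tie group: one ROC point per distinct score
  idx <- which(!duplicated(rev(s))); idx <- length(s) + 1L - rev(idx)
  tp <- cumsum(y == 1L)[idx]; fp <- cumsum(y == 0L)[idx]
  pts <- data.frame(fpr = c(0, fp / nn, 1), tpr = c(0, tp / np, 1))
  pts <- unique(pts)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

stratified_split <- function(y, train_frac, rng_unused = NULL) {
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- round(train_frac * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# One train/test pass of features -> ensemble, shared by both protocols.
# X is the P x S segmented-and-flattened data matrix; the SVD feature model
# is fit on the training rows only.
fit_predict_split <- function(X, y, train, test, energy_fraction, standardize) {
  fm <- build_feature_model(X[train, , drop = FALSE], energy_fraction)
  F_tr <- project_features(fm, X[train, , drop = FALSE])
  F_te <- project_features(fm, X[test, , drop = FALSE])
  model <- train_ensemble(F_tr, y[train], standardize = standardize)
  votes <- predict_votes(model, F_te)
  list(votes = votes, ens = as.integer(rowSums(votes) >= 2L),
       score = rowSums(votes) / 3, rank = fm$rank)
}

summarize_eval <- function(acc_mat, pooled, truth_all, score_all) {
  cm <- as_confusion_matrix(TP = sum(truth_all == 1L & pooled == 1L),
                            FN = sum(truth_all == 1L & pooled == 0L),
                            TN = sum(truth_all == 0L & pooled == 0L),
                            FP = sum(truth_all == 0L & pooled == 1L))
  roc <- roc_curve(score_all, truth_all)
  list(per_rep_acc = acc_mat,
       mean_acc = colMeans(acc_mat),
       min_acc = apply(acc_mat, 2, min),
       max_acc = apply(acc_mat, 2, max),
       # a single repetition has no spread: report 0, not NA
       sd_acc = ifelse(is.na(apply(acc_mat, 2, sd)), 0,
                       apply(acc_mat, 2, sd)),
       pooled_cm = cm,
       sensitivity = sensitivity(cm),
       specificity = specificity(cm),
       accuracy = accuracy(cm),
       roc_points = roc$points, auc = roc$auc)
}

#' Repeated stratified holdout evaluation of the full classifier stage
#'
#' Per repetition: stratified train/test split, SVD feature model fit on the
#' training rows only, the three base classifiers and the voting ensemble
#' trained and evaluated on identical splits. Accuracies are recorded per
#' repetition and the confusion matrix is pooled over all repetitions' test
#' predictions.
#'
#' @param X `P x S` data matrix of flattened segmented images.
#' @param labels length-P 0/1 (or `normal`/`tumor`) labels.
#' @param reps number of repetitions, default 20.
#' @param train_frac training fraction, default 0.7.
#' @param seed RNG seed.
#' @param energy_fraction SVD energy rule threshold, default 0.99.
#' @param standardize z-score features, default `FALSE`.
#' @return object of class `eval_report`; accuracy columns cover `svm`,
#'   `nb`, `knn` and `ensemble`.
#' @export
repeated_holdout <- function(X, labels, reps = 20L, train_frac = 0.7,
                             seed = 1L, energy_fraction = 0.99,
                             standardize = FALSE) {
  X <- as.matrix(X); y <- encode_labels(labels)
  if (min(table(y)) < 2L) stop("need >= 2 samples per class", call. = FALSE)
  set.seed(seed)
  models <- c("svm", "nb", "knn", "ensemble")
  acc <- matrix(NA_real_, reps, 4L, dimnames = list(NULL, models))
  pooled <- truth_all <- score_all <- numeric(0)
  for (r in seq_len(reps)) {
    train <- stratified_split(y, train_frac)
    test <- setdiff(seq_along(y), train)
    fp <- fit_predict_split(X, y, train, test, energy_fraction, standardize)
    hit <- cbind(fp$votes == y[test], ensemble = fp$ens == y[test])
    acc[r, ] <- 100 * colMeans(hit)
    pooled <- c(pooled, fp$ens); truth_all <- c(truth_all, y[test])
    score_all <- c(score_all, fp$score)
  }
  rep <- summarize_eval(acc, pooled, truth_all, score_all)
  rep$protocol <- list(mode = "holdout", reps = reps, train_frac = train_frac,
                       seed = seed)
  structure(rep, class = "eval_report")
}

#' Stratified k-fold cross-validation of the classifier stage
#'
#' @param X `P x S` data matrix of flattened segmented images.
#' @param labels length-P labels.
#' @param k number of folds, default 10; must not exceed the smaller class.
#' @param seed RNG seed.
#' @param energy_fraction SVD energy rule threshold, default 0.99.
#' @param standardize z-score features, default `FALSE`.
#' @return object of class `eval_report` (per-fold accuracies in
#'   `per_rep_acc`).
#' @export
kfold_cv <- function(X, labels, k = 10L, seed = 1L, energy_fraction = 0.99,
                     standardize = FALSE) {
  X <- as.matrix(X); y <- encode_labels(labels)
  if (k > min(table(y)))
    stop("k exceeds the size of the smaller class", call. = FALSE)
  set.seed(seed)
  fold <- stratified_folds(y, k)
  models <- c("svm", "nb", "knn", "ensemble")
  acc <- matrix(NA_real_, k, 4L, dimnames = list(NULL, models))
  pooled <- truth_all <- score_all <- numeric(0)
  for (f in seq_len(k)) {
    test <- which(fold == f); train <- which(fold != f)
    fp <- fit_predict_split(X, y, train, test, energy_fraction, standardize)
    hit <- cbind(fp$votes == y[test], ensemble = fp$ens == y[test])
    acc[f, ] <- 100 * colMeans(hit)
    pooled <- c(pooled, fp$ens); truth_all <- c(truth_all, y[test])
    score_all <- c(score_all, fp$score)
  }
  rep <- summarize_eval(acc, pooled, truth_all, score_all)
  rep$protocol <- list(mode = "cv", k = k, seed = seed)
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%s)\n", x$protocol$mode))
  tab <- rbind(mean = x$mean_acc, min = x$min_acc, max = x$max_acc,
               sd = x$sd_acc)
  print(round(tab, 4))
  cat(sprintf("pooled: accuracy %.4f%%, sensitivity %.4f%%, specificity %.4f%%, AUC %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  print(x$pooled_cm)
  invisible(x)
}
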