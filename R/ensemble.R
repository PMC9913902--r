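# Linear soft-margin SVM fit by solving the dual QP with quadprog:
#   max sum(a) - 1/2 a' (yy' XX') a,  0 <= a <= C,  sum(a y) = 0.
# A small ridge keeps the Gram matrix positive definite. Deterministic.
svm_fit_linear <- function(X, y01, cost = 1.0) {
  y <- ifelse(y01 == 1L, 1, -1)
  n <- nrow(X)
  K <- tcrossprod(X)
  D <- K * tcrossprod(y)
  diag(D) <- diag(D) + max(1e-8, 1e-10 * mean(diag(K)))
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A,
                            bvec = b0, meq = 1)
  alpha <- pmin(cost, pmax(0, sol$solution))
  w <- drop(crossprod(X, alpha * y))
  margin_sv <- which(alpha > 1e-6 * cost & alpha < cost * (1 - 1e-6))
  if (!length(margin_sv)) margin_sv <- which(alpha > 1e-6 * cost)
  b <- mean(y[margin_sv] - X[margin_sv, , drop = FALSE] %*% w)
  list(w = w, b = b, cost = cost)
}

svm_decision <- function(fit, X) drop(X %*% fit$w + fit$b)

# Gaussian naive Bayes: per-class, per-feature normal likelihoods with a
# variance floor; prediction is the maximum-posterior class, ties to 0.
nb_fit_gaussian <- function(X, y01, var_floor = 1e-9) {
  fit <- lapply(c(0L, 1L), function(cl) {
    Xc <- X[y01 == cl, , drop = FALSE]
    list(mean = colMeans(Xc),
         var = pmax(apply(Xc, 2, function(v) mean((v - mean(v))^2)), var_floor),
         prior = nrow(Xc) / nrow(X))
  })
  names(fit) <- c("0", "1")
  fit
}

nb_log_posterior <- function(fit, X, class) {
  p <- fit[[as.character(class)]]
  ll <- -0.5 * sweep(sweep(X, 2, p$mean)^2, 2, p$var, "/") -
    0.5 * matrix(log(2 * pi * p$var), nrow(X), ncol(X), byrow = TRUE)
  rowSums(ll) + log(p$prior)
}

# 3-NN with Euclidean distance; distance ties prefer the normal-class
# neighbour, vote ties cannot occur with k = 3 and two classes.
knn_predict <- function(train_X, train_y, X, k = 3L) {
  apply(X, 1, function(x) {
    d <- sqrt(colSums((t(train_X) - x)^2))
    nn <- order(d, train_y)[seq_len(k)]
    as.integer(sum(train_y[nn]) * 2L > k)
  })
}

#' Train the three-classifier voting ensemble
#'
#' Fits a linear-kernel soft-margin SVM, a Gaussian naive Bayes, and a
#' 3-nearest-neighbour classifier on the same labelled feature matrix.
#' Labels are 0 = normal, 1 = tumor.
#'
#' @param features numeric `P x N` matrix of feature vectors.
#' @param labels integer/numeric vector of 0/1 labels (or a factor /
#'   character vector with levels `normal`, `tumor`).
#' @param standardize z-score features using training statistics before the
#'   SVM and KNN? Default `FALSE`.
#' @param cost SVM regularization constant, default 1.
#' @return object of class `ensemble_model`.
#' @export
train_ensemble <- function(features, labels, standardize = FALSE, cost = 1.0) {
  X <- as.matrix(features)
  y <- encode_labels(labels)
  if (length(y) != nrow(X)) stop("labels/features length mismatch", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  scale_center <- scale_sd <- NULL
  Xs <- X
  if (standardize) {
    scale_center <- colMeans(X)
    scale_sd <- pmax(apply(X, 2, sd), 1e-12)
    Xs <- sweep(sweep(X, 2, scale_center), 2, scale_sd, "/")
  }
  structure(list(svm = svm_fit_linear(Xs, y, cost),
                 nb = nb_fit_gaussian(X, y),
                 knn = list(X = Xs, y = y, k = 3L),
                 standardize = standardize,
                 scale_center = scale_center, scale_sd = scale_sd,
                 n_features = ncol(X)),
            class = "ensemble_model")
}

encode_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("normal", "tumor"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    return(as.integer(labels == "tumor"))
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  as.integer(labels)
}

#' Per-sample votes of the three base classifiers
#'
#' @param model an [train_ensemble()] model.
#' @param features matrix with the training feature width.
#' @return integer matrix with columns `svm`, `nb`, `knn` of 0/1 votes.
#' @export
predict_votes <- function(model, features) {
  stopifnot(inherits(model, "ensemble_model"))
  X <- as.matrix(features)
  if (is.vector(features)) X <- matrix(features, nrow = 1L)
  if (ncol(X) != model$n_features)
    stop(sprintf("expected %d features, got %d", model$n_features, ncol(X)),
         call. = FALSE)
  Xs <- X
  if (model$standardize)
    Xs <- sweep(sweep(X, 2, model$scale_center), 2, model$scale_sd, "/")
  svm_v <- as.integer(svm_decision(model$svm, Xs) > 0)
  # posterior ties break toward class 0 (normal)
  nb_v <- as.integer(nb_log_posterior(model$nb, X, 1L) >
                       nb_log_posterior(model$nb, X, 0L))
  knn_v <- knn_predict(model$knn$X, model$knn$y, Xs, model$knn$k)
  cbind(svm = svm_v, nb = nb_v, knn = knn_v)
}

#' Majority-vote ensemble prediction
#'
#' With two classes and three voters a strict majority always exists.
#'
#' @param object an `ensemble_model`.
#' @param features feature matrix.
#' @param ... unused.
#' @return integer vector of 0/1 labels.
#' @export
predict.ensemble_model <- function(object, features, ...) {
  v <- predict_votes(object, features)
  as.integer(rowSums(v) >= 2L)
}

#' Fraction of tumor votes, for ROC analysis
#'
#' @param model an `ensemble_model`.
#' @param features feature matrix.
#' @return numeric vector in `{0, 1/3, 2/3, 1}`; thresholding at 0.5
#'   reproduces [predict.ensemble_model()].
#' @export
vote_score <- function(model, features) {
  rowSums(predict_votes(model, features)) / 3
}
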