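# Shared fixtures, all built in code.

# Small, fast phantom spec for unit tests (full-size spec only in acceptance).
small_spec <- function(seed = 1L, noise_sd = 3, ...) {
  phantom_spec(image_size = 64L, n_normal = 4L, n_tumor = 4L,
               noise_sd = noise_sd, seed = seed, ...)
}

# Noise-free variant: every pixel exactly at its region mean.
noise_free_spec <- function(seed = 1L, image_size = 64L, ...) {
  phantom_spec(image_size = image_size,
               intensity_sds = c(background = 0, skull = 0, outer_tissue = 0,
                                 inner_tissue = 0, tumor = 0),
               noise_sd = 0, seed = seed, ...)
}

# Sparse toy histogram over the first `levels` intensities.
toy_histogram <- function(levels = 16L, seed = 1L) {
  set.seed(seed)
  p <- rep(0, 256)
  sup <- sample.int(levels, max(4L, levels %/% 2L))
  p[sup] <- runif(length(sup))
  list(probs = p / sum(p), n = 1000L)
}

# Spike histogram: probability mass at the given intensities.
spike_histogram <- function(intensities, masses = NULL) {
  p <- rep(0, 256)
  if (is.null(masses)) masses <- rep(1, length(intensities))
  p[intensities + 1L] <- masses
  list(probs = p / sum(p), n = 1000L)
}

# Two well-separated Gaussian clusters in n_dim dimensions.
gaussian_clusters <- function(n_per_class = 20L, n_dim = 2L, gap = 8,
                              seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * n_dim), ncol = n_dim),
             matrix(rnorm(n_per_class * n_dim, mean = gap), ncol = n_dim))
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

# Hand-built ensemble model whose three base classifiers are fully
# controlled: 1-D feature x; svm votes x > a, nb votes x > b (via two
# unit-variance Gaussians with midpoint b), knn votes by stored neighbours.
rigged_ensemble <- function(svm_cut, nb_cut, knn_X, knn_y) {
  structure(list(
    svm = list(w = 1, b = -svm_cut, cost = 1),
    nb = list("0" = list(mean = nb_cut - 1, var = 1, prior = 0.5),
              "1" = list(mean = nb_cut + 1, var = 1, prior = 0.5)),
    knn = list(X = matrix(knn_X, ncol = 1), y = as.integer(knn_y), k = 3L),
    standardize = FALSE, scale_center = NULL, scale_sd = NULL,
    n_features = 1L), class = "ensemble_model")
}
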