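#' Intensity histogram of an image as a probability vector
#'
#' All pixels are counted, including the zeros left by background removal:
#' the background forms its own intensity region in the segmentation.
#'
#' @param image integer matrix in `[0, 255]`.
#' @return object of class `gray_histogram`: list with `probs` (length 256,
#'   sums to 1) and `n` (pixel count).
#' @export
image_histogram <- function(image) {
  image <- as_gray_image(image)
  counts <- tabulate(as.vector(image) + 1L, nbins = 256L)
  structure(list(probs = counts / length(image), n = length(image)),
            class = "gray_histogram")
}

#' Tsallis entropy of a discrete distribution
#'
#' `S_q = (1 - sum(p_i^q)) / (q - 1)`; zero-probability entries contribute
#' nothing. Recovers Shannon entropy (natural log) as `q -> 1`.
#'
#' @param probs non-negative vector summing to 1.
#' @param q entropic index, `q > 0`, `q != 1`.
#' @return the entropy value.
#' @export
tsallis_entropy <- function(probs, q) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("probs must be non-negative and sum to 1", call. = FALSE)
  if (q <= 0) stop("entropic index q must be positive", call. = FALSE)
  if (q == 1)
    stop("q = 1 is the Shannon limit; use shannon_entropy()", call. = FALSE)
  p <- probs[probs > 0]
  (1 - sum(p^q)) / (q - 1)
}

#' Shannon entropy (natural log) of a discrete distribution
#'
#' @param probs non-negative vector summing to 1.
#' @return `-sum(p_i * log(p_i))` over positive entries.
#' @export
shannon_entropy <- function(probs) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("probs must be non-negative and sum to 1", call. = FALSE)
  p <- probs[probs > 0]
  -sum(p * log(p))
}

validate_thresholds <- function(thresholds) {
  thresholds <- as.integer(thresholds)
  if (length(thresholds)) {
    if (any(thresholds < 1L | thresholds > 255L))
      stop("thresholds must lie in [1, 255]", call. = FALSE)
    if (any(diff(thresholds) <= 0L))
      stop("thresholds must be strictly increasing", call. = FALSE)
  }
  thresholds
}

#' Multilevel Tsallis fitness of a threshold vector
#'
#' Thresholds `t_1 < ... < t_m` (stored in the lower-inclusive convention:
#' region j is `[t_{j-1}, t_j - 1]`, region 1 starting at 0 and region C
#' ending at 255) partition the intensity axis into `C = m + 1` regions.
#' Each non-empty region contributes the Tsallis entropy of its renormalized
#' intensity distribution; empty regions contribute zero. For `C >= 2` the
#' per-region entropies combine pseudo-additively,
#' `sum_j S_j + (1 - q) * prod_j S_j`; for `m = 0` the fitness is the plain
#' Tsallis entropy of the histogram.
#'
#' @param hist a [image_histogram()] result (or list with `$probs`).
#' @param thresholds strictly increasing integers in `[1, 255]` (may be
#'   empty).
#' @param q entropic index, `q > 0`, `q != 1`.
#' @return the fitness value to be maximized.
#' @export
segmentation_fitness <- function(hist, thresholds, q) {
  probs <- hist$probs
  thresholds <- validate_thresholds(thresholds)
  if (length(thresholds) == 0L) return(tsallis_entropy(probs, q))
  if (q <= 0 || q == 1) stop("q must be positive and != 1", call. = FALSE)
  cp <- cumsum(probs)
  cpq <- cumsum(probs^q)
  # region j spans intensity [lo_j, hi_j]; +1 converts to vector index
  lo <- c(0L, thresholds); hi <- c(thresholds - 1L, 255L)
  P <- cp[hi + 1L] - c(0, cp[lo[-1L]])
  Pq <- cpq[hi + 1L] - c(0, cpq[lo[-1L]])
  S <- ifelse(P > 0, (1 - Pq / P^q) / (q - 1), 0)
  sum(S) + (1 - q) * prod(S)
}

#' Globally optimal thresholds by exhaustive enumeration
#'
#' Brute-force oracle over all strictly increasing threshold vectors drawn
#' from `[1, max_level]`, where `max_level` is capped at the top occupied
#' intensity plus one (thresholds above the support cannot change the
#' partition). Ties break toward the lexicographically smallest vector.
#'
#' @param hist a [image_histogram()] result.
#' @param m number of thresholds, `m >= 0`.
#' @param q entropic index.
#' @param max_candidates guard on `choose(n_candidates, m)` (default 2e5);
#'   exceeding it raises an error suggesting the SSO search.
#' @return list with `thresholds` (integer vector, internal convention) and
#'   `fitness`.
#' @export
exhaustive_thresholds <- function(hist, m, q, max_candidates = 2e5) {
  m <- as.integer(m)
  if (m == 0L)
    return(list(thresholds = integer(0),
                fitness = tsallis_entropy(hist$probs, q)))
  support_top <- max(which(hist$probs > 0)) - 1L   # highest occupied level
  # allow up to m thresholds above the support so trailing-empty-region
  # partitions are representable too
  cand <- seq_len(min(255L, support_top + m))
  if (choose(length(cand), m) > max_candidates)
    stop(sprintf(paste0("exhaustive enumeration over choose(%d, %d) threshold",
                        " vectors exceeds the guard; use the SSO search"),
                 length(cand), m), call. = FALSE)
  combos <- combn(cand, m)
  best_f <- -Inf; best_t <- NULL
  for (k in seq_len(ncol(combos))) {
    f <- segmentation_fitness(hist, combos[, k], q)
    if (f > best_f + 1e-15) { best_f <- f; best_t <- combos[, k] }
  }
  list(thresholds = as.integer(best_t), fitness = best_f)
}

# Repair a continuous SSO position into a valid threshold vector: round,
# clamp, sort, and bump duplicates upward (spilling over 255 is re-clamped
# by dropping, which shrinks the effective region count for that candidate).
repair_thresholds <- function(x, lo = 1L, hi = 255L) {
  t <- sort(pmin(hi, pmax(lo, round(x))))
  if (length(t) > 1L)
    for (i in 2:length(t)) if (t[i] <= t[i - 1L]) t[i] <- t[i - 1L] + 1L
  as.integer(t[t <= hi])
}

#' Convert internal thresholds to the inclusive upper-bound convention
#'
#' Internally region j ends at `t_j - 1`; user-facing solution vectors list
#' the inclusive upper bound of each region instead (a first entry of 20
#' means intensities 0..20 fall in region 1).
#'
#' @param thresholds internal (lower-inclusive) threshold vector.
#' @return inclusive upper bounds, same length.
#' @export
thresholds_to_upper <- function(thresholds) validate_thresholds(thresholds) - 1L

#' Convert inclusive upper bounds to internal thresholds
#'
#' @param upper inclusive region upper bounds (e.g. `c(20, 80)`).
#' @return internal threshold vector (`c(21, 81)` for the example).
#' @export
upper_to_thresholds <- function(upper) validate_thresholds(upper + 1L)

#' Segment an image by SSO-optimized multilevel Tsallis thresholding
#'
#' Optimizes `m = C - 1` thresholds over the image histogram with the
#' social spider optimizer, then labels every pixel with its region index
#' in `[1, C]` (label is non-decreasing in intensity; region 1 holds the
#' background).
#'
#' @param image integer matrix in `[0, 255]` (typically preprocessed).
#' @param C number of regions, `C >= 2`; default 5.
#' @param q entropic index, default 0.8.
#' @param config an [sso_config()]; bounds default to `[1, 254]` per
#'   dimension when omitted.
#' @return object of class `segmented_image`: list with `labels` (integer
#'   matrix in `[1, C]`), `thresholds` (internal convention), `upper`
#'   (inclusive upper bounds), `fitness`, `fitness_trace`.
#' @export
segment_image <- function(image, C = 5L, q = 0.8, config = NULL) {
  image <- as_gray_image(image)
  C <- as.integer(C)
  if (C < 2L) stop("C must be >= 2", call. = FALSE)
  m <- C - 1L
  if (is.null(config))
    config <- sso_config(bounds = matrix(rep(c(1, 254), each = m), m, 2L))
  if (nrow(config$bounds) != m)
    stop("sso_config bounds must have one row per threshold", call. = FALSE)
  hist <- image_histogram(image)
  obj <- function(x) segmentation_fitness(hist, repair_thresholds(x), q)
  res <- sso_optimize(obj, config)
  thr <- repair_thresholds(res$best_position)
  labels <- apply_thresholds(image, thr)
  structure(list(labels = labels, thresholds = thr,
                 upper = thresholds_to_upper(thr),
                 fitness = res$best_fitness,
                 fitness_trace = res$fitness_trace,
                 C = length(thr) + 1L, q = q),
            class = "segmented_image")
}

#' Label pixels by a threshold vector
#'
#' @param image integer matrix in `[0, 255]`.
#' @param thresholds internal-convention thresholds `t_1 < ... < t_m`.
#' @return integer matrix of region labels in `[1, m + 1]`.
#' @export
apply_thresholds <- function(image, thresholds) {
  image <- as_gray_image(image)
  thresholds <- validate_thresholds(thresholds)
  lab <- matrix(findInterval(image, thresholds) + 1L,
                nrow(image), ncol(image))
  storage.mode(lab) <- "integer"
  lab
}
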