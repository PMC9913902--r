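#' Configuration for the social spider optimizer
#'
#' @param bounds two-column matrix (or 2-vector recycled) of per-dimension
#'   `(low, high)` search bounds.
#' @param population_size number of spiders, default 25.
#' @param max_iterations fixed iteration budget, default 100.
#' @param r_a vibration attenuation rate, positive, default 1.
#' @param p_c probability of resampling a spider's dimension mask each
#'   iteration, default 0.7.
#' @param p_m probability that a resampled mask bit is 1, default 0.1.
#' @param seed RNG seed, default 1.
#' @return an object of class `sso_config`.
#' @export
sso_config <- function(bounds, population_size = 25L, max_iterations = 100L,
                       r_a = 1.0, p_c = 0.7, p_m = 0.1, seed = 1L) {
  if (is.vector(bounds) && length(bounds) == 2L) bounds <- matrix(bounds, 1L, 2L)
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be a matrix of (low, high) pairs with low < high", call. = FALSE)
  if (population_size < 2L) stop("population_size must be >= 2", call. = FALSE)
  if (p_c < 0 || p_c > 1 || p_m < 0 || p_m > 1)
    stop("p_c and p_m must lie in [0, 1]", call. = FALSE)
  if (r_a <= 0) stop("r_a must be positive", call. = FALSE)
  structure(list(bounds = bounds, population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations), r_a = r_a,
                 p_c = p_c, p_m = p_m, seed = as.integer(seed)),
            class = "sso_config")
}

#' Distance attenuation of a vibration
#'
#' Intensity decays exponentially with inter-spider distance, scaled by the
#' population spread `sigma_bar` and the attenuation rate `r_a`:
#' `intensity * exp(-distance / (sigma_bar * r_a))`.
#'
#' @param intensity source intensity, >= 0.
#' @param distance distance from source, >= 0.
#' @param sigma_bar mean per-dimension standard deviation of positions, > 0.
#' @param r_a attenuation rate, > 0.
#' @return attenuated intensity.
#' @export
vibration_attenuate <- function(intensity, distance, sigma_bar, r_a) {
  stopifnot(all(intensity >= 0), all(distance >= 0), sigma_bar > 0, r_a > 0)
  intensity * exp(-distance / (sigma_bar * r_a))
}

#' Maximize an objective with social spider optimization
#'
#' Candidate solutions ("spiders") sit on a web of positions inside the
#' bounds. Each iteration every spider emits a vibration whose intensity
#' increases with its fitness (`log(1/(C - f) + 1)` with `C` held below all
#' observed fitness values); vibrations attenuate exponentially with
#' Euclidean distance; every spider picks the strongest received vibration,
#' keeps it only if it beats the vibration stored from previous iterations,
#' and random-walks toward its stored target with a per-dimension binary
#' mask that occasionally substitutes a random spider's coordinate.
#' Positions are clamped to the bounds; the best-ever position is returned.
#'
#' @param objective function mapping a numeric vector to a finite scalar to
#'   be maximized.
#' @param config an [sso_config()].
#' @return object of class `sso_result`: list with `best_position`,
#'   `best_fitness`, and the non-decreasing per-iteration `fitness_trace`.
#' @export
sso_optimize <- function(objective, config) {
  stopifnot(inherits(config, "sso_config"))
  set.seed(config$seed)
  lo <- config$bounds[, 1]; hi <- config$bounds[, 2]
  d <- length(lo); np <- config$population_size

  eval_fit <- function(x) {
    f <- objective(x)
    if (!is.finite(f))
      stop("objective returned a non-finite value at position (",
           paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
    f
  }

  pos <- matrix(runif(np * d, rep(lo, each = np), rep(hi, each = np)), np, d)
  prev_pos <- pos
  fit <- apply(pos, 1, eval_fit)
  # stored target vibration: position + intensity (starts at zero intensity)
  tgt_pos <- pos
  tgt_int <- rep(0, np)
  mask <- matrix(0L, np, d)
  inactive <- rep(0L, np)

  best_i <- which.max(fit)
  best_pos <- pos[best_i, ]; best_fit <- fit[best_i]
  trace <- numeric(config$max_iterations)

  for (it in seq_len(config$max_iterations)) {
    # intensity increases with (maximized) fitness; C sits above all current
    # values so 1/(C - f) is finite and largest for the fittest spider
    Cshift <- max(fit) + 1
    inten <- log(1 / (Cshift - fit) + 1)
    sig <- mean(apply(pos, 2, sd))
    if (!is.finite(sig) || sig <= 0) sig <- 1e-9
    dist <- as.matrix(stats::dist(pos))
    recv <- vibration_attenuate(matrix(inten, np, np, byrow = TRUE), dist,
                                sig, config$r_a)
    sel <- max.col(recv, ties.method = "first")
    v_best_int <- recv[cbind(seq_len(np), sel)]
    switch_to <- v_best_int > tgt_int
    tgt_pos[switch_to, ] <- pos[sel[switch_to], , drop = FALSE]
    tgt_int[switch_to] <- v_best_int[switch_to]
    inactive <- ifelse(switch_to, 0L, inactive + 1L)

    resample <- runif(np) < config$p_c
    if (any(resample))
      mask[resample, ] <- (matrix(runif(sum(resample) * d), ncol = d) <
                             config$p_m) * 1L
    # followed position: target coordinates where mask = 0, a random
    # spider's coordinates where mask = 1
    rnd_idx <- matrix(sample.int(np, np * d, replace = TRUE), np, d)
    rnd_coord <- matrix(pos[cbind(as.vector(rnd_idx), rep(seq_len(d), each = np))], np, d)
    p_fo <- tgt_pos * (1 - mask) + rnd_coord * mask

    inertia <- matrix(runif(np), np, 1)
    step_r <- matrix(runif(np * d), np, d)
    new_pos <- pos + (pos - prev_pos) * inertia[, rep(1, d)] +
      (p_fo - pos) * step_r
    new_pos <- pmin(pmax(new_pos, rep(lo, each = np)), rep(hi, each = np))
    prev_pos <- pos
    pos <- new_pos
    fit <- apply(pos, 1, eval_fit)

    i <- which.max(fit)
    if (fit[i] > best_fit) { best_fit <- fit[i]; best_pos <- pos[i, ] }
    trace[it] <- best_fit
  }

  structure(list(best_position = best_pos, best_fitness = best_fit,
                 fitness_trace = trace),
            class = "sso_result")
}
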