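#' Build an SVD feature model from a sample-by-pixel matrix
#'
#' Rows are samples (flattened segmented images, region labels as reals),
#' columns are pixels. The thin SVD `R = U D V'` is computed and the rank
#' `N` is the smallest k whose leading squared singular values reach
#' `energy_fraction` of the total squared spectrum — the default 0.99
#' discards the ~1% of spectral energy attributed to noise.
#'
#' @param data numeric matrix, `P >= 2` rows, no missing values.
#' @param energy_fraction energy threshold in (0, 1], default 0.99.
#' @return object of class `feature_model`: list with `right_basis`
#'   (`S x N`), `singular_values`, `rank` (N), `energy_fraction`, `S`.
#' @export
build_feature_model <- function(data, energy_fraction = 0.99) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("data contains missing values", call. = FALSE)
  if (nrow(data) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (energy_fraction <= 0 || energy_fraction > 1)
    stop("energy_fraction must lie in (0, 1]", call. = FALSE)
  if (all(data == 0)) stop("degenerate all-zero data matrix", call. = FALSE)
  dec <- svd(data)
  N <- select_rank(dec$d, energy_fraction)
  structure(list(right_basis = dec$v[, seq_len(N), drop = FALSE],
                 singular_values = dec$d,
                 rank = N,
                 energy_fraction = energy_fraction,
                 S = ncol(data)),
            class = "feature_model")
}

#' Rank selected by the cumulative energy rule
#'
#' @param singular_values non-increasing non-negative vector.
#' @param energy_fraction threshold in (0, 1].
#' @return smallest `k` with `sum(d[1:k]^2) >= energy_fraction * sum(d^2)`.
#' @export
select_rank <- function(singular_values, energy_fraction = 0.99) {
  if (any(diff(singular_values) > 1e-12))
    stop("singular values must be non-increasing", call. = FALSE)
  e <- singular_values^2
  which(cumsum(e) >= energy_fraction * sum(e) - 1e-12)[1]
}

#' Project flattened images into the feature space
#'
#' Features are the coordinates in the truncated right-singular basis,
#' `x %*% V_N`; for a training row this reproduces the corresponding row of
#' `U_N D_N`. The basis is fit on training samples only, so test images are
#' embedded without leakage.
#'
#' @param model a [build_feature_model()] result.
#' @param x numeric vector of length `S`, or a matrix with `S` columns.
#' @return feature matrix (`length-N` vector input gives a 1-row matrix).
#' @export
project_features <- function(model, x) {
  stopifnot(inherits(model, "feature_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$S)
    stop(sprintf("expected vectors of length %d, got %d", model$S, ncol(x)),
         call. = FALSE)
  x %*% model$right_basis
}

#' Feature indices in order of importance
#'
#' Columns of the feature matrix are already ordered by singular value
#' (largest first, ties keeping their original column order), so this is
#' `1:N`; exposed for reporting.
#'
#' @param model a [build_feature_model()] result.
#' @return integer vector `1:N`.
#' @export
rank_features <- function(model) {
  stopifnot(inherits(model, "feature_model"))
  seq_len(model$rank)
}
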