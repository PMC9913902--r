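#' @importFrom stats rnorm runif sd setNames aggregate
#' @importFrom utils read.csv write.csv combn modifyList head
NULL

#' Validate an 8-bit grayscale image matrix
#'
#' Images throughout the package are plain integer matrices with values in
#' `[0, 255]`; this checks the contract and returns the matrix in integer
#' storage mode.
#'
#' @param image numeric matrix.
#' @param min_dim minimum number of rows and columns (default 2).
#' @return the validated matrix, integer storage.
#' @export
as_gray_image <- function(image, min_dim = 2L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop(sprintf("image must be at least %dx%d", min_dim, min_dim), call. = FALSE)
  if (anyNA(image)) stop("image contains NA values", call. = FALSE)
  if (any(image < 0 | image > 255))
    stop("image values must lie in [0, 255]", call. = FALSE)
  if (any(image != round(image)))
    stop("image values must be integers in [0, 255]", call. = FALSE)
  storage.mode(image) <- "integer"
  image
}

assert_binary_mask <- function(mask) {
  if (!is.matrix(mask) || anyNA(mask) || !all(mask %in% c(0L, 1L)))
    stop("mask must be a binary {0,1} matrix", call. = FALSE)
  storage.mode(mask) <- "integer"
  mask
}

#' Read an 8-bit grayscale PNG image
#'
#' @param path PNG file path.
#' @return integer matrix in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # grayscale stored with channels
  as_gray_image(round(px * 255))
}

#' Write an image matrix as an 8-bit grayscale PNG
#'
#' @param image integer matrix in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with header `filename,label`; labels are
#' `"normal"` or `"tumor"`. Filenames are interpreted relative to the
#' manifest's directory.
#'
#' @param path manifest CSV path.
#' @return data.frame with columns `filename`, `label`, and `path` (absolute).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path, call. = FALSE)
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("filename", "label") %in% names(m)))
    stop("manifest must have columns 'filename' and 'label'", call. = FALSE)
  bad <- setdiff(unique(m$label), c("normal", "tumor"))
  if (length(bad))
    stop("unknown labels in manifest: ", paste(bad, collapse = ", "), call. = FALSE)
  m$path <- file.path(dirname(normalizePath(path)), m$filename)
  m
}

# Stable per-stage seed derivation: one global seed fans out to derived
# seeds so partial reruns of a stage are reproducible. Plain polynomial
# string hash folded into [0, 2^31 - 2].
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h) %% 2147483646 + 1)
}
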