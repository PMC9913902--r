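#' Binarize an image at a normalized intensity threshold
#'
#' Foreground is everything strictly above `threshold_norm * 255`; with the
#' default 0.05 the cut sits at 12.75, so integer intensity 12 maps to
#' background and 13 to foreground.
#'
#' @param image integer matrix in `[0, 255]`.
#' @param threshold_norm normalized threshold in (0, 1), default 0.05.
#' @return binary integer matrix, same shape.
#' @export
binarize <- function(image, threshold_norm = 0.05) {
  image <- as_gray_image(image)
  if (threshold_norm <= 0 || threshold_norm >= 1)
    stop("threshold_norm must lie in (0, 1)", call. = FALSE)
  mask <- (image > threshold_norm * 255) * 1L
  storage.mode(mask) <- "integer"
  mask
}

#' The absolute 8-bit intensity cut of a normalized threshold
#'
#' @param threshold_norm normalized threshold in (0, 1).
#' @param bits bit depth, default 8.
#' @return `threshold_norm * (2^bits - 1)` (12.75 for the defaults).
#' @export
binarization_cut <- function(threshold_norm = 0.05, bits = 8L) {
  threshold_norm * (2^bits - 1)
}

# Run-based connected-component labelling with union-find.
# Decomposes each row into runs of 1s (rle), then merges runs on adjacent
# rows whose column ranges touch; 8-connectivity counts diagonal contact.
label_components <- function(mask, connectivity = 8L) {
  mask <- assert_binary_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  # runs per row: start col, end col, row, id
  runs_row <- integer(0); runs_s <- integer(0); runs_e <- integer(0)
  for (i in seq_len(nr)) {
    r <- rle(mask[i, ])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values == 1L
    if (any(keep)) {
      runs_row <- c(runs_row, rep.int(i, sum(keep)))
      runs_s <- c(runs_s, starts[keep]); runs_e <- c(runs_e, ends[keep])
    }
  }
  n_runs <- length(runs_row)
  labels <- matrix(0L, nr, nc)
  if (n_runs == 0L) return(labels)
  parent <- seq_len(n_runs)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  slack <- if (connectivity == 8L) 1L else 0L
  row_index <- split(seq_len(n_runs), runs_row)
  for (i in seq_len(nr - 1L)) {
    a <- row_index[[as.character(i)]]; b <- row_index[[as.character(i + 1L)]]
    if (is.null(a) || is.null(b)) next
    for (x in a) for (y in b) {
      if (runs_s[y] <= runs_e[x] + slack && runs_e[y] >= runs_s[x] - slack) {
        rx <- find(x); ry <- find(y)
        if (rx != ry) parent[ry] <- rx
      }
    }
  }
  roots <- vapply(seq_len(n_runs), find, integer(1))
  comp <- match(roots, unique(roots))
  for (k in seq_len(n_runs))
    labels[runs_row[k], runs_s[k]:runs_e[k]] <- comp[k]
  labels
}

#' Keep the largest connected foreground component and fill its holes
#'
#' Components use 8-connectivity; holes are background regions (4-connected,
#' the standard dual) not reachable from the image border. The result is the
#' largest component with every enclosed hole set to 1. Idempotent.
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @return binary matrix of the filled largest component.
#' @export
largest_component_mask <- function(mask) {
  mask <- assert_binary_mask(mask)
  if (!any(mask == 1L)) stop("no foreground found", call. = FALSE)
  lab <- label_components(mask, connectivity = 8L)
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  keep <- (lab == big) * 1L
  # hole fill: background components (4-conn) not touching the border
  bg <- 1L - keep
  bg_lab <- label_components(bg, connectivity = 4L)
  border_ids <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                         bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
  border_ids <- border_ids[border_ids > 0L]
  hole <- bg_lab > 0L & !(bg_lab %in% border_ids)
  keep[hole] <- 1L
  storage.mode(keep) <- "integer"
  keep
}

#' Zero out background pixels using a binary mask
#'
#' @param image integer matrix in `[0, 255]`.
#' @param mask binary matrix of the same shape.
#' @return integer matrix: elementwise `image * mask`.
#' @export
extract_foreground <- function(image, mask) {
  image <- as_gray_image(image)
  mask <- assert_binary_mask(mask)
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  out <- image * mask
  storage.mode(out) <- "integer"
  out
}

#' Downsample an image by 2x2 block averaging
#'
#' Each non-overlapping 2x2 block becomes one pixel holding the block mean,
#' rounded half-up to keep 8-bit integers. A trailing odd row/column is
#' dropped.
#'
#' @param image integer matrix, at least 2x2.
#' @return integer matrix of halved dimensions.
#' @export
downsample_mean2x2 <- function(image) {
  image <- as_gray_image(image)
  nr <- nrow(image) %/% 2L; nc <- ncol(image) %/% 2L
  im <- image[seq_len(2L * nr), seq_len(2L * nc), drop = FALSE]
  o <- seq_len(nr) * 2L - 1L; p <- seq_len(nc) * 2L - 1L
  s <- im[o, p, drop = FALSE] + im[o + 1L, p, drop = FALSE] +
    im[o, p + 1L, drop = FALSE] + im[o + 1L, p + 1L, drop = FALSE]
  out <- matrix(as.integer(floor(s / 4 + 0.5)), nr, nc)
  out
}

#' Full preprocessing chain for one image
#'
#' Binarize, keep the largest hole-filled component, zero the background,
#' then optionally 2x2-downsample the foreground image (and mask).
#'
#' @param image integer matrix in `[0, 255]`.
#' @param threshold_norm binarization threshold, default 0.05.
#' @param downsample apply 2x2 averaging after foreground extraction?
#' @return list with `image` (foreground, possibly downsampled) and `mask`
#'   (the filled head mask at the same resolution as `image`).
#' @export
preprocess_image <- function(image, threshold_norm = 0.05, downsample = TRUE) {
  mask <- largest_component_mask(binarize(image, threshold_norm))
  fg <- extract_foreground(image, mask)
  if (downsample) {
    fg <- downsample_mean2x2(fg)
    mask <- (downsample_mean2x2(mask * 255L) >= 128L) * 1L
    storage.mode(mask) <- "integer"
  }
  list(image = fg, mask = mask)
}
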