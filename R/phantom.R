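#' Specification of the synthetic head-phantom generator
#'
#' A phantom is a 2-D 8-bit grayscale head-like image with five intensity
#' regimes: dark background, bright elliptical skull annulus, outer brain
#' tissue, inner brain tissue, and (for tumor-labelled samples) a single
#' ellipsoidal lesion inside the brain. The defaults encode a balanced
#' 60 + 60 dataset of 250x250 images whose background stays below the
#' 8-bit binarization cut of 12.75 used by the preprocessing stage.
#'
#' @param image_size pixels per side (square images), default 250.
#' @param n_normal,n_tumor class counts, default 60 each.
#' @param intensity_means named vector of region mean intensities with names
#'   `background`, `skull`, `outer_tissue`, `inner_tissue`, `tumor`.
#' @param intensity_sds per-region intensity standard deviations, same names.
#' @param tumor_radius_range min/max lesion radius as a fraction of the brain
#'   radius.
#' @param noise_sd additive Gaussian noise SD (intensity units) applied on
#'   top of the per-region variation, then clipped to `[0, 255]`.
#' @param seed RNG seed controlling every random element.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 250L,
                         n_normal = 60L,
                         n_tumor = 60L,
                         intensity_means = c(background = 5, skull = 230,
                                             outer_tissue = 90,
                                             inner_tissue = 140, tumor = 200),
                         intensity_sds = c(background = 2, skull = 6,
                                           outer_tissue = 6,
                                           inner_tissue = 6, tumor = 6),
                         tumor_radius_range = c(0.18, 0.38),
                         noise_sd = 3,
                         seed = 1L) {
  roles <- c("background", "skull", "outer_tissue", "inner_tissue", "tumor")
  spec <- structure(list(image_size = as.integer(image_size),
                         n_normal = as.integer(n_normal),
                         n_tumor = as.integer(n_tumor),
                         intensity_means = intensity_means,
                         intensity_sds = intensity_sds,
                         tumor_radius_range = as.numeric(tumor_radius_range),
                         noise_sd = as.numeric(noise_sd),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  if (!all(roles %in% names(spec$intensity_means)) ||
      !all(roles %in% names(spec$intensity_sds)))
    stop("intensity_means/intensity_sds must name: ",
         paste(roles, collapse = ", "), call. = FALSE)
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  mu <- spec$intensity_means
  sdv <- spec$intensity_sds
  if (any(mu < 0 | mu > 255))
    stop("phantom_spec invariant violated: all region means must lie in [0, 255]",
         call. = FALSE)
  if (spec$n_normal < 0L || spec$n_tumor < 0L)
    stop("phantom_spec invariant violated: sample counts must be >= 0",
         call. = FALSE)
  if (mu[["background"]] + 3 * sdv[["background"]] >= 12.75)
    stop("phantom_spec invariant violated: background mean + 3*SD must stay below 12.75",
         call. = FALSE)
  roles <- names(mu)
  for (i in seq_along(roles)[-1]) for (j in seq_len(i - 1L)) {
    gap <- abs(mu[[roles[i]]] - mu[[roles[j]]])
    if (gap < 4 * max(sdv[[roles[i]]], sdv[[roles[j]]]))
      stop(sprintf(paste0("phantom_spec invariant violated: means of '%s' and '%s'",
                          " are separated by %.1f < 4*max(SD)"),
                   roles[i], roles[j], gap), call. = FALSE)
  }
  if (length(spec$tumor_radius_range) != 2L ||
      any(spec$tumor_radius_range <= 0) ||
      diff(spec$tumor_radius_range) < 0 || spec$tumor_radius_range[2] > 0.6)
    stop("phantom_spec invariant violated: tumor_radius_range must be 0 < min <= max <= 0.6",
         call. = FALSE)
  if (spec$noise_sd < 0)
    stop("phantom_spec invariant violated: noise_sd must be >= 0", call. = FALSE)
  if (spec$image_size < 16L)
    stop("phantom_spec invariant violated: image_size must be >= 16", call. = FALSE)
  invisible(spec)
}

# Squared normalized ellipse coordinate: <= 1 inside.
ellipse_q <- function(rows, cols, cx, cy, rx, ry) {
  outer((rows - cx) / rx, rep(1, length(cols)))^2 +
    outer(rep(1, length(rows)), (cols - cy) / ry)^2
}

#' Generate one labelled phantom image with ground truth
#'
#' @param spec a [phantom_spec()].
#' @param label `"normal"` or `"tumor"`.
#' @param seed RNG seed for this sample; defaults to the spec's seed.
#' @return an object of class `phantom_sample`: list with `image` (integer
#'   matrix), `label`, `tumor_mask`, `brain_mask` (binary matrices).
#' @export
generate_phantom <- function(spec, label = c("normal", "tumor"),
                             seed = spec$seed) {
  validate_phantom_spec(spec)
  label <- match.arg(label)
  set.seed(seed)
  n <- spec$image_size
  rows <- seq_len(n); cols <- seq_len(n)
  # Shepp-Logan-style fixed head geometry: anatomy is identical across
  # subjects (slices assumed spatially normalized); per-subject variation
  # comes from the noise model and, for tumor samples, the lesion
  cx <- n / 2
  cy <- n / 2
  head_rx <- n * 0.42
  head_ry <- n * 0.35

  q_head <- ellipse_q(rows, cols, cx, cy, head_rx, head_ry)
  skull_frac <- 0.88                     # inner edge of the skull annulus
  inner_frac <- 0.55                     # inner-tissue core, fraction of brain
  q_brain <- ellipse_q(rows, cols, cx, cy, head_rx * skull_frac, head_ry * skull_frac)
  q_core <- ellipse_q(rows, cols, cx, cy, head_rx * skull_frac * inner_frac,
                      head_ry * skull_frac * inner_frac)

  role <- matrix("background", n, n)
  role[q_head <= 1] <- "skull"
  role[q_brain <= 1] <- "outer_tissue"
  role[q_core <= 1] <- "inner_tissue"
  brain_mask <- matrix(0L, n, n); brain_mask[q_brain <= 1] <- 1L
  tumor_mask <- matrix(0L, n, n)

  if (label == "tumor") {
    brain_r <- sqrt(head_rx * head_ry) * skull_frac
    r_frac <- runif(1, spec$tumor_radius_range[1], spec$tumor_radius_range[2])
    r <- r_frac * brain_r
    # keep the lesion fully inside the brain ellipse
    for (attempt in 1:100) {
      u <- runif(1, 0, 2 * pi)
      # deep-seated lesions: centers stay within 0.15 brain radii of the
      # brain center (the slice is curated to cut through the lesion), so
      # lesions across subjects share a central footprint
      rad <- sqrt(runif(1)) * min(0.15, max(0, 1 - r_frac - 0.08))
      tcx <- cx + rad * head_rx * skull_frac * cos(u)
      tcy <- cy + rad * head_ry * skull_frac * sin(u)
      trx <- r * runif(1, 0.92, 1.08)
      try_ <- r * runif(1, 0.92, 1.08)
      edge <- ellipse_q(c(tcx - trx, tcx + trx, tcx, tcx),
                        c(tcy, tcy, tcy - try_, tcy + try_),
                        cx, cy, head_rx * skull_frac, head_ry * skull_frac)
      if (all(diag(edge) <= 1)) break
    }
    q_tumor <- ellipse_q(rows, cols, tcx, tcy, trx, try_)
    tumor_mask[q_tumor <= 1] <- 1L
    tumor_mask <- tumor_mask * brain_mask
    role[tumor_mask == 1L] <- "tumor"
    attr(tumor_mask, "radii") <- c(trx, try_)
    attr(tumor_mask, "r") <- r
  }

  mu <- spec$intensity_means[role]
  sdv <- spec$intensity_sds[role]
  px <- mu + rnorm(n * n, 0, 1) * sdv + rnorm(n * n, 0, spec$noise_sd)
  img <- matrix(pmin(255, pmax(0, round(px))), n, n)

  structure(list(image = as_gray_image(img), label = label,
                 tumor_mask = tumor_mask, brain_mask = brain_mask),
            class = "phantom_sample")
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_normal + n_tumor` grayscale PNG images, PNG ground-truth tumor
#' masks, and a CSV manifest `filename,label`. Per-sample seeds are derived
#' deterministically from the spec's seed, so identical specs produce
#' byte-identical datasets.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @return manifest data.frame with columns `filename`, `label`, `mask`.
#' @export
generate_dataset <- function(spec, out_dir) {
  validate_phantom_spec(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)
  labels <- rep(c("normal", "tumor"), c(spec$n_normal, spec$n_tumor))
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    s <- generate_phantom(spec, labels[i],
                          seed = derive_seed(spec$seed, paste0("phantom/", i)))
    fn <- sprintf("%s_%03d.png", labels[i], i)
    mfn <- sprintf("%s_%03d_mask.png", labels[i], i)
    ok <- try(write_gray_image(s$image, file.path(out_dir, fn)), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("failed writing ", file.path(out_dir, fn), ": ",
           attr(ok, "condition")$message, call. = FALSE)
    write_gray_image(s$tumor_mask * 255L, file.path(out_dir, mfn))
    rows[[i]] <- data.frame(filename = fn, label = labels[i], mask = mfn,
                            stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(filename = character(), label = character(), mask = character(),
               stringsAsFactors = FALSE)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  manifest
}

#' Generate a phantom dataset in memory
#'
#' Same sampling scheme as [generate_dataset()] but returns the
#' `phantom_sample` objects directly, avoiding disk I/O.
#'
#' @param spec a [phantom_spec()].
#' @return list of `phantom_sample` objects.
#' @export
generate_samples <- function(spec) {
  validate_phantom_spec(spec)
  labels <- rep(c("normal", "tumor"), c(spec$n_normal, spec$n_tumor))
  lapply(seq_along(labels), function(i)
    generate_phantom(spec, labels[i],
                     seed = derive_seed(spec$seed, paste0("phantom/", i))))
}
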