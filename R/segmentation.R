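#' Default texture-segmentation parameters
#'
#' The published local-contrast configuration for segmenting the
#' fibroblast-occupied area in phase-contrast-like images: Gaussian window
#' scale sigma = 4 px, contrast threshold epsilon = 0.08, plus cleanup
#' defaults (fill holes, drop objects under 64 px).
#'
#' @return A [segmentation_params()] object.
#' @export
default_segmentation_params <- function() {
  segmentation_params(sigma_px = 4, epsilon = 0.08)
}

#' Construct and validate texture-segmentation parameters
#'
#' @param sigma_px Gaussian window scale for local contrast (px, > 0).
#' @param epsilon Contrast threshold (> 0).
#' @param min_object_px Minimal retained connected-component area (px).
#' @param fill_holes Fill holes in foreground components.
#' @return A validated parameter list of class `segmentation_params`.
#' @export
segmentation_params <- function(sigma_px = 4, epsilon = 0.08,
                                min_object_px = 64L, fill_holes = TRUE) {
  assert_scalar_pos(sigma_px, "sigma_px")
  assert_scalar_pos(epsilon, "epsilon")
  if (min_object_px < 0) abort("min_object_px must be >= 0")
  structure(list(sigma_px = sigma_px, epsilon = epsilon,
                 min_object_px = as.integer(min_object_px),
                 fill_holes = isTRUE(fill_holes)),
            class = c("segmentation_params", "list"))
}

# Wrap a logical foreground plane with its area summaries.
new_mask <- function(fg) {
  structure(list(mask = fg, area_px = sum(fg),
                 area_fraction = sum(fg) / length(fg)),
            class = "caf_mask")
}

#' @export
print.caf_mask <- function(x, ...) {
  cat(sprintf("<caf_mask> %dx%d px, foreground %d px (fraction %.4f)\n",
              nrow(x$mask), ncol(x$mask), x$area_px, x$area_fraction))
  invisible(x)
}

#' Local-contrast (coefficient-of-variation) image
#'
#' Computes `C = sqrt(max(G(I^2) - G(I)^2, 0)) / (G(I) + delta)` with `G` a
#' Gaussian window of scale `sigma_px` — the windowed standard deviation
#' over mean. Textured regions (adherent cells in phase contrast) score
#' high; flat background scores near zero. `C` is invariant to a global
#' intensity gain, which is what makes a fixed threshold transferable
#' across acquisitions. The stabilizer `delta = 1e-6 * mean(I)` prevents
#' blow-up in dark regions without visibly shifting `C`.
#'
#' @param image Nonnegative 2-D numeric matrix, not all zero.
#' @param sigma_px Gaussian window scale (px).
#' @return Contrast matrix of the same shape.
#' @export
local_contrast <- function(image, sigma_px = 4) {
  assert_image(image)
  assert_scalar_pos(sigma_px, "sigma_px")
  if (any(image < 0)) abort("image must be nonnegative")
  if (all(image == 0)) abort("cannot normalize an all-zero image")
  mu <- blur_gaussian(image, sigma_px)
  m2 <- blur_gaussian(image^2, sigma_px)
  v <- pmax(m2 - mu^2, 0)
  delta <- 1e-6 * mean(image)
  sqrt(v) / (mu + delta)
}

#' Segment textured (adherent-cell) area by local contrast
#'
#' Thresholds the [local_contrast()] image at `epsilon`, optionally fills
#' holes, and removes connected components smaller than `min_object_px`.
#' Halo correction of the original phase-contrast plugin is not
#' implemented (the synthetic fixtures have no phase halo).
#'
#' @param image Nonnegative 2-D numeric matrix.
#' @param params A [segmentation_params()] object.
#' @return A `caf_mask`: list with `mask` (logical), `area_px`,
#'   `area_fraction`.
#' @export
segment_texture <- function(image, params = default_segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  C <- local_contrast(image, params$sigma_px)
  fg <- C > params$epsilon
  fg <- cleanup_mask(fg, params$fill_holes, params$min_object_px)
  new_mask(fg)
}

cleanup_mask <- function(fg, fill_holes, min_object_px) {
  if (!any(fg)) return(fg)
  m <- matrix(as.integer(fg), nrow(fg), ncol(fg))
  if (fill_holes) m <- as.matrix(EBImage::fillHull(m))
  if (min_object_px > 0L) {
    lab <- as.matrix(EBImage::bwlabel(m))
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_object_px)
    if (length(small) > 0L) m[lab %in% small] <- 0L
  }
  m > 0L
}

#' Segment fluorescence foreground by intensity threshold
#'
#' Foreground is everything strictly above the threshold: Otsu's method on
#' a 256-bin histogram over the image range (`method = "otsu"`), or a
#' user-fixed cutoff (`method = "fixed"`).
#'
#' @param image 2-D numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Cutoff for `method = "fixed"`.
#' @return A `caf_mask`.
#' @export
segment_fluorescence <- function(image, method = c("otsu", "fixed"),
                                 threshold = NULL) {
  assert_image(image)
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold)) abort("threshold required for method = 'fixed'")
    return(new_mask(image > threshold))
  }
  rng <- range(image)
  if (rng[1] == rng[2]) abort("degenerate histogram: image has a single value")
  thr <- EBImage::otsu(EBImage::Image(image), range = rng, levels = 256)
  new_mask(image > thr)
}
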