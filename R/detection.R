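#' Default spot-detection parameters
#'
#' The detector is configured by the expected object diameter and a minimal
#' quality: 8 µm and 1, the settings used for tracking Treg-sized cells in
#' the time-lapse co-cultures. Quality is the scale-normalized
#' Laplacian-of-Gaussian response at the detection maximum, so its units
#' follow the image intensity units.
#'
#' @return A list with `diameter_um` and `quality_min`.
#' @examples
#' default_detection_params()
#' @export
default_detection_params <- function() {
  detection_params(diameter_um = 8, quality_min = 1)
}

#' Construct and validate spot-detection parameters
#'
#' @param diameter_um Expected object diameter in µm (> 0).
#' @param quality_min Minimal detection quality (filter-response units).
#' @param subpixel Refine each maximum by a quadratic fit through its
#'   response neighborhood (off by default; the contact rule operates at
#'   pixel scale, but refinement removes the one-pixel localization ties
#'   that occur when an object center falls between pixels).
#' @return A validated parameter list of class `detection_params`.
#' @export
detection_params <- function(diameter_um = 8, quality_min = 1,
                             subpixel = FALSE) {
  assert_scalar_pos(diameter_um, "diameter_um")
  if (!is.numeric(quality_min) || length(quality_min) != 1L ||
      is.na(quality_min)) {
    abort("quality_min must be a number")
  }
  structure(list(diameter_um = diameter_um, quality_min = quality_min,
                 subpixel = isTRUE(subpixel)),
            class = c("detection_params", "list"))
}

# Quadratic (parabolic) subpixel refinement of integer maxima: 1-D fits
# through the response at the peak and its two neighbors, per axis.
refine_subpixel <- function(resp, y, x) {
  nr <- nrow(resp); nc <- ncol(resp)
  dx <- numeric(length(x)); dy <- numeric(length(y))
  for (k in seq_along(x)) {
    r <- y[k] + 1L; c <- x[k] + 1L
    if (c > 1L && c < nc) {
      den <- resp[r, c - 1] - 2 * resp[r, c] + resp[r, c + 1]
      if (den < 0) dx[k] <- 0.5 * (resp[r, c - 1] - resp[r, c + 1]) / den
    }
    if (r > 1L && r < nr) {
      den <- resp[r - 1, c] - 2 * resp[r, c] + resp[r + 1, c]
      if (den < 0) dy[k] <- 0.5 * (resp[r - 1, c] - resp[r + 1, c]) / den
    }
  }
  list(x = x + pmin(pmax(dx, -0.5), 0.5), y = y + pmin(pmax(dy, -0.5), 0.5))
}

#' Scale-normalized Laplacian-of-Gaussian blob response
#'
#' Computes `-sigma^2 * (LoG * I)` so bright blobs give positive peaks. The
#' filter scale follows the standard blob-size relation: a disk of radius
#' `r` maximizes the scale-normalized response at `sigma = r / sqrt(2)`, so
#' `sigma_px = (diameter_um / pixel_size_um) / (2 * sqrt(2))`. The kernel is
#' mean-subtracted (exactly zero DC response) and applied with reflecting
#' boundaries.
#'
#' @param image 2-D numeric matrix.
#' @param diameter_um Expected blob diameter (µm); must be >= 1 pixel.
#' @param pixel_size_um Pixel size (µm/px).
#' @return Response matrix of the same shape.
#' @export
log_response <- function(image, diameter_um, pixel_size_um) {
  assert_image(image)
  assert_scalar_pos(diameter_um, "diameter_um")
  d_px <- um_to_px(diameter_um, pixel_size_um)
  if (d_px < 1) abort("diameter smaller than 1 pixel")
  sigma <- d_px / (2 * sqrt(2))
  radius <- max(2L, ceiling(4 * sigma))
  ax <- seq.int(-radius, radius)
  r2 <- outer(ax^2, ax^2, `+`)
  g <- exp(-r2 / (2 * sigma^2))
  # -sigma^2 * laplacian-of-gaussian: positive at bright blob centers
  kern <- -sigma^2 * ((r2 - 2 * sigma^2) / (2 * pi * sigma^6)) * g
  kern <- kern - mean(kern)
  conv2_reflect(image, kern)
}

# Strict 8-connected local maxima of a response matrix; returns a logical
# matrix. Border ring (1 px) is excluded.
strict_local_maxima <- function(resp) {
  nr <- nrow(resp)
  nc <- ncol(resp)
  if (nr < 3L || nc < 3L) return(matrix(FALSE, nr, nc))
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  ismax <- matrix(TRUE, nr - 2L, nc - 2L)
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      nb <- resp[(2 + dy):(nr - 1 + dy), (2 + dx):(nc - 1 + dx)]
      ismax <- ismax & (core > nb)
    }
  }
  out <- matrix(FALSE, nr, nc)
  out[2:(nr - 1), 2:(nc - 1)] <- ismax
  out
}

#' Detect spot-like cells in one frame
#'
#' Candidate spots are strict 8-connected local maxima of the
#' scale-normalized LoG response ([log_response()]). Maxima below
#' `quality_min`, or within `diameter / 2` of the image border, are
#' discarded; of any two maxima closer than `diameter / 2` the lower-quality
#' one is suppressed. Spots are returned sorted by descending quality.
#'
#' @param image 2-D numeric matrix.
#' @param params A [detection_params()] object.
#' @param pixel_size_um Pixel size (µm/px).
#' @return A tibble with columns `x_px`, `y_px` (0-based pixel coordinates),
#'   and `quality`.
#' @examples
#' img <- matrix(0, 64, 64)
#' yx <- outer((1:64 - 32)^2, (1:64 - 32)^2, "+")
#' img <- 4 * exp(-yx / (2 * 2.83^2))
#' detect_spots(img, detection_params(8, 1), pixel_size_um = 1)
#' @export
detect_spots <- function(image, params = default_detection_params(),
                         pixel_size_um = 1) {
  assert_image(image)
  stopifnot(inherits(params, "detection_params"))
  empty <- tibble(x_px = numeric(0), y_px = numeric(0), quality = numeric(0))
  if (all(image == image[1])) return(empty)
  resp <- log_response(image, params$diameter_um, pixel_size_um)
  peaks <- strict_local_maxima(resp)
  if (!any(peaks)) return(empty)
  idx <- which(peaks, arr.ind = TRUE)
  q <- resp[peaks]
  keep <- q >= params$quality_min
  idx <- idx[keep, , drop = FALSE]
  q <- q[keep]
  if (nrow(idx) == 0L) return(empty)

  d_px <- um_to_px(params$diameter_um, pixel_size_um)
  margin <- d_px / 2
  y <- unname(idx[, 1]) - 1
  x <- unname(idx[, 2]) - 1
  inb <- y >= margin & y <= nrow(image) - 1 - margin &
         x >= margin & x <= ncol(image) - 1 - margin
  y <- y[inb]; x <- x[inb]; q <- q[inb]
  if (length(q) == 0L) return(empty)

  # non-maximum suppression within d/2, greedy by quality (ties: y then x)
  ord <- order(-q, y, x)
  y <- y[ord]; x <- x[ord]; q <- q[ord]
  keep <- logical(length(q))
  min_d2 <- (d_px / 2)^2
  for (i in seq_along(q)) {
    if (i == 1L) { keep[1] <- TRUE; next }
    sel <- which(keep)
    keep[i] <- all((x[i] - x[sel])^2 + (y[i] - y[sel])^2 >= min_d2)
  }
  x <- x[keep]; y <- y[keep]; q <- q[keep]
  if (params$subpixel && length(x) > 0L) {
    ref <- refine_subpixel(resp, y, x)
    x <- ref$x; y <- ref$y
  }
  tibble(x_px = x, y_px = y, quality = q)
}

#' Detect spots in every frame of a movie channel
#'
#' @param movie A [movie()] object.
#' @param channel Channel name to detect in.
#' @param params A [detection_params()] object.
#' @return A tibble with columns `frame` (0-based), `x_px`, `y_px`,
#'   `quality`, ordered by frame then descending quality.
#' @export
detect_movie <- function(movie, channel = "treg",
                         params = default_detection_params()) {
  stopifnot(inherits(movie, "caf_movie"))
  if (!channel %in% movie$channel_names) {
    abort(sprintf("channel not in movie: %s", channel))
  }
  purrr::map_dfr(seq_len(n_frames(movie)), function(f) {
    det <- detect_spots(movie$frames[[channel]][[f]], params, movie$pixel_size_um)
    if (nrow(det) == 0L) return(tibble(frame = integer(0), x_px = numeric(0),
                                       y_px = numeric(0), quality = numeric(0)))
    mutate(det, frame = f - 1L, .before = 1L)
  })
}
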