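#' Construct a time-lapse movie object
#'
#' A movie bundles ordered image frames for one or more channels with the
#' acquisition metadata every downstream step needs: the pixel size (µm/px)
#' used to convert all micrometre thresholds to pixels, and the frame
#' interval (minutes) used to convert frame counts to durations.
#'
#' @param frames A named list of channels; each channel is a list of 2-D
#'   numeric matrices (one per time point). All frames must share one shape.
#' @param pixel_size_um Pixel size in µm per pixel (> 0).
#' @param frame_interval_min Minutes between consecutive frames (> 0).
#' @return An object of class `caf_movie`.
#' @examples
#' f <- matrix(0, 32, 32)
#' mov <- movie(list(treg = list(f, f, f)), pixel_size_um = 1,
#'              frame_interval_min = 5)
#' n_frames(mov)
#' @export
movie <- function(frames, pixel_size_um, frame_interval_min) {
  if (!is.list(frames) || length(frames) == 0L || is.null(names(frames)) ||
      any(names(frames) == "")) {
    abort("frames must be a non-empty named list of channels")
  }
  assert_scalar_pos(pixel_size_um, "pixel_size_um")
  if (!is.numeric(frame_interval_min) || length(frame_interval_min) != 1L ||
      !is.finite(frame_interval_min) || frame_interval_min <= 0) {
    abort("frame_interval_min must be > 0")
  }
  n_per_channel <- vapply(frames, length, integer(1))
  if (any(n_per_channel < 1L)) abort("each channel needs at least one frame")
  if (length(unique(n_per_channel)) != 1L) {
    abort("all channels must have the same number of frames")
  }
  dims <- unique(do.call(rbind, lapply(frames, function(ch) {
    t(vapply(ch, dim, integer(2)))
  })))
  if (nrow(dims) != 1L) abort("all frames must share one shape")
  structure(
    list(
      frames = frames,
      pixel_size_um = pixel_size_um,
      frame_interval_min = frame_interval_min,
      channel_names = names(frames)
    ),
    class = "caf_movie"
  )
}

#' Number of frames in a movie
#' @param x A `caf_movie`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "caf_movie"))
  length(x$frames[[1]])
}

#' @export
print.caf_movie <- function(x, ...) {
  d <- dim(x$frames[[1]][[1]])
  cat(sprintf(
    "<caf_movie> %d frame(s), %d channel(s) [%s], %dx%d px, %.3g um/px, dt = %.3g min\n",
    n_frames(x), length(x$frames), paste(x$channel_names, collapse = ", "),
    d[1], d[2], x$pixel_size_um, x$frame_interval_min
  ))
  invisible(x)
}

#' Read a multi-page TIFF time-lapse into a movie
#'
#' Pages are assumed channel-interleaved in acquisition order: with channels
#' `c("treg", "caf")`, page 1 is frame 1 of "treg", page 2 is frame 1 of
#' "caf", page 3 is frame 2 of "treg", and so on. The page count must be
#' divisible by the number of channels.
#'
#' TIFF files store intensities in \[0, 1\]; `intensity_scale` multiplies
#' pixel values on read so movies written with [write_movie()] (which
#' divides by the scale it reports) round-trip to their original units.
#'
#' @param path Path to a readable multi-page TIFF.
#' @param pixel_size_um,frame_interval_min Acquisition metadata (> 0).
#' @param channels Character vector of channel names, in interleave order.
#' @param intensity_scale Factor applied to pixel values on read (> 0).
#' @return A [movie()] object.
#' @export
read_movie <- function(path, pixel_size_um, frame_interval_min,
                       channels = "treg", intensity_scale = 1) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  assert_scalar_pos(intensity_scale, "intensity_scale")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra samples per pixel
    as.matrix(p) * intensity_scale
  })
  dims <- unique(t(vapply(pages, dim, integer(2))))
  if (nrow(dims) != 1L) abort("inconsistent page shapes in TIFF")
  k <- length(channels)
  if (length(pages) %% k != 0L) {
    abort(sprintf("page count (%d) not divisible by channel count (%d)",
                  length(pages), k))
  }
  frames <- lapply(seq_len(k), function(ci) pages[seq(ci, length(pages), by = k)])
  names(frames) <- channels
  movie(frames, pixel_size_um, frame_interval_min)
}

#' Write a movie as a channel-interleaved multi-page float TIFF
#'
#' Pixel values are divided by `scale` (default: the maximum intensity over
#' all frames, or 1 if everything is <= 1) so the file stays within the
#' \[0, 1\] range TIFF storage requires. Pass the returned scale to
#' [read_movie()] as `intensity_scale` to recover the original units.
#'
#' @param x A `caf_movie`.
#' @param path Output path.
#' @param scale Intensity divisor; `NULL` picks one automatically.
#' @return The scale used, invisibly.
#' @export
write_movie <- function(x, path, scale = NULL) {
  stopifnot(inherits(x, "caf_movie"))
  if (is.null(scale)) {
    mx <- max(vapply(x$frames, function(ch) max(vapply(ch, max, numeric(1))),
                     numeric(1)))
    scale <- if (mx > 1) mx else 1
  }
  assert_scalar_pos(scale, "scale")
  k <- length(x$frames)
  pages <- vector("list", n_frames(x) * k)
  for (f in seq_len(n_frames(x))) {
    for (ci in seq_len(k)) {
      pages[[(f - 1L) * k + ci]] <- pmin(pmax(x$frames[[ci]][[f]] / scale, 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}

#' Write a binary mask as PNG
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#' @param path PNG path; any nonzero pixel is foreground.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}
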