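# Independent oracles used across the suite. Each reimplements the
# operation it checks by direct enumeration or dense summation, sharing no
# code with the package internals.

# Minimal cost over ALL partial matchings between point sets a and b:
# cost = sum of squared matched distances + cap^2 per unmatched point.
# Recursive enumeration, feasible for <= 6 points per side.
oracle_match_cost <- function(ax, ay, bx, by, cap_um) {
  na <- length(ax)
  nb <- length(bx)
  cap2 <- cap_um^2
  best <- Inf
  recurse <- function(i, used_b, acc) {
    if (acc >= best) return()
    if (i > na) {
      total <- acc + cap2 * sum(!used_b)
      if (total < best) best <<- total
      return()
    }
    # leave a_i unmatched
    recurse(i + 1L, used_b, acc + cap2)
    for (j in seq_len(nb)) {
      if (used_b[j]) next
      d2 <- (ax[i] - bx[j])^2 + (ay[i] - by[j])^2
      if (d2 > cap2) next
      used_b[j] <- TRUE
      recurse(i + 1L, used_b, acc + d2)
      used_b[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nb), 0)
  best
}

# Cost of a matching returned by link_frame_pair under the same objective.
match_cost_of <- function(matches, ax, ay, bx, by, cap_um) {
  cap2 <- cap_um^2
  matched_d2 <- (ax[matches$i] - bx[matches$j])^2 +
    (ay[matches$i] - by[matches$j])^2
  sum(matched_d2) + cap2 * (length(ax) - nrow(matches)) +
    cap2 * (length(bx) - nrow(matches))
}

# Run-length-encoding oracle for episode extraction: maximal runs of TRUE
# over consecutive frames, filtered at a minimal length.
oracle_runs <- function(flags, min_len) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start_frame = starts[keep] - 1L, end_frame = ends[keep] - 1L,
             n_frames = r$lengths[keep])
}

# Dense direct convolution of an image with the scale-normalized LoG
# kernel (mean-subtracted), reflect boundary, by explicit summation.
oracle_log_response <- function(image, diameter_px) {
  sigma <- diameter_px / (2 * sqrt(2))
  radius <- max(2L, ceiling(4 * sigma))
  ax <- seq.int(-radius, radius)
  r2 <- outer(ax^2, ax^2, `+`)
  kern <- -sigma^2 * ((r2 - 2 * sigma^2) / (2 * pi * sigma^6)) *
    exp(-r2 / (2 * sigma^2))
  kern <- kern - mean(kern)
  nr <- nrow(image)
  nc <- ncol(image)
  refl <- function(i, n) {
    period <- 2L * n - 2L
    j <- (i - 1L) %% period
    ifelse(j >= n, period - j, j) + 1L
  }
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      rows <- refl(y + ax, nr)
      cols <- refl(x + ax, nc)
      out[y, x] <- sum(kern * image[rows, cols])
    }
  }
  out
}

# Small synthetic blob image: Gaussian bumps on a flat background.
make_blob_image <- function(h, w, cx, cy, sigma, amplitude, background = 0) {
  yy <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  xx <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  img <- matrix(background, h, w)
  for (k in seq_along(cx)) {
    img <- img + amplitude[k] *
      exp(-((yy - cy[k])^2 + (xx - cx[k])^2) / (2 * sigma[k]^2))
  }
  img
}
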