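# Internal numeric/image helpers shared across modules.

# Images are plain numeric matrices indexed [row, col] = [y + 1, x + 1];
# exported coordinates are 0-based with x = column, y = row.

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("%s must be > 0", name))
  }
  invisible(x)
}

assert_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("%s must be a 2-D numeric matrix", name))
  }
  invisible(img)
}

# Reflect-pad a matrix by `r` pixels on every side (edge pixel not repeated,
# matching scipy-style "reflect" used by standard blob detectors).
pad_reflect <- function(img, r) {
  nr <- nrow(img)
  nc <- ncol(img)
  if (r >= nr || r >= nc) {
    # fall back to repeated reflection for very small images
    idx_r <- reflect_index(nr, r)
    idx_c <- reflect_index(nc, r)
    return(img[idx_r, idx_c, drop = FALSE])
  }
  idx_r <- c((r + 1L):2L, 1L:nr, (nr - 1L):(nr - r))
  idx_c <- c((r + 1L):2L, 1L:nc, (nc - 1L):(nc - r))
  img[idx_r, idx_c, drop = FALSE]
}

reflect_index <- function(n, r) {
  # indices -r+1 .. n+r mapped by reflection about the borders
  i <- seq.int(1L - r, n + r)
  period <- 2L * n - 2L
  if (period <= 0L) return(rep(1L, length(i)))
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  j + 1L
}

# 2-D convolution with reflect boundary handling via EBImage's FFT filter.
conv2_reflect <- function(img, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  padded <- pad_reflect(img, r)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out <- as.matrix(out)
  out[(r + 1L):(r + nrow(img)), (r + 1L):(r + ncol(img)), drop = FALSE]
}

gaussian_kernel <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  ax <- seq.int(-radius, radius)
  g <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Separable Gaussian smoothing with reflect boundaries.
blur_gaussian <- function(img, sigma) {
  conv2_reflect(img, gaussian_kernel(sigma))
}

# Distance (in pixels) from every pixel to the nearest TRUE pixel of `mask`.
distance_to_foreground <- function(mask) {
  if (!any(mask)) {
    return(matrix(Inf, nrow(mask), ncol(mask)))
  }
  inv <- matrix(1, nrow(mask), ncol(mask))
  inv[mask] <- 0
  as.matrix(EBImage::distmap(inv, metric = "euclidean"))
}

# Clamp 0-based (x, y) coordinates to matrix indices.
coord_to_index <- function(x_px, y_px, dim_img) {
  row <- pmin(pmax(round(y_px) + 1, 1), dim_img[1])
  col <- pmin(pmax(round(x_px) + 1, 1), dim_img[2])
  cbind(row, col)
}

um_to_px <- function(um, pixel_size_um) {
  assert_scalar_pos(pixel_size_um, "pixel_size_um")
  um / pixel_size_um
}

# Bilinear interpolation of a field at continuous 0-based (x, y);
# coordinates outside the grid are clamped to it.
bilinear_at <- function(field, x_px, y_px) {
  nr <- nrow(field); nc <- ncol(field)
  x <- pmin(pmax(x_px, 0), nc - 1)
  y <- pmin(pmax(y_px, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  if (nc < 2 || nr < 2) return(field[cbind(round(y) + 1, round(x) + 1)])
  fx <- x - x0; fy <- y - y0
  i0 <- cbind(y0 + 1, x0 + 1)
  f00 <- field[i0]
  f01 <- field[cbind(y0 + 1, x0 + 2)]
  f10 <- field[cbind(y0 + 2, x0 + 1)]
  f11 <- field[cbind(y0 + 2, x0 + 2)]
  f00 * (1 - fx) * (1 - fy) + f01 * fx * (1 - fy) +
    f10 * (1 - fx) * fy + f11 * fx * fy
}
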