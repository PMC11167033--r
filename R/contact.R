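#' Construct and validate contact parameters
#'
#' `contact_radius_um` is the spot-center-to-stroma distance that counts as
#' contact; its default, 4 µm, is the tracked-cell radius (half the 8 µm
#' detection diameter), so "contact" means the cell body overlaps the
#' segmented stromal area. `min_episode_frames = 2` encodes the 10-minute
#' (2 frames at 5-min sampling) minimal interaction window.
#'
#' @param contact_radius_um Contact distance (µm, >= 0).
#' @param min_episode_frames Minimal frames for a counted episode (>= 1).
#' @param bridge_max_frames Bridge contact interruptions up to this many
#'   frames (default 0: strict runs, the conservative reading).
#' @return A validated parameter list of class `contact_params`.
#' @export
contact_params <- function(contact_radius_um = 4, min_episode_frames = 2L,
                           bridge_max_frames = 0L) {
  if (contact_radius_um < 0) abort("contact_radius_um must be >= 0")
  if (min_episode_frames < 1) abort("min_episode_frames must be >= 1")
  if (bridge_max_frames < 0) abort("bridge_max_frames must be >= 0")
  structure(list(contact_radius_um = contact_radius_um,
                 min_episode_frames = as.integer(min_episode_frames),
                 bridge_max_frames = as.integer(bridge_max_frames)),
            class = c("contact_params", "list"))
}

#' Is a spot in contact with the segmented stromal area?
#'
#' Contact is boundary-inclusive: true iff the Euclidean distance from the
#' spot center to the nearest foreground pixel is at most
#' `contact_radius_um`. The distance is the exact Euclidean distance
#' transform of the mask, interpolated bilinearly at the (possibly
#' subpixel) spot position. An empty mask gives `FALSE`, never an error.
#'
#' @param x_px,y_px Spot center, 0-based pixel coordinates (vectorized).
#' @param mask A `caf_mask` or logical matrix.
#' @param contact_radius_um Contact distance (µm).
#' @param pixel_size_um Pixel size (µm/px).
#' @return Logical vector.
#' @export
in_contact <- function(x_px, y_px, mask, contact_radius_um = 4,
                       pixel_size_um = 1) {
  fg <- if (inherits(mask, "caf_mask")) mask$mask else mask
  if (!any(fg)) return(rep(FALSE, length(x_px)))
  dt <- distance_to_foreground(fg)
  bilinear_at(dt, x_px, y_px) * pixel_size_um <= contact_radius_um
}

#' Per-frame contact timeline of one track
#'
#' One contact flag per observed spot of the track; frames skipped by gap
#' closing carry no flag (and therefore break episode runs unless
#' bridging is enabled in [extract_episodes()]).
#'
#' @param track Tibble with `frame`, `x_px`, `y_px` (one track).
#' @param masks A single mask (static stroma) or a list of masks indexed by
#'   frame + 1.
#' @param params A [contact_params()] object.
#' @param pixel_size_um Pixel size (µm/px).
#' @return Tibble with `frame` and `in_contact`.
#' @export
contact_timeline <- function(track, masks, params = contact_params(),
                             pixel_size_um = 1) {
  stopifnot(inherits(params, "contact_params"))
  track <- arrange(track, .data$frame)
  static <- inherits(masks, "caf_mask") ||
    (is.matrix(masks) && is.logical(masks))
  if (static) {
    flags <- in_contact(track$x_px, track$y_px, masks,
                        params$contact_radius_um, pixel_size_um)
  } else {
    if (any(track$frame + 1L > length(masks))) {
      abort("missing mask for a track frame")
    }
    flags <- vapply(seq_len(nrow(track)), function(r) {
      in_contact(track$x_px[r], track$y_px[r], masks[[track$frame[r] + 1L]],
                 params$contact_radius_um, pixel_size_um)
    }, logical(1))
  }
  tibble(frame = track$frame, in_contact = flags)
}

#' Extract contact episodes from a timeline
#'
#' Episodes are maximal runs of consecutive frames flagged in-contact;
#' runs shorter than `min_episode_frames` are discarded. Durations follow
#' the frame-count convention `duration = n_frames x frame interval` (a
#' 2-frame contact at 5-min sampling is a 10-min interaction). With
#' `bridge_max_frames > 0`, interruptions up to that many frames are
#' bridged before run extraction (off by default).
#'
#' @param timeline Output of [contact_timeline()], or a logical vector
#'   (frames 0, 1, ...).
#' @param params A [contact_params()] object.
#' @param frame_interval_min Frame interval (minutes).
#' @return Tibble with `start_frame`, `end_frame` (inclusive), `n_frames`,
#'   `duration_min`.
#' @export
extract_episodes <- function(timeline, params = contact_params(),
                             frame_interval_min = 5) {
  stopifnot(inherits(params, "contact_params"))
  assert_scalar_pos(frame_interval_min, "frame_interval_min")
  if (is.logical(timeline)) {
    timeline <- tibble(frame = seq_along(timeline) - 1L, in_contact = timeline)
  }
  empty <- tibble(start_frame = integer(0), end_frame = integer(0),
                  n_frames = integer(0), duration_min = numeric(0))
  tl <- arrange(timeline, .data$frame)
  contact_frames <- tl$frame[tl$in_contact]
  if (length(contact_frames) == 0L) return(empty)
  if (params$bridge_max_frames > 0L && length(contact_frames) > 1L) {
    gaps <- diff(contact_frames) - 1L
    bridge <- which(gaps >= 1L & gaps <= params$bridge_max_frames)
    extra <- unlist(lapply(bridge, function(k) {
      seq.int(contact_frames[k] + 1L, contact_frames[k + 1L] - 1L)
    }))
    # only bridge frames the track actually observed
    extra <- intersect(extra, tl$frame)
    contact_frames <- sort(unique(c(contact_frames, extra)))
  }
  # maximal runs of consecutive frame numbers
  brk <- c(0L, which(diff(contact_frames) != 1L), length(contact_frames))
  runs <- purrr::map_dfr(seq_len(length(brk) - 1L), function(k) {
    seg <- contact_frames[(brk[k] + 1L):brk[k + 1L]]
    tibble(start_frame = seg[1], end_frame = seg[length(seg)],
           n_frames = length(seg))
  })
  runs <- filter(runs, .data$n_frames >= params$min_episode_frames)
  if (nrow(runs) == 0L) return(empty)
  mutate(runs, duration_min = .data$n_frames * frame_interval_min)
}

#' Arrest coefficient of a timeline
#'
#' Fraction of a track's observed frames spent in contact.
#'
#' @param timeline Output of [contact_timeline()], or a logical vector.
#' @return A number in \[0, 1\].
#' @export
arrest_coefficient <- function(timeline) {
  flags <- if (is.logical(timeline)) timeline else timeline$in_contact
  if (length(flags) == 0L) abort("empty timeline")
  mean(flags)
}

#' Two-sample comparison of contact durations between conditions
#'
#' Compares per-episode durations (or any two numeric samples) with a
#' two-sided rank-sum test or Welch's t-test. For the rank-sum test with
#' both samples of size at most 8, the null distribution is enumerated
#' exactly over all `choose(n_a + n_b, n_a)` labelings (midranks under
#' ties); larger samples use the standard normal approximation.
#'
#' @param durations_a,durations_b Numeric vectors, each of length >= 2.
#' @param test `"ranksum"` or `"t"`.
#' @return An object of class `condition_comparison` with `statistic`,
#'   `p.value`, `method`, sample sizes and medians; see [tidy()].
#' @examples
#' compare_conditions(c(10, 20, 30), c(5, 10, 15))
#' @export
compare_conditions <- function(durations_a, durations_b,
                               test = c("ranksum", "t")) {
  test <- match.arg(test)
  a <- as.numeric(durations_a)
  b <- as.numeric(durations_b)
  if (length(a) < 2L || length(b) < 2L) abort("each sample needs >= 2 values")
  if (test == "t") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      abort("degenerate: both samples have zero variance")
    }
    ht <- t.test(a, b, alternative = "two.sided")
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    method <- "Welch two-sample t-test"
  } else if (length(a) <= 8L && length(b) <= 8L) {
    res <- ranksum_exact(a, b)
    statistic <- res$statistic
    p <- res$p.value
    method <- "exact rank-sum (full enumeration)"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                       exact = FALSE, correct = TRUE))
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    method <- "Wilcoxon rank-sum (normal approximation)"
  }
  structure(list(statistic = statistic, p.value = p, method = method,
                 n_a = length(a), n_b = length(b),
                 median_a = median(a), median_b = median(b)),
            class = "condition_comparison")
}

# Exact two-sided rank-sum test by full enumeration of labelings.
# Two-sided p = P(|W - E[W]| >= |w_obs - E[W]|) under the permutation null.
ranksum_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  na <- length(a)
  N <- length(pooled)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  combs <- utils::combn(N, na)
  w_all <- colSums(matrix(r[combs], nrow = na))
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  list(statistic = w_obs, p.value = p)
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s\n", x$method))
  cat(sprintf("  n = %d vs %d, medians %.4g vs %.4g\n",
              x$n_a, x$n_b, x$median_a, x$median_b))
  cat(sprintf("  statistic = %.4g, two-sided p = %.4g\n", x$statistic, x$p.value))
  invisible(x)
}

#' Summarise contact episodes per condition
#'
#' @param episodes Episodes tibble with `duration_min` and optionally a
#'   `condition` column.
#' @return One row per condition: `n_episodes`, `mean_duration_min`,
#'   `median_duration_min`.
#' @export
summarize_episodes <- function(episodes) {
  if (!"condition" %in% names(episodes)) episodes$condition <- "all"
  episodes |>
    group_by(.data$condition) |>
    summarise(n_episodes = n(),
              mean_duration_min = mean(.data$duration_min),
              median_duration_min = median(.data$duration_min),
              .groups = "drop")
}
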