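#' Default trajectory-linking parameters
#'
#' The published linking configuration for Treg tracking: frame-to-frame
#' links capped at 36 µm, gap closing capped at 12 µm end-to-start distance
#' and at most 5 skipped frames.
#'
#' @return A [linking_params()] object.
#' @export
default_linking_params <- function() {
  linking_params(link_max_um = 36, gap_max_um = 12, gap_max_frames = 5L)
}

#' Construct and validate linking parameters
#'
#' @param link_max_um Maximal frame-to-frame link distance (µm, > 0).
#' @param gap_max_um Maximal end-to-start distance for gap closing (µm, > 0).
#' @param gap_max_frames Maximal number of skipped frames a closed gap may
#'   span (integer >= 0; 0 disables gap closing).
#' @return A validated parameter list of class `linking_params`.
#' @export
linking_params <- function(link_max_um = 36, gap_max_um = 12, gap_max_frames = 5L) {
  assert_scalar_pos(link_max_um, "link_max_um")
  assert_scalar_pos(gap_max_um, "gap_max_um")
  if (!is.numeric(gap_max_frames) || length(gap_max_frames) != 1L ||
      gap_max_frames < 0 || gap_max_frames != round(gap_max_frames)) {
    abort("gap_max_frames must be an integer >= 0")
  }
  structure(list(link_max_um = link_max_um, gap_max_um = gap_max_um,
                 gap_max_frames = as.integer(gap_max_frames)),
            class = c("linking_params", "list"))
}

#' Optimally match detections between two consecutive frames
#'
#' Solves the capped linear assignment problem: among one-to-one matchings
#' whose every link is at most `link_max_um`, minimize the total squared
#' link distance plus `link_max_um^2` for every spot left unmatched (the
#' standard alternative-cost formulation, which always links a feasible
#' pair rather than leaving both spots free). Candidate spots are ordered
#' by (y, x) before solving so ties resolve deterministically.
#'
#' @param spots_a,spots_b Tibbles with `x_px`, `y_px` columns (spots of two
#'   consecutive frames).
#' @param link_max_um Maximal link distance (µm).
#' @param pixel_size_um Pixel size (µm/px).
#' @return A tibble with columns `i`, `j` (row indices into `spots_a` and
#'   `spots_b`) and `dist_um`.
#' @export
link_frame_pair <- function(spots_a, spots_b, link_max_um = 36, pixel_size_um = 1) {
  assert_scalar_pos(link_max_um, "link_max_um")
  empty <- tibble(i = integer(0), j = integer(0), dist_um = numeric(0))
  na <- nrow(spots_a)
  nb <- nrow(spots_b)
  if (na == 0L || nb == 0L) return(empty)

  ax <- spots_a$x_px * pixel_size_um; ay <- spots_a$y_px * pixel_size_um
  bx <- spots_b$x_px * pixel_size_um; by <- spots_b$y_px * pixel_size_um
  d2 <- outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2
  cap2 <- link_max_um^2
  if (!any(d2 <= cap2)) return(empty)

  big <- 2 * cap2 * (na + nb) + max(d2[d2 <= cap2]) + 1
  n <- na + nb
  cost <- matrix(big, n, n)
  top <- d2
  top[top > cap2] <- big
  cost[seq_len(na), seq_len(nb)] <- top
  for (i in seq_len(na)) cost[i, nb + i] <- cap2        # a_i unmatched
  for (j in seq_len(nb)) cost[na + j, j] <- cap2        # b_j unmatched
  cost[(na + 1):n, (nb + 1):n] <- 0                     # dummy-dummy, free

  a <- lap_solve(cost)
  i <- which(a[seq_len(na)] <= nb)
  j <- a[i]
  ok <- d2[cbind(i, j)] <= cap2
  i <- i[ok]; j <- j[ok]
  out <- tibble(i = as.integer(i), j = as.integer(j),
                dist_um = sqrt(d2[cbind(i, j)]))
  arrange(out, .data$i)
}

#' Chain per-frame detections into tracklets
#'
#' Links detections of consecutive frames with [link_frame_pair()]; a
#' detection with no admissible partner in the next frame ends its
#' tracklet, and every unmatched detection starts a new one. Every
#' detection belongs to at most one tracklet.
#'
#' @param detections Tibble with `frame` (0-based), `x_px`, `y_px` and
#'   optionally `quality`.
#' @param params A [linking_params()] object.
#' @param pixel_size_um Pixel size (µm/px).
#' @return The detections tibble with a `track_id` column (1-based, dense,
#'   ordered by first appearance) and `gap_closed = FALSE`, ordered by
#'   track then frame.
#' @export
build_tracklets <- function(detections, params = default_linking_params(),
                            pixel_size_um = 1) {
  stopifnot(inherits(params, "linking_params"))
  if (!all(c("frame", "x_px", "y_px") %in% names(detections))) {
    abort("detections needs columns frame, x_px, y_px")
  }
  det <- arrange(detections, .data$frame, .data$y_px, .data$x_px)
  det$track_id <- NA_integer_
  if (!"quality" %in% names(det)) det$quality <- NA_real_
  if (nrow(det) == 0L) {
    out <- as_tibble(det[, c("track_id", "frame", "x_px", "y_px", "quality")])
    out$gap_closed <- logical(0)
    return(out)
  }
  frames <- sort(unique(det$frame))
  next_id <- 1L
  rows_of <- function(f) which(det$frame == f)
  first <- rows_of(frames[1])
  det$track_id[first] <- seq.int(next_id, length.out = length(first))
  next_id <- next_id + length(first)
  if (length(frames) > 1L) {
    for (k in seq_len(length(frames) - 1L)) {
      fa <- frames[k]; fb <- frames[k + 1L]
      ra <- rows_of(fa); rb <- rows_of(fb)
      if (fb == fa + 1L) {
        m <- link_frame_pair(det[ra, ], det[rb, ], params$link_max_um, pixel_size_um)
        if (nrow(m) > 0L) det$track_id[rb[m$j]] <- det$track_id[ra[m$i]]
      }
      new <- rb[is.na(det$track_id[rb])]
      if (length(new) > 0L) {
        det$track_id[new] <- seq.int(next_id, length.out = length(new))
        next_id <- next_id + length(new)
      }
    }
  }
  det$gap_closed <- FALSE
  out <- det[, c("track_id", "frame", "x_px", "y_px", "quality", "gap_closed")]
  renumber_tracks(arrange(as_tibble(out), .data$track_id, .data$frame))
}

# dense track ids ordered by (first frame, x, y) of each track
renumber_tracks <- function(tracks) {
  if (nrow(tracks) == 0L) return(tracks)
  firsts <- tracks |>
    group_by(.data$track_id) |>
    summarise(f0 = min(.data$frame),
              x0 = .data$x_px[which.min(.data$frame)],
              y0 = .data$y_px[which.min(.data$frame)], .groups = "drop") |>
    arrange(.data$f0, .data$x0, .data$y0)
  remap <- setNames(seq_len(nrow(firsts)), firsts$track_id)
  tracks$track_id <- as.integer(remap[as.character(tracks$track_id)])
  arrange(tracks, .data$track_id, .data$frame)
}

#' Close detection gaps between tracklets
#'
#' A tracklet end may be joined to a later tracklet start when between 1
#' and `gap_max_frames` frames are skipped and the end-to-start distance is
#' at most `gap_max_um`. Candidate joins are applied greedily by ascending
#' distance (ties by track ids); each end and each start is used at most
#' once. Gap closing is an approximation to a global assignment, adequate
#' at the cell densities these movies have.
#'
#' @param tracks Output of [build_tracklets()].
#' @param params A [linking_params()] object.
#' @param pixel_size_um Pixel size (µm/px).
#' @return Tracks tibble with merged `track_id`s; the first spot after each
#'   closed gap has `gap_closed = TRUE`.
#' @export
close_gaps <- function(tracks, params = default_linking_params(),
                       pixel_size_um = 1) {
  stopifnot(inherits(params, "linking_params"))
  if (nrow(tracks) == 0L || params$gap_max_frames == 0L) return(tracks)
  ends <- tracks |>
    group_by(.data$track_id) |>
    summarise(end_frame = max(.data$frame),
              end_x = .data$x_px[which.max(.data$frame)],
              end_y = .data$y_px[which.max(.data$frame)],
              start_frame = min(.data$frame),
              start_x = .data$x_px[which.min(.data$frame)],
              start_y = .data$y_px[which.min(.data$frame)],
              .groups = "drop")
  cand <- tidyr::expand_grid(a = ends$track_id, b = ends$track_id) |>
    filter(.data$a != .data$b)
  ea <- ends[match(cand$a, ends$track_id), ]
  sb <- ends[match(cand$b, ends$track_id), ]
  gap <- sb$start_frame - ea$end_frame - 1L
  dist_um <- sqrt((sb$start_x - ea$end_x)^2 + (sb$start_y - ea$end_y)^2) *
    pixel_size_um
  ok <- gap >= 1L & gap <= params$gap_max_frames & dist_um <= params$gap_max_um
  cand <- cand[ok, ]; cand$dist_um <- dist_um[ok]
  if (nrow(cand) == 0L) return(tracks)
  cand <- arrange(cand, .data$dist_um, .data$a, .data$b)

  end_used <- logical(max(ends$track_id))
  start_used <- logical(max(ends$track_id))
  joins <- list()
  for (r in seq_len(nrow(cand))) {
    a <- cand$a[r]; b <- cand$b[r]
    if (end_used[a] || start_used[b]) next
    end_used[a] <- TRUE
    start_used[b] <- TRUE
    joins[[length(joins) + 1L]] <- c(a, b)
  }
  if (length(joins) == 0L) return(tracks)

  # union joined chains: map each track to the head of its chain
  max_id <- max(ends$track_id)
  succ <- rep(NA_integer_, max_id)
  for (jn in joins) succ[jn[1]] <- jn[2]
  heads <- setdiff(vapply(joins, `[`, integer(1), 1),
                   vapply(joins, `[`, integer(1), 2))
  root <- seq_len(max_id)
  for (h in heads) {
    cur <- h
    while (!is.na(succ[cur])) {
      cur <- succ[cur]
      root[cur] <- h
    }
  }
  joined_starts <- tracks |>
    group_by(.data$track_id) |>
    summarise(start_frame = min(.data$frame), .groups = "drop") |>
    filter(.data$track_id %in% vapply(joins, `[`, integer(1), 2))
  mark <- paste(tracks$track_id, tracks$frame) %in%
    paste(joined_starts$track_id, joined_starts$start_frame)
  tracks$gap_closed <- tracks$gap_closed | mark
  tracks$track_id <- root[tracks$track_id]
  renumber_tracks(tracks)
}

#' Link a detection table into gap-closed tracks
#'
#' Convenience wrapper: [build_tracklets()] followed by [close_gaps()].
#'
#' @inheritParams build_tracklets
#' @return Tracks tibble (see [close_gaps()]).
#' @export
track_spots <- function(detections, params = default_linking_params(),
                        pixel_size_um = 1) {
  close_gaps(build_tracklets(detections, params, pixel_size_um),
             params, pixel_size_um)
}

#' Per-track trajectory statistics
#'
#' For each track: total path length (sum of step distances, including
#' steps across closed gaps), net start-to-end displacement, confinement
#' ratio (net / path, defined as 0 for a zero-length path), and duration
#' (`frames spanned x frame interval`).
#'
#' @param tracks Tracks tibble ([track_spots()] output).
#' @param pixel_size_um Pixel size (µm/px).
#' @param frame_interval_min Frame interval (minutes).
#' @return A tibble with one row per track: `track_id`, `n_spots`,
#'   `path_length_um`, `net_displacement_um`, `confinement_ratio`,
#'   `duration_min`.
#' @export
trajectory_stats <- function(tracks, pixel_size_um = 1, frame_interval_min = 5) {
  assert_scalar_pos(frame_interval_min, "frame_interval_min")
  if (nrow(tracks) == 0L) {
    return(tibble(track_id = integer(0), n_spots = integer(0),
                  path_length_um = numeric(0), net_displacement_um = numeric(0),
                  confinement_ratio = numeric(0), duration_min = numeric(0)))
  }
  tracks |>
    arrange(.data$track_id, .data$frame) |>
    group_by(.data$track_id) |>
    summarise(
      n_spots = n(),
      path_length_um = sum(sqrt(diff(.data$x_px)^2 + diff(.data$y_px)^2)) *
        pixel_size_um,
      net_displacement_um = sqrt((.data$x_px[n()] - .data$x_px[1])^2 +
                                 (.data$y_px[n()] - .data$y_px[1])^2) *
        pixel_size_um,
      duration_min = (max(.data$frame) - min(.data$frame) + 1) *
        frame_interval_min,
      .groups = "drop"
    ) |>
    mutate(path_length_um = ifelse(is.na(.data$path_length_um), 0,
                                   .data$path_length_um),
           confinement_ratio = ifelse(.data$path_length_um > 0,
                                      .data$net_displacement_um /
                                        .data$path_length_um, 0),
           .after = "net_displacement_um")
}
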