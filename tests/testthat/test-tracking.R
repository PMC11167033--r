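spots_at <- function(x, y) tibble::tibble(x_px = x, y_px = y)

test_that("default linking parameters are the published ones", {
  p <- default_linking_params()
  expect_equal(p$link_max_um, 36)
  expect_equal(p$gap_max_um, 12)
  expect_equal(p$gap_max_frames, 5L)
})

test_that("frame-pair linking handles empty and over-cap inputs", {
  expect_equal(nrow(link_frame_pair(spots_at(numeric(0), numeric(0)),
                                    spots_at(1, 1), 36, 1)), 0L)
  expect_equal(nrow(link_frame_pair(spots_at(0, 0), spots_at(50, 0), 36, 1)),
               0L)
  m <- link_frame_pair(spots_at(0, 0), spots_at(30, 0), 36, 1)
  expect_equal(nrow(m), 1L)
  expect_equal(m$dist_um, 30)
})

test_that("frame-pair matching cost equals the brute-force optimum", {
  set.seed(31)
  for (rep in 1:60) {
    na <- sample(0:5, 1)
    nb <- sample(0:5, 1)
    ax <- runif(na, 0, 60); ay <- runif(na, 0, 60)
    bx <- runif(nb, 0, 60); by <- runif(nb, 0, 60)
    cap <- runif(1, 10, 40)
    m <- link_frame_pair(spots_at(ax, ay), spots_at(bx, by), cap, 1)
    expect_equal(match_cost_of(m, ax, ay, bx, by, cap),
                 oracle_match_cost(ax, ay, bx, by, cap), tolerance = 1e-8)
    expect_false(anyDuplicated(m$i) > 0 || anyDuplicated(m$j) > 0)
    if (nrow(m) > 0) expect_true(all(m$dist_um <= cap + 1e-9))
  }
})

test_that("a stationary spot chains into one full-length tracklet", {
  det <- tibble::tibble(frame = 0:9, x_px = 50, y_px = 50)
  tr <- build_tracklets(det, default_linking_params(), 1)
  expect_equal(dplyr::n_distinct(tr$track_id), 1L)
  expect_equal(nrow(tr), 10L)
  expect_false(any(tr$gap_closed))
})

test_that("spots farther apart than the cap form separate tracklets", {
  det <- tibble::tibble(frame = rep(0:4, each = 2),
                        x_px = rep(c(10, 110), 5), y_px = 20)
  tr <- build_tracklets(det, default_linking_params(), 1)
  expect_equal(dplyr::n_distinct(tr$track_id), 2L)
  by_track <- split(tr$x_px, tr$track_id)
  expect_true(all(vapply(by_track, function(v) length(unique(v)) == 1,
                         logical(1))))
})

test_that("tracking conserves detections and never duplicates them", {
  set.seed(32)
  det <- tibble::tibble(frame = rep(0:14, each = 4),
                        x_px = runif(60, 0, 200), y_px = runif(60, 0, 200))
  tr <- track_spots(det, default_linking_params(), 1)
  expect_equal(nrow(tr), nrow(det))
  expect_false(any(duplicated(tr[, c("frame", "x_px", "y_px")]) &
                   duplicated(tr[, c("frame", "x_px", "y_px", "track_id")])))
  # within a track, frames strictly increase
  ok <- tapply(tr$frame, tr$track_id, function(f) all(diff(f) > 0))
  expect_true(all(ok))
})

test_that("gap closing merges across <= 5 skipped frames but not 6", {
  make_gap <- function(k) {
    tibble::tibble(frame = c(0:4, (5 + k):(9 + k)),
                   x_px = c(rep(20, 5), rep(30, 5)), y_px = 20)
  }
  p <- default_linking_params()
  t5 <- track_spots(make_gap(5), p, 1)  # 10 um jump, 5 skipped frames
  expect_equal(dplyr::n_distinct(t5$track_id), 1L)
  expect_equal(sum(t5$gap_closed), 1L)
  t6 <- track_spots(make_gap(6), p, 1)
  expect_equal(dplyr::n_distinct(t6$track_id), 2L)
})

test_that("gap closing respects the 12 um distance cap", {
  far <- tibble::tibble(frame = c(0:2, 5:7),
                        x_px = c(rep(20, 3), rep(33, 3)), y_px = 20)
  expect_equal(dplyr::n_distinct(
    track_spots(far, default_linking_params(), 1)$track_id), 2L)
})

test_that("gap closing picks the nearest candidate start", {
  det <- tibble::tibble(frame = c(0:2, 5:7, 5:7),
                        x_px = c(rep(20, 3), rep(23, 3), rep(28, 3)),
                        y_px = rep(c(20, 20, 20), each = 3))
  tr <- track_spots(det, default_linking_params(), 1)
  merged <- tr[tr$frame == 0, "track_id"][[1]]
  joined_x <- tr$x_px[tr$track_id == merged & tr$frame == 5]
  expect_equal(joined_x, 23)  # 3 um beats 8 um
})

test_that("gap closing never increases the number of tracks", {
  set.seed(33)
  for (rep in 1:10) {
    det <- tibble::tibble(frame = sample(0:12, 40, replace = TRUE),
                          x_px = runif(40, 0, 80), y_px = runif(40, 0, 80))
    det <- det[!duplicated(det), ]
    tl <- build_tracklets(det, default_linking_params(), 1)
    gc <- close_gaps(tl, default_linking_params(), 1)
    expect_lte(dplyr::n_distinct(gc$track_id),
               dplyr::n_distinct(tl$track_id))
    expect_equal(nrow(gc), nrow(tl))
  }
})

test_that("high-SNR simulated cells are tracked with the right identity", {
  sim <- simulate_movie(n_cells = 8, n_frames = 25, seed = 14,
                        height_px = 256, width_px = 256)
  cfg <- default_config()
  res <- run_pipeline(sim$movie, cfg, stromal_mask = sim$truth$mask)
  j <- dplyr::inner_join(
    dplyr::select(res$tracks, track_id, frame, rx = x_px, ry = y_px),
    dplyr::select(sim$truth$tracks, cell_id, frame, tx = x_px, ty = y_px),
    by = "frame", relationship = "many-to-many")
  j$d2 <- (j$rx - j$tx)^2 + (j$ry - j$ty)^2
  near <- j |> dplyr::group_by(track_id, frame) |>
    dplyr::slice_min(d2, n = 1, with_ties = FALSE) |> dplyr::ungroup()
  # almost every tracked position lies on a true cell
  expect_gte(mean(near$d2 <= 4), 0.99)
})

test_that("trajectory statistics match direct geometry", {
  still <- tibble::tibble(track_id = 1L, frame = 0:4, x_px = 10, y_px = 10)
  s <- trajectory_stats(still, 1, 5)
  expect_equal(s$path_length_um, 0)
  expect_equal(s$net_displacement_um, 0)
  expect_equal(s$confinement_ratio, 0)
  expect_equal(s$duration_min, 25)

  square <- tibble::tibble(track_id = 1L, frame = 0:4,
                           x_px = c(0, 7, 7, 0, 0), y_px = c(0, 0, 7, 7, 0))
  s <- trajectory_stats(square, 1, 5)
  expect_equal(s$path_length_um, 28)
  expect_equal(s$net_displacement_um, 0)

  set.seed(34)
  walk <- tibble::tibble(track_id = 1L, frame = 0:20,
                         x_px = cumsum(rnorm(21)), y_px = cumsum(rnorm(21)))
  s <- trajectory_stats(walk, 2, 5)
  manual <- sum(sqrt(diff(walk$x_px)^2 + diff(walk$y_px)^2)) * 2
  expect_equal(s$path_length_um, manual)
  expect_true(s$confinement_ratio >= 0 && s$confinement_ratio <= 1)
  expect_lte(s$net_displacement_um, s$path_length_um)
})
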