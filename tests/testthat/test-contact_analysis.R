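toy_mask <- function(n = 20, fg = cbind(10, 10)) {
  m <- matrix(FALSE, n, n)
  m[fg] <- TRUE
  m
}

test_that("contact is boundary-inclusive against the exact distance", {
  # single foreground pixel at (x=9, y=9) 0-based; spot on it, near it,
  # and at exactly the contact radius (3-4-5 triangle: distance 5)
  m <- toy_mask(20, cbind(10, 10))
  expect_true(in_contact(9, 9, m, contact_radius_um = 0, pixel_size_um = 1))
  expect_true(in_contact(12, 13, m, contact_radius_um = 5, pixel_size_um = 1))
  expect_false(in_contact(12, 13, m, contact_radius_um = 4.999,
                          pixel_size_um = 1))
  expect_false(in_contact(9, 18, m, contact_radius_um = 5, pixel_size_um = 1))
})

test_that("an empty mask means no contact, never an error", {
  m <- matrix(FALSE, 10, 10)
  expect_false(in_contact(5, 5, m, 4, 1))
  expect_equal(in_contact(c(1, 2), c(1, 2), m, 4, 1), c(FALSE, FALSE))
})

test_that("pixel size converts the contact radius correctly", {
  m <- toy_mask(20, cbind(10, 10))
  # 4 px at 0.5 um/px = 2 um
  expect_true(in_contact(13, 9, m, contact_radius_um = 2, pixel_size_um = 0.5))
  expect_false(in_contact(13, 9, m, contact_radius_um = 1.9,
                          pixel_size_um = 0.5))
})

test_that("a track entering the stroma flips its timeline once", {
  m <- matrix(FALSE, 40, 40)
  m[, 30:40] <- TRUE  # stroma = columns x >= 29
  track <- tibble::tibble(frame = 0:9, x_px = seq(2, 29, length.out = 10),
                          y_px = 20)
  tl <- contact_timeline(track, m, contact_params(contact_radius_um = 4), 1)
  dist_to_stroma <- 29 - track$x_px  # x steps 2, 5, ..., 29; within 4 um at x >= 25
  expect_equal(tl$in_contact, dist_to_stroma <= 4)
  expect_equal(tl$in_contact, c(rep(FALSE, 8), rep(TRUE, 2)))
})

test_that("per-frame masks are required for every track frame", {
  track <- tibble::tibble(frame = 0:2, x_px = 5, y_px = 5)
  masks <- list(toy_mask(10, cbind(5, 5)), toy_mask(10, cbind(5, 5)))
  expect_error(contact_timeline(track, masks, contact_params(), 1),
               "missing mask")
})

test_that("episode extraction follows the published duration convention", {
  flags <- rep(FALSE, 10)
  flags[4:5] <- TRUE  # frames 3 and 4 (0-based)
  ep <- extract_episodes(flags, contact_params(min_episode_frames = 2), 5)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$start_frame, 3L)
  expect_equal(ep$end_frame, 4L)
  expect_equal(ep$n_frames, 2L)
  expect_equal(ep$duration_min, 10)  # 2 frames x 5 min
})

test_that("an isolated single contact frame is below the episode window", {
  flags <- c(FALSE, TRUE, FALSE, FALSE)
  ep <- extract_episodes(flags, contact_params(min_episode_frames = 2), 5)
  expect_equal(nrow(ep), 0L)
})

test_that("runs are never bridged across an interruption by default", {
  ep <- extract_episodes(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
                         contact_params(min_episode_frames = 2), 5)
  expect_equal(ep$n_frames, c(3L, 2L))
  expect_equal(ep$start_frame, c(0L, 4L))
})

test_that("episode extraction equals the run-length oracle on random strings", {
  set.seed(51)
  for (rep in 1:300) {
    flags <- runif(sample(1:30, 1)) < 0.5
    min_len <- sample(1:3, 1)
    got <- extract_episodes(flags, contact_params(min_episode_frames = min_len),
                            5)
    want <- oracle_runs(flags, min_len)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start_frame, want$start_frame)
      expect_equal(got$end_frame, want$end_frame)
      expect_equal(got$duration_min, want$n_frames * 5)
    }
  }
})

test_that("timelines with non-consecutive observed frames break runs", {
  tl <- tibble::tibble(frame = c(0L, 1L, 3L, 4L),
                       in_contact = c(TRUE, TRUE, TRUE, TRUE))
  ep <- extract_episodes(tl, contact_params(min_episode_frames = 2), 5)
  expect_equal(ep$start_frame, c(0L, 3L))
  expect_equal(ep$n_frames, c(2L, 2L))
})

test_that("arrest coefficient is the contact fraction", {
  expect_equal(arrest_coefficient(rep(FALSE, 8)), 0)
  expect_equal(arrest_coefficient(rep(TRUE, 8)), 1)
  expect_equal(arrest_coefficient(c(rep(TRUE, 3), rep(FALSE, 9))), 0.25)
  expect_error(arrest_coefficient(logical(0)), "empty")
})

test_that("dilating the mask never shortens episodes or arrest", {
  set.seed(52)
  base <- matrix(FALSE, 60, 60)
  base[25:35, 25:35] <- TRUE
  grown <- matrix(FALSE, 60, 60)
  grown[23:37, 23:37] <- TRUE
  for (rep in 1:20) {
    track <- tibble::tibble(frame = 0:19,
                            x_px = cumsum(rnorm(20, 0, 6)) %% 59,
                            y_px = cumsum(rnorm(20, 0, 6)) %% 59)
    p <- contact_params(contact_radius_um = 4, min_episode_frames = 2)
    tl0 <- contact_timeline(track, base, p, 1)
    tl1 <- contact_timeline(track, grown, p, 1)
    expect_true(all(tl1$in_contact | !tl0$in_contact))  # superset
    expect_gte(arrest_coefficient(tl1), arrest_coefficient(tl0))
    ep0 <- extract_episodes(tl0, p, 5)
    ep1 <- extract_episodes(tl1, p, 5)
    expect_gte(sum(ep1$duration_min), sum(ep0$duration_min))
  }
})

test_that("episode durations per track cannot exceed the movie duration", {
  sim <- simulate_movie(n_cells = 10, n_frames = 30, seed = 16,
                        height_px = 192, width_px = 192)
  res <- run_pipeline(sim$movie, stromal_mask = sim$truth$mask)
  if (nrow(res$episodes) > 0) {
    per_track <- tapply(res$episodes$duration_min, res$episodes$track_id, sum)
    expect_true(all(per_track <= 30 * 5))
  }
})

test_that("identical samples give p = 1 under the exact rank-sum test", {
  cmp <- compare_conditions(c(3, 1, 4, 1), c(3, 1, 4, 1))
  expect_equal(cmp$p.value, 1)
  expect_match(cmp$method, "exact")
})

test_that("exact rank-sum p matches full enumeration on a toy instance", {
  # {1,2} vs {100,101}: rank sums over C(4,2)=6 labelings are
  # {3,4,5,5,6,7}; |W-5| >= 2 for W in {3,7} -> p = 2/6
  cmp <- compare_conditions(c(1, 2), c(100, 101))
  expect_equal(cmp$p.value, 1 / 3, tolerance = 1e-12)
})

test_that("exact rank-sum agrees with wilcox.test on tie-free samples", {
  set.seed(53)
  for (rep in 1:20) {
    a <- sample(1:1000, sample(3:8, 1))
    b <- sample(1001:2000, sample(3:8, 1))
    got <- compare_conditions(a, b)$p.value
    want <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("comparison input validation and t-test route work", {
  expect_error(compare_conditions(1, c(1, 2)), ">= 2")
  expect_error(compare_conditions(c(2, 2, 2), c(2, 2, 2), test = "t"),
               "zero variance")
  cmp <- compare_conditions(c(10, 12, 9, 14), c(30, 28, 33, 31), test = "t")
  expect_lt(cmp$p.value, 0.01)
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$p.value, cmp$p.value)
  gl <- glance(cmp)
  expect_equal(gl$n_a, 4L)
})
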