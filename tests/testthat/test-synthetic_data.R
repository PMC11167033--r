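test_that("motility model validates its rates", {
  m <- motility_model("antigen")
  expect_equal(c(m$p_on, m$p_off), c(0.6, 0.05))
  m <- motility_model("control")
  expect_equal(c(m$p_on, m$p_off), c(0.1, 0.5))
  expect_error(motility_model(p_on = 1.2), "p_on")
  expect_error(motility_model(step_sd_arrest_um = 7), "step_sd_arrest_um")
})

test_that("zero cells give an empty truth and a blank tracked channel", {
  sim <- simulate_movie(n_cells = 0, n_frames = 3, seed = 2,
                        height_px = 64, width_px = 64)
  expect_equal(nrow(sim$truth$tracks), 0L)
  expect_equal(nrow(sim$truth$episodes), 0L)
  # background + noise only: nothing approaching blob amplitude
  expect_lt(max(sim$movie$frames$treg[[1]]), 1)
})

test_that("identical seeds reproduce the movie bit for bit", {
  a <- simulate_movie(n_cells = 5, n_frames = 6, seed = 42,
                      height_px = 96, width_px = 96)
  b <- simulate_movie(n_cells = 5, n_frames = 6, seed = 42,
                      height_px = 96, width_px = 96)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$tracks, b$truth$tracks)
  c <- simulate_movie(n_cells = 5, n_frames = 6, seed = 43,
                      height_px = 96, width_px = 96)
  expect_false(identical(a$movie$frames$treg[[1]], c$movie$frames$treg[[1]]))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_movie(n_cells = 2, n_frames = 3, seed = 1,
                           height_px = 64, width_px = 64))
  expect_identical(.Random.seed, before)
})

test_that("simulator preconditions reject bad geometry", {
  expect_error(simulate_movie(n_cells = 2, n_frames = 1, seed = 1), "n_frames")
  expect_error(simulate_movie(n_cells = 2, n_frames = 5, seed = 1,
                              height_px = 0), "dimensions")
  expect_error(simulate_movie(n_cells = 2, n_frames = 5), "seed")
})

test_that("antigen arrest yields longer true contact episodes than control", {
  ag <- simulate_movie(n_cells = 40, n_frames = 90,
                       model = motility_model("antigen"), seed = 21)
  ct <- simulate_movie(n_cells = 40, n_frames = 90,
                       model = motility_model("control"), seed = 21)
  expect_gt(mean(ag$truth$episodes$duration_min),
            mean(ct$truth$episodes$duration_min))
})

test_that("truth episodes are exactly the maximal runs of the contact state", {
  sim <- simulate_movie(n_cells = 12, n_frames = 40, seed = 8,
                        height_px = 192, width_px = 192)
  redone <- do.call(rbind, lapply(split(sim$truth$tracks,
                                        sim$truth$tracks$cell_id), function(g) {
    g <- g[order(g$frame), ]
    runs <- oracle_runs(g$in_contact, min_len = 1L)
    if (nrow(runs) == 0) return(NULL)
    cbind(cell_id = g$cell_id[1], runs)
  }))
  got <- as.data.frame(sim$truth$episodes[
    order(sim$truth$episodes$cell_id, sim$truth$episodes$start_frame),
    c("cell_id", "start_frame", "end_frame", "n_frames")])
  rownames(got) <- rownames(redone) <- NULL
  expect_equal(got, as.data.frame(redone))
})

test_that("raising the arrest on-rate does not reduce total arrested frames", {
  tot <- vapply(c(0.1, 0.4, 0.8), function(p) {
    sim <- simulate_movie(n_cells = 200, n_frames = 25,
                          model = motility_model("antigen", p_on = p),
                          seed = 77, height_px = 256, width_px = 256)
    sum(sim$truth$tracks$arrested)
  }, numeric(1))
  expect_true(all(diff(tot) >= 0))
})

test_that("IF field marker fraction matches the request to within 0.01", {
  f <- simulate_if_field(n_cells_rich = 6, n_cells_poor = 2,
                         marker_area_fraction = 0.25, seed = 4)
  expect_gte(f$truth$marker_area_fraction, 0.24)
  expect_lte(f$truth$marker_area_fraction, 0.26)
  z <- simulate_if_field(n_cells_rich = 0, n_cells_poor = 0,
                         marker_area_fraction = 0.1, seed = 4)
  expect_equal(nrow(z$truth$cells), 0L)
})

test_that("IF fields are reproducible and reject overcrowding", {
  a <- simulate_if_field(seed = 9)
  b <- simulate_if_field(seed = 9)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_error(simulate_if_field(n_cells_rich = 400, seed = 1,
                                 height_px = 96, width_px = 96),
               "overcrowding")
  expect_error(simulate_if_field(marker_area_fraction = 1.3, seed = 1),
               "marker_area_fraction")
})

test_that("puncta images record exact truth counts", {
  one <- simulate_puncta_image(
    cells = tibble::tibble(x_px = 60, y_px = 60, radius_um = 8, n_puncta = 7L),
    seed = 5, height_px = 128, width_px = 128)
  expect_equal(one$truth$counts$n_puncta, 7L)
  expect_equal(nrow(one$truth$puncta), 7L)
  zero <- simulate_puncta_image(
    cells = tibble::tibble(x_px = 60, y_px = 60, radius_um = 8, n_puncta = 0L),
    seed = 5, height_px = 128, width_px = 128)
  expect_equal(zero$truth$counts$n_puncta, 0L)
  expect_error(simulate_puncta_image(
    cells = tibble::tibble(x_px = 60, y_px = 60, radius_um = 8, n_puncta = -1L),
    seed = 5), "puncta count")
  expect_error(simulate_puncta_image(
    cells = tibble::tibble(x_px = 60, y_px = 60, radius_um = 1, n_puncta = 2L),
    seed = 5), "fit")
})
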