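# Seeded synthetic-image generators with full ground truth. Each generator
# draws everything from one seeded RNG stream with a fixed draw order, so
# identical seeds give bit-identical output and parameter variants stay
# coupled (common random numbers).

#' Two-state motility model for simulated tracked cells
#'
#' Cells diffuse with isotropic Gaussian steps and switch between a free
#' and an arrested state. Arrest can only be entered while the cell is
#' inside the contact zone (the stromal mask dilated by the cell radius);
#' it is left with per-frame probability `p_off`. The `"antigen"`
#' condition models antigen-dependent movement arrest (high on-rate, low
#' off-rate); `"control"` models transient encounters without arrest.
#'
#' @param condition `"antigen"` (p_on 0.6, p_off 0.05) or `"control"`
#'   (p_on 0.1, p_off 0.5); explicit `p_on`/`p_off` override these.
#' @param step_sd_free_um Step SD while free (µm/frame).
#' @param step_sd_arrest_um Step SD while arrested (µm/frame); must be
#'   smaller than `step_sd_free_um`.
#' @param p_on,p_off Per-frame arrest entry/exit probabilities in \[0, 1\].
#' @return A validated list of class `motility_model`.
#' @examples
#' motility_model("antigen")
#' @export
motility_model <- function(condition = c("antigen", "control"),
                           step_sd_free_um = 6, step_sd_arrest_um = 0.5,
                           p_on = NULL, p_off = NULL) {
  condition <- match.arg(condition)
  defaults <- if (condition == "antigen") c(0.6, 0.05) else c(0.1, 0.5)
  p_on <- p_on %||% defaults[1]
  p_off <- p_off %||% defaults[2]
  if (p_on < 0 || p_on > 1 || p_off < 0 || p_off > 1) {
    abort("p_on and p_off must be in [0, 1]")
  }
  assert_scalar_pos(step_sd_free_um, "step_sd_free_um")
  if (step_sd_arrest_um < 0 || step_sd_arrest_um >= step_sd_free_um) {
    abort("step_sd_arrest_um must be in [0, step_sd_free_um)")
  }
  structure(list(condition = condition, step_sd_free_um = step_sd_free_um,
                 step_sd_arrest_um = step_sd_arrest_um,
                 p_on = p_on, p_off = p_off),
            class = c("motility_model", "list"))
}

# Build a stromal mask from a spec list: shape "disk" (default), "band",
# or "custom" with an explicit logical matrix.
build_stromal_mask <- function(mask_spec, height_px, width_px) {
  spec <- mask_spec %||% list(shape = "disk")
  shape <- spec$shape %||% "disk"
  if (shape == "custom") {
    m <- spec$mask
    if (!is.matrix(m) || !all(dim(m) == c(height_px, width_px))) {
      abort("custom mask must be a logical matrix of the image shape")
    }
    return(m > 0)
  }
  if (shape == "band") {
    lo <- spec$x_from %||% floor(width_px / 3)
    hi <- spec$x_to %||% floor(2 * width_px / 3)
    cols <- matrix(rep(seq_len(width_px) - 1L, each = height_px),
                   height_px, width_px)
    return(cols >= lo & cols <= hi)
  }
  cy <- spec$center_y %||% ((height_px - 1) / 2)
  cx <- spec$center_x %||% ((width_px - 1) / 2)
  r <- spec$radius_px %||% round(0.31 * min(height_px, width_px))
  yy <- matrix(rep(seq_len(height_px) - 1L, times = width_px), height_px, width_px)
  xx <- matrix(rep(seq_len(width_px) - 1L, each = height_px), height_px, width_px)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Additively render Gaussian blobs at 0-based centers (x, y).
render_blobs <- function(img, x, y, sigma_px, amplitude) {
  if (length(x) == 0L) return(img)
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(3.5 * sigma_px)
  for (i in seq_along(x)) {
    rows <- max(1L, floor(y[i]) + 1L - r):min(h, floor(y[i]) + 1L + r)
    cols <- max(1L, floor(x[i]) + 1L - r):min(w, floor(x[i]) + 1L + r)
    dy <- (rows - 1L) - y[i]
    dx <- (cols - 1L) - x[i]
    patch <- amplitude * exp(-outer(dy^2, dx^2, `+`) / (2 * sigma_px^2))
    img[rows, cols] <- img[rows, cols] + patch
  }
  img
}

reflect_coord <- function(p, lo, hi) {
  span <- hi - lo
  q <- (p - lo) %% (2 * span)
  lo + ifelse(q > span, 2 * span - q, q)
}

# Cells are impenetrable: push any pair of centers closer than min_sep
# apart, symmetrically along their separation vector (a few deterministic
# relaxation sweeps; no RNG so the draw stream is untouched).
resolve_collisions <- function(x, y, min_sep, width_px, height_px,
                               max_iter = 10L) {
  n <- length(x)
  if (n < 2L) return(list(x = x, y = y))
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    for (i in seq_len(n - 1L)) {
      dx <- x[(i + 1L):n] - x[i]
      dy <- y[(i + 1L):n] - y[i]
      d2 <- dx^2 + dy^2
      hit <- which(d2 < min_sep^2)
      for (h in hit) {
        j <- i + h
        d <- sqrt(d2[h])
        if (d < 1e-9) { ux <- 1; uy <- 0 } else { ux <- dx[h] / d; uy <- dy[h] / d }
        push <- (min_sep - d) / 2
        x[i] <- x[i] - ux * push; y[i] <- y[i] - uy * push
        x[j] <- x[j] + ux * push; y[j] <- y[j] + uy * push
        moved <- TRUE
      }
    }
    x <- pmin(pmax(x, 0), width_px - 1)
    y <- pmin(pmax(y, 0), height_px - 1)
    if (!moved) break
  }
  list(x = x, y = y)
}

#' Simulate a two-channel CAF-Treg co-culture movie with ground truth
#'
#' Generates a dual-channel time lapse: spot-like motile cells (Gaussian
#' blobs, tracked-cell channel) moving by the two-state
#' [motility_model()] over a static textured stromal region (stromal
#' channel). Arrest entry is only possible inside the contact zone — the
#' stromal mask dilated by the cell radius, the same rule the analysis
#' side uses — so recovery of contact episodes is well-posed. Boundaries
#' reflect.
#'
#' @param n_cells Number of simulated cells (>= 0).
#' @param n_frames Number of frames (>= 2).
#' @param model A [motility_model()].
#' @param mask_spec Stromal mask spec: `list(shape = "disk"|"band"|"custom",
#'   ...)`; see details in the source. `NULL` = centered disk.
#' @param noise_sd Gaussian background noise SD (intensity units).
#' @param seed Integer seed (required).
#' @param height_px,width_px Image size in pixels.
#' @param pixel_size_um Pixel size (µm/px).
#' @param frame_interval_min Frame interval (minutes).
#' @param cell_diameter_um Rendered cell blob diameter (µm); matches the
#'   default detection diameter.
#' @param amplitude Blob peak intensity above background (arbitrary
#'   units; the default gives detection qualities well above the default
#'   quality threshold of 1).
#' @return A list of class `caf_simulation`: `movie` (a [movie()] with
#'   channels `treg` and `caf`) and `truth` with `tracks` (cell_id, frame,
#'   x_px, y_px, arrested, in_contact), `mask`, `episodes` (all maximal
#'   runs of the true contact state, min length 1) and the model.
#' @examples
#' sim <- simulate_movie(n_cells = 3, n_frames = 10, seed = 1,
#'                       height_px = 96, width_px = 96)
#' sim$truth$episodes
#' @export
simulate_movie <- function(n_cells = 40, n_frames = 90,
                           model = motility_model("antigen"),
                           mask_spec = NULL, noise_sd = 0.05, seed,
                           height_px = 320, width_px = 320,
                           pixel_size_um = 1, frame_interval_min = 5,
                           cell_diameter_um = 8, amplitude = 4) {
  if (missing(seed)) abort("seed is required")
  stopifnot(inherits(model, "motility_model"))
  if (n_frames < 2) abort("n_frames must be >= 2")
  if (height_px <= 0 || width_px <= 0) abort("image dimensions must be > 0")
  if (n_cells < 0) abort("n_cells must be >= 0")

  mask <- build_stromal_mask(mask_spec, height_px, width_px)
  cell_radius_px <- um_to_px(cell_diameter_um, pixel_size_um) / 2
  sigma_render <- um_to_px(cell_diameter_um, pixel_size_um) / (2 * sqrt(2))
  dt_px <- distance_to_foreground(mask)
  in_zone_at <- function(x, y) {
    if (length(x) == 0L) return(logical(0))
    bilinear_at(dt_px, x, y) <= cell_radius_px
  }
  sd_free <- um_to_px(model$step_sd_free_um, pixel_size_um)
  sd_arr <- um_to_px(model$step_sd_arrest_um, pixel_size_um)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  # --- dynamics (all dynamics draws precede all rendering draws) ---
  x <- matrix(numeric(0), n_cells, n_frames)
  y <- matrix(numeric(0), n_cells, n_frames)
  arrested <- matrix(logical(0), n_cells, n_frames)
  if (n_cells > 0L) {
    x <- matrix(NA_real_, n_cells, n_frames)
    y <- matrix(NA_real_, n_cells, n_frames)
    arrested <- matrix(FALSE, n_cells, n_frames)
    min_sep <- 2 * cell_radius_px  # impenetrable cell bodies
    p0 <- resolve_collisions(runif(n_cells, 0, width_px - 1),
                             runif(n_cells, 0, height_px - 1),
                             min_sep, width_px, height_px)
    x[, 1] <- p0$x
    y[, 1] <- p0$y
    state <- rep(FALSE, n_cells)
    for (f in 2:n_frames) {
      u <- runif(n_cells)
      inz <- in_zone_at(x[, f - 1], y[, f - 1])
      enter <- !state & inz & u < model$p_on
      leave <- state & u < model$p_off
      state <- (state | enter) & !leave
      step <- matrix(rnorm(2 * n_cells), n_cells, 2)
      sd_now <- ifelse(state, sd_arr, sd_free)
      p <- resolve_collisions(
        reflect_coord(x[, f - 1] + step[, 1] * sd_now, 0, width_px - 1),
        reflect_coord(y[, f - 1] + step[, 2] * sd_now, 0, height_px - 1),
        min_sep, width_px, height_px)
      x[, f] <- p$x
      y[, f] <- p$y
      arrested[, f] <- state
    }
  }

  # --- rendering ---
  # stromal channel: adherent cells do not rearrange between frames, so
  # the texture is drawn once and reused (static stromal scene). The
  # region has background mean with elevated texture only, as in phase
  # contrast where adherent cells differ by local contrast, not mean
  # intensity: local contrast ~0.12 inside vs ~0.02 outside.
  tex <- matrix(rnorm(height_px * width_px, 0, 0.004), height_px, width_px)
  tex[mask] <- rnorm(sum(mask), 0, 0.024)
  caf_plane <- pmax(0.2 + tex, 0)
  treg <- vector("list", n_frames)
  caf <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    bg <- 0.2 + matrix(rnorm(height_px * width_px, 0, noise_sd),
                       height_px, width_px)
    if (n_cells > 0L) {
      bg <- render_blobs(bg, x[, f], y[, f], sigma_render, amplitude)
    }
    treg[[f]] <- pmax(bg, 0)
    caf[[f]] <- caf_plane
  }

  truth_tracks <- if (n_cells > 0L) {
    purrr::map_dfr(seq_len(n_cells), function(i) {
      tibble(cell_id = i, frame = seq_len(n_frames) - 1L,
             x_px = x[i, ], y_px = y[i, ],
             arrested = arrested[i, ],
             in_contact = in_zone_at(x[i, ], y[i, ]))
    })
  } else {
    tibble(cell_id = integer(0), frame = integer(0), x_px = numeric(0),
           y_px = numeric(0), arrested = logical(0), in_contact = logical(0))
  }
  truth_episodes <- truth_episode_table(truth_tracks, frame_interval_min)

  structure(
    list(
      movie = movie(list(treg = treg, caf = caf), pixel_size_um,
                    frame_interval_min),
      truth = list(tracks = truth_tracks, mask = mask,
                   episodes = truth_episodes, model = model,
                   cell_radius_px = cell_radius_px),
      seed = seed
    ),
    class = "caf_simulation"
  )
}

# All maximal runs of the true contact state, per cell (min length 1;
# downstream comparisons apply their own minimal-length filter).
truth_episode_table <- function(truth_tracks, frame_interval_min) {
  empty <- tibble(cell_id = integer(0), start_frame = integer(0),
                  end_frame = integer(0), n_frames = integer(0),
                  duration_min = numeric(0))
  if (nrow(truth_tracks) == 0L) return(empty)
  out <- truth_tracks |>
    group_by(.data$cell_id) |>
    dplyr::group_map(function(g, key) {
      ep <- extract_episodes(
        tibble(frame = g$frame, in_contact = g$in_contact),
        contact_params(min_episode_frames = 1L), frame_interval_min)
      if (nrow(ep) == 0L) return(NULL)
      mutate(ep, cell_id = key$cell_id, .before = 1L)
    }) |>
    bind_rows()
  if (nrow(out) == 0L) empty else out
}

#' @export
print.caf_simulation <- function(x, ...) {
  cat(sprintf("<caf_simulation> seed %d, %s condition\n", x$seed,
              x$truth$model$condition))
  print(x$movie)
  cat(sprintf("  truth: %d cell(s), %d contact episode(s)\n",
              dplyr::n_distinct(x$truth$tracks$cell_id),
              nrow(x$truth$episodes)))
  invisible(x)
}

#' Simulate a two-channel immunofluorescence field with ground truth
#'
#' A nuclei channel with countable blobs and a marker channel whose true
#' foreground fraction equals `marker_area_fraction` to within one pixel
#' (the foreground mask is a smooth random field thresholded at the
#' matching quantile, biased toward the left "rich" half of the field).
#' Cells are placed by rejection sampling with a minimal separation;
#' overcrowded requests error.
#'
#' @param n_cells_rich,n_cells_poor Cells placed in the left (rich) and
#'   right (poor) halves of the field.
#' @param marker_area_fraction Requested marker foreground fraction in
#'   \[0, 1\].
#' @param seed Integer seed (required).
#' @param height_px,width_px Field size (px).
#' @param pixel_size_um Pixel size (µm/px).
#' @param cell_diameter_um Rendered nucleus blob diameter (µm).
#' @param amplitude Nucleus blob peak intensity.
#' @param noise_sd Background noise SD.
#' @return A list of class `caf_if_field`: `nuclei`, `marker` (matrices),
#'   `regions` (named list of rich/poor masks) and `truth` (cell positions
#'   and counts per region, marker mask and its exact fraction).
#' @export
simulate_if_field <- function(n_cells_rich = 12, n_cells_poor = 4,
                              marker_area_fraction = 0.25, seed,
                              height_px = 256, width_px = 256,
                              pixel_size_um = 1, cell_diameter_um = 8,
                              amplitude = 4, noise_sd = 0.02) {
  if (missing(seed)) abort("seed is required")
  if (marker_area_fraction < 0 || marker_area_fraction > 1) {
    abort("marker_area_fraction must be in [0, 1]")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  xx <- matrix(rep(seq_len(width_px) - 1L, each = height_px), height_px, width_px)
  rich_region <- xx < width_px / 2
  regions <- list(rich = rich_region, poor = !rich_region)

  # marker mask: smooth noise field, biased to the rich half, cut at the
  # quantile that yields the requested fraction exactly (up to one pixel)
  field <- blur_gaussian(matrix(rnorm(height_px * width_px), height_px, width_px), 8)
  field <- field / stats::sd(field) + ifelse(rich_region, 0.8, -0.8)
  marker_mask <- if (marker_area_fraction == 0) {
    matrix(FALSE, height_px, width_px)
  } else if (marker_area_fraction == 1) {
    matrix(TRUE, height_px, width_px)
  } else {
    field > quantile(field, 1 - marker_area_fraction, names = FALSE)
  }

  d_px <- um_to_px(cell_diameter_um, pixel_size_um)
  margin <- d_px / 2 + 2
  min_sep <- 1.5 * d_px
  place <- function(region_mask, n, placed_x, placed_y) {
    px <- numeric(0); py <- numeric(0)
    tries <- 0L
    while (length(px) < n) {
      tries <- tries + 1L
      if (tries > 400L * max(n, 1L)) abort("overcrowding: cannot place cells")
      cx <- runif(1, margin, width_px - 1 - margin)
      cy <- runif(1, margin, height_px - 1 - margin)
      if (!region_mask[floor(cy) + 1, floor(cx) + 1]) next
      ax <- c(placed_x, px); ay <- c(placed_y, py)
      if (length(ax) > 0 && any((ax - cx)^2 + (ay - cy)^2 < min_sep^2)) next
      px <- c(px, cx); py <- c(py, cy)
    }
    list(x = px, y = py)
  }
  rich <- place(rich_region, n_cells_rich, numeric(0), numeric(0))
  poor <- place(!rich_region, n_cells_poor, rich$x, rich$y)

  nuclei <- 0.1 + matrix(rnorm(height_px * width_px, 0, noise_sd),
                         height_px, width_px)
  nuclei <- render_blobs(nuclei, c(rich$x, poor$x), c(rich$y, poor$y),
                         d_px / (2 * sqrt(2)), amplitude)
  nuclei <- pmax(nuclei, 0)
  marker <- 0.1 + matrix(rnorm(height_px * width_px, 0, noise_sd),
                         height_px, width_px)
  marker[marker_mask] <- marker[marker_mask] + 0.6
  marker <- pmax(marker, 0)

  cells <- tibble(
    cell_id = seq_len(n_cells_rich + n_cells_poor),
    x_px = c(rich$x, poor$x), y_px = c(rich$y, poor$y),
    region = rep(c("rich", "poor"), c(n_cells_rich, n_cells_poor))
  )
  structure(
    list(nuclei = nuclei, marker = marker, regions = regions,
         pixel_size_um = pixel_size_um,
         truth = list(cells = cells,
                      n_rich = n_cells_rich, n_poor = n_cells_poor,
                      marker_mask = marker_mask,
                      marker_area_fraction = mean(marker_mask)),
         seed = seed),
    class = "caf_if_field"
  )
}

#' Simulate cells with countable fluorescent puncta
#'
#' Renders, per cell, a dim cytoplasm disk, a nucleus blob (separate
#' channel) and `n_puncta` small bright Gaussian puncta placed inside the
#' cell at mutual separations large enough to be resolvable. Ground-truth
#' puncta counts and cell disk labels are recorded.
#'
#' @param cells Tibble with `x_px`, `y_px`, `radius_um`, `n_puncta` (one
#'   row per cell). Default: two cells with 5 and 9 puncta.
#' @param seed Integer seed (required).
#' @param height_px,width_px Image size (px).
#' @param pixel_size_um Pixel size (µm/px); puncta imaging is
#'   high-magnification, default 0.2.
#' @param punctum_diameter_um Rendered punctum diameter (µm).
#' @param punctum_amplitude Punctum peak intensity.
#' @param noise_sd Background noise SD.
#' @return A list of class `caf_puncta_image`: channels `nuclei`,
#'   `cytoplasm`, `puncta`, and `truth` (per-cell counts, punctum
#'   positions, label matrix of true cell disks).
#' @export
simulate_puncta_image <- function(cells = NULL, seed,
                                  height_px = 256, width_px = 256,
                                  pixel_size_um = 0.2,
                                  punctum_diameter_um = 0.8,
                                  punctum_amplitude = 1, noise_sd = 0.005) {
  if (missing(seed)) abort("seed is required")
  if (is.null(cells)) {
    cells <- tibble(x_px = c(70, 186), y_px = c(70, 186),
                    radius_um = 8, n_puncta = c(5L, 9L))
  }
  if (any(cells$n_puncta < 0)) abort("puncta count must be >= 0")
  if (any(cells$radius_um <= 2 * punctum_diameter_um)) {
    abort("puncta do not fit inside the cell radius")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  r_px <- um_to_px(cells$radius_um, pixel_size_um)
  sig_p <- um_to_px(punctum_diameter_um, pixel_size_um) / (2 * sqrt(2))
  min_sep_px <- um_to_px(2, pixel_size_um)  # 2 um between puncta

  yy <- matrix(rep(seq_len(height_px) - 1L, times = width_px), height_px, width_px)
  xx <- matrix(rep(seq_len(width_px) - 1L, each = height_px), height_px, width_px)
  labels <- matrix(0L, height_px, width_px)
  cyto <- 0.02 + matrix(rnorm(height_px * width_px, 0, noise_sd),
                        height_px, width_px)
  nuclei <- 0.02 + matrix(rnorm(height_px * width_px, 0, noise_sd),
                          height_px, width_px)
  puncta_ch <- 0.02 + matrix(rnorm(height_px * width_px, 0, noise_sd),
                             height_px, width_px)

  truth_puncta <- list()
  for (i in seq_len(nrow(cells))) {
    disk <- (yy - cells$y_px[i])^2 + (xx - cells$x_px[i])^2 <= r_px[i]^2
    labels[disk] <- i
    cyto[disk] <- cyto[disk] + 0.4
    nuclei <- render_blobs(nuclei, cells$x_px[i], cells$y_px[i],
                           0.25 * r_px[i], 4)
    n <- cells$n_puncta[i]
    if (n > 0L) {
      px <- numeric(0); py <- numeric(0)
      tries <- 0L
      while (length(px) < n) {
        tries <- tries + 1L
        if (tries > 500L * n) abort("overcrowding: cannot place puncta")
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1, 0.25^2, 0.85^2)) * r_px[i]
        qx <- cells$x_px[i] + rad * cos(ang)
        qy <- cells$y_px[i] + rad * sin(ang)
        if (length(px) > 0 && any((px - qx)^2 + (py - qy)^2 < min_sep_px^2)) next
        px <- c(px, qx); py <- c(py, qy)
      }
      puncta_ch <- render_blobs(puncta_ch, px, py, sig_p, punctum_amplitude)
      truth_puncta[[i]] <- tibble(cell_id = i, x_px = px, y_px = py)
    }
  }
  counts <- tibble(cell_id = seq_len(nrow(cells)),
                   n_puncta = as.integer(cells$n_puncta))
  structure(
    list(nuclei = pmax(nuclei, 0), cytoplasm = pmax(cyto, 0),
         puncta = pmax(puncta_ch, 0),
         pixel_size_um = pixel_size_um,
         truth = list(counts = counts,
                      puncta = bind_rows(truth_puncta),
                      labels = labels, cells = cells),
         seed = seed),
    class = "caf_puncta_image"
  )
}
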