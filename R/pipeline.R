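#' Run the full contact-duration pipeline on a movie
#'
#' Detection on the tracked-cell channel, per-frame (or static)
#' local-contrast segmentation of the stromal channel, LAP linking with
#' gap closing, per-track contact timelines, episode extraction and
#' summary statistics. Deterministic for a fixed config and input. If
#' `outdir` is given, all tables, masks and the fully resolved config are
#' written there.
#'
#' @param movie A [movie()] with the tracked-cell channel and either a
#'   stromal channel or a precomputed `stromal_mask`.
#' @param config A config list ([default_config()]); validated before use.
#' @param stromal_mask Optional precomputed mask (`caf_mask`, logical
#'   matrix, or list of masks per frame) replacing segmentation.
#' @param condition Optional condition label copied into outputs.
#' @param outdir Optional output directory (created if needed).
#' @return A list of class `caf_pipeline_result`: tibbles `detections`,
#'   `tracks`, `episodes`, `timelines`, `stats` (per-track trajectory
#'   statistics + arrest coefficient), `summary`, plus the masks and
#'   resolved config.
#' @examples
#' sim <- simulate_movie(n_cells = 4, n_frames = 12, seed = 1,
#'                       height_px = 128, width_px = 128)
#' res <- run_pipeline(sim$movie)
#' res$summary
#' @export
run_pipeline <- function(movie, config = default_config(), stromal_mask = NULL,
                         condition = NA_character_, outdir = NULL) {
  stopifnot(inherits(movie, "caf_movie"))
  validate_config(config)
  px <- movie$pixel_size_um
  dt <- movie$frame_interval_min
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  treg_ch <- config$channels$treg
  if (!treg_ch %in% movie$channel_names) {
    abort(sprintf("movie lacks tracked-cell channel '%s'", treg_ch))
  }
  det_par <- detection_params(config$detection$diameter_um,
                              config$detection$quality_min,
                              config$detection$subpixel %||% FALSE)
  link_par <- linking_params(config$linking$link_max_um,
                             config$linking$gap_max_um,
                             config$linking$gap_max_frames)
  seg_par <- segmentation_params(config$segmentation$sigma_px,
                                 config$segmentation$epsilon,
                                 config$segmentation$min_object_px,
                                 config$segmentation$fill_holes)
  con_par <- contact_params(config$contact$contact_radius_um,
                            config$contact$min_episode_frames,
                            config$contact$bridge_max_frames)

  detections <- stage("detection", detect_movie(movie, treg_ch, det_par))

  masks <- stage("segmentation", {
    if (!is.null(stromal_mask)) {
      if (inherits(stromal_mask, "caf_mask") || is.matrix(stromal_mask)) {
        list(static = stromal_mask)
      } else {
        stromal_mask
      }
    } else {
      caf_ch <- config$channels$caf
      if (!caf_ch %in% movie$channel_names) {
        abort(sprintf("movie lacks stromal channel '%s' and no mask given",
                      caf_ch))
      }
      if (identical(config$segmentation$mode, "static")) {
        list(static = segment_texture(movie$frames[[caf_ch]][[1]], seg_par))
      } else {
        lapply(movie$frames[[caf_ch]], segment_texture, params = seg_par)
      }
    }
  })
  static_mask <- length(masks) == 1L && identical(names(masks), "static")

  tracks <- stage("tracking", track_spots(detections, link_par, px))

  timelines <- stage("contact", {
    if (nrow(tracks) == 0L) {
      tibble(track_id = integer(0), frame = integer(0), in_contact = logical(0))
    } else {
      # one distance transform per distinct mask, evaluated for all spots
      fg_of <- function(m) if (inherits(m, "caf_mask")) m$mask else m
      flags <- logical(nrow(tracks))
      if (static_mask) {
        fg <- fg_of(masks$static)
        if (any(fg)) {
          dt_px <- distance_to_foreground(fg)
          flags <- bilinear_at(dt_px, tracks$x_px, tracks$y_px) * px <=
            con_par$contact_radius_um
        }
      } else {
        if (any(tracks$frame + 1L > length(masks))) {
          abort("missing mask for a track frame")
        }
        for (f in sort(unique(tracks$frame))) {
          rows <- which(tracks$frame == f)
          fg <- fg_of(masks[[f + 1L]])
          if (!any(fg)) next
          dt_px <- distance_to_foreground(fg)
          flags[rows] <- bilinear_at(dt_px, tracks$x_px[rows],
                                     tracks$y_px[rows]) * px <=
            con_par$contact_radius_um
        }
      }
      tibble(track_id = tracks$track_id, frame = tracks$frame,
             in_contact = flags) |>
        arrange(.data$track_id, .data$frame)
    }
  })

  episodes <- stage("episodes", {
    if (nrow(timelines) == 0L) {
      tibble(track_id = integer(0), start_frame = integer(0),
             end_frame = integer(0), n_frames = integer(0),
             duration_min = numeric(0))
    } else {
      timelines |>
        group_by(.data$track_id) |>
        dplyr::group_map(function(g, key) {
          ep <- extract_episodes(g, con_par, dt)
          if (nrow(ep) == 0L) return(NULL)
          mutate(ep, track_id = key$track_id, .before = 1L)
        }) |>
        bind_rows()
    }
  })
  if (nrow(episodes) == 0L) {
    episodes <- tibble(track_id = integer(0), start_frame = integer(0),
                       end_frame = integer(0), n_frames = integer(0),
                       duration_min = numeric(0))
  }

  stats <- stage("stats", {
    st <- trajectory_stats(tracks, px, dt)
    if (nrow(st) > 0L) {
      ac <- timelines |>
        group_by(.data$track_id) |>
        summarise(arrest_coefficient = mean(.data$in_contact), .groups = "drop")
      st <- left_join(st, ac, by = "track_id")
    } else {
      st$arrest_coefficient <- numeric(0)
    }
    st
  })

  summary <- tibble(
    condition = condition,
    n_tracks = dplyr::n_distinct(tracks$track_id),
    n_episodes = nrow(episodes),
    mean_duration_min = if (nrow(episodes)) mean(episodes$duration_min) else NA_real_,
    median_duration_min = if (nrow(episodes)) median(episodes$duration_min) else NA_real_,
    mean_arrest_coefficient = if (nrow(stats)) mean(stats$arrest_coefficient) else NA_real_,
    mean_net_displacement_um = if (nrow(stats)) mean(stats$net_displacement_um) else NA_real_
  )

  result <- structure(
    list(detections = detections, tracks = tracks, timelines = timelines,
         episodes = episodes, stats = stats, summary = summary,
         masks = masks, config = config, condition = condition,
         pixel_size_um = px, frame_interval_min = dt),
    class = "caf_pipeline_result"
  )
  if (!is.null(outdir)) write_pipeline_result(result, outdir)
  result
}

#' @export
print.caf_pipeline_result <- function(x, ...) {
  cat("<caf_pipeline_result>\n")
  print(x$summary)
  invisible(x)
}

write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_table(result$tracks, file.path(outdir, "tracks.csv"))
  write_table(result$episodes, file.path(outdir, "episodes.csv"))
  write_table(result$stats, file.path(outdir, "stats.csv"))
  write_table(result$summary, file.path(outdir, "summary.csv"))
  write_config(result$config, file.path(outdir, "config.yaml"))
  msk <- result$masks
  for (k in seq_along(msk)) {
    m <- msk[[k]]
    fg <- if (inherits(m, "caf_mask")) m$mask else m
    nm <- if (identical(names(msk), "static")) "mask_static.png" else
      sprintf("mask_frame_%04d.png", k - 1L)
    write_mask_png(fg, file.path(outdir, nm))
  }
  invisible(outdir)
}

#' Write a table as CSV with fixed column order
#'
#' Comma-separated, UTF-8, mandatory header, no index column; floating
#' point values rendered with 6 significant digits so re-reading
#' reproduces the file exactly. An empty table writes a header-only file.
#'
#' @param records A data frame or tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) abort("records must be a data frame")
  out <- as_tibble(records)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- formatC(out[[nm]], digits = 6, format = "g")
    }
  }
  readr::write_csv(out, path)
  invisible(path)
}
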